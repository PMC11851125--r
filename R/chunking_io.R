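#' Med-MAD normalize a raw signal
#'
#' Robust normalization standard in basecalling pipelines:
#' `(x - median(x)) / (1.4826 * mad(x))`. When the MAD is zero (constant or
#' near-constant signal) the divisor falls back to 1 so the output is simply
#' median-centered.
#'
#' @param signal numeric vector of raw current samples (nonempty).
#' @return Normalized numeric vector of the same length.
#' @export
normalize_signal <- function(signal) {
  if (length(signal) == 0L) stop("empty signal")
  med <- median(signal)
  scale <- 1.4826 * median(abs(signal - med))
  if (scale == 0) scale <- 1
  (signal - med) / scale
}

# Temporal geometry of a conv stack: output length and the offset between a
# frame index and the input sample at the center of its receptive field.
.conv_out_len <- function(L, conv_specs) {
  for (cs in conv_specs) L <- (L + 2L * cs[2] - cs[1]) %/% cs[3] + 1L
  as.integer(L)
}
.conv_frame_offset <- function(conv_specs) {
  # stride-1 stacks only: cumulative center shift (k-1)/2 - p per layer
  sum(vapply(conv_specs, function(cs) (cs[1] - 1) / 2 - cs[2], 0))
}

#' Cut a read into fixed-length chunks
#'
#' Signals are cut into non-overlapping chunks of `chunk_len` samples. In
#' `"train"` mode the trailing partial chunk is dropped; in `"inference"` mode
#' it is zero-padded and its valid length recorded. Each chunk's `label` is
#' the subsequence of bases whose dwell midpoint falls inside the chunk, and
#' `frame_labels` holds one class index (1..4, or NA when no base maps there)
#' per encoder output frame, derived from the read's exact `base_index`
#' alignment via the conv stack's frame-to-sample geometry.
#'
#' @param read a `simulated_read` (or a list with `signal`, and optionally
#'   `sequence` + `base_index` for labels).
#' @param chunk_len samples per chunk (default 3600).
#' @param mode `"train"` (drop tail) or `"inference"` (pad tail).
#' @param conv_specs conv layer specs used to derive per-frame labels;
#'   defaults to the standard three-layer front-end.
#' @param normalize med-MAD normalize the whole read before chunking
#'   (per-read, so chunk boundaries do not change levels).
#' @return List of `chunk` objects: `signal`, `label`, `frame_labels`,
#'   `valid_len`, `start`.
#' @export
chunk_read <- function(read, chunk_len = 3600L,
                       mode = c("train", "inference"),
                       conv_specs = default_conv_specs(),
                       normalize = TRUE) {
  mode <- match.arg(mode)
  chunk_len <- as.integer(chunk_len)
  if (chunk_len < 1L) stop("chunk_len must be >= 1")
  signal <- if (normalize) normalize_signal(read$signal) else read$signal
  L <- length(signal)
  n_full <- L %/% chunk_len
  n_chunks <- if (mode == "inference" && L %% chunk_len > 0L) n_full + 1L else n_full
  if (n_chunks == 0L) return(list())

  has_labels <- !is.null(read$base_index) && !is.null(read$sequence)
  base_classes <- NULL; base_chunk <- NULL
  if (has_labels) {
    bases <- strsplit(read$sequence, "")[[1]]
    # midpoint (in samples) of each base's dwell; bases never resident in the
    # pore (k > 1 edges) have no samples and are dropped from labels
    first <- match(seq_along(bases), read$base_index)
    last <- length(read$base_index) + 1L -
      match(seq_along(bases), rev(read$base_index))
    mid <- (first + last) / 2
    base_classes <- match(bases, BASES)
    base_chunk <- ceiling(mid / chunk_len)
  }

  offset <- round(.conv_frame_offset(conv_specs))
  lapply(seq_len(n_chunks), function(ci) {
    s0 <- (ci - 1L) * chunk_len
    valid <- min(chunk_len, L - s0)
    sig <- signal[s0 + seq_len(valid)]
    if (valid < chunk_len) sig <- c(sig, numeric(chunk_len - valid))
    label <- ""
    frame_labels <- NULL
    if (has_labels) {
      inb <- which(!is.na(base_chunk) & base_chunk == ci)
      label <- paste0(bases[inb], collapse = "")
      t_enc <- .conv_out_len(chunk_len, conv_specs)
      samp <- pmin(pmax(seq_len(t_enc) + offset, 1L), chunk_len)
      bidx <- ifelse(samp <= valid, read$base_index[s0 + pmin(samp, valid)],
                     NA_integer_)
      frame_labels <- base_classes[bidx]
    }
    structure(list(signal = sig, label = label, frame_labels = frame_labels,
                   valid_len = valid, start = s0 + 1L),
              class = "chunk")
  })
}

#' Default convolution front-end geometry
#'
#' The printed three-layer stack: kernels 5/5/19, paddings 1/1/10, all
#' strides 1, channels 4/16/512 (the last equals the model width).
#'
#' @param width output channels of the final layer (model width).
#' @return List of `c(kernel, padding, stride, out_channels)` per layer.
#' @export
default_conv_specs <- function(width = 512L) {
  list(c(5L, 1L, 1L, 4L), c(5L, 1L, 1L, 16L), c(19L, 10L, 1L, as.integer(width)))
}

#' Write sequences as FASTA (80-column wrapped)
#'
#' @param sequences named character vector of DNA sequences.
#' @param path output file.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path FASTA file.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write basecalls as FASTQ
#'
#' Standard 4-line-per-record FASTQ with Phred+33 qualities. Qualities may be
#' given as integer vectors (one per base) or pre-encoded strings; records
#' without qualities get `'!'` placeholders.
#'
#' @param records list of lists with fields `id`, `sequence` and optionally
#'   `quality` (integer Phred scores or a character string).
#' @param path output file.
#' @export
write_fastq <- function(records, path) {
  lines <- character(0)
  if (length(records)) {
    lines <- unlist(lapply(records, function(r) {
      if (grepl("[[:space:]]", r$id)) stop("FASTQ id contains whitespace: ", r$id)
      if (nchar(r$sequence) && grepl("[^ACGT]", r$sequence))
        stop("sequence must be over {A,C,G,T}")
      q <- r$quality
      qs <- if (is.null(q)) {
        strrep("!", nchar(r$sequence))
      } else if (is.character(q)) {
        q
      } else {
        intToUtf8(pmin(pmax(as.integer(q), 0L), 93L) + 33L)
      }
      if (nchar(qs) != nchar(r$sequence))
        stop("quality length mismatch for record ", r$id)
      c(paste0("@", r$id), r$sequence, "+", qs)
    }))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTQ file
#' @param path FASTQ file.
#' @return List with `sequences` (named character) and `qualities` (named
#'   character, Phred+33 encoded).
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) stop("malformed FASTQ: ", path)
  n <- length(lines) %/% 4L
  if (n == 0L) return(list(sequences = character(0), qualities = character(0)))
  ids <- sub("^@", "", sub("[[:space:]].*$", "", lines[seq(1L, by = 4L, length.out = n)]))
  list(sequences = setNames(lines[seq(2L, by = 4L, length.out = n)], ids),
       qualities = setNames(lines[seq(4L, by = 4L, length.out = n)], ids))
}
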