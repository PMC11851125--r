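# Inference workflow: per-read med-MAD normalization, non-overlapping
# chunking (trailing partial chunk zero-padded), encoder forward without
# masking, prefix beam search per chunk, and in-order concatenation of the
# chunk basecalls (chunks do not overlap, so no merge step is needed).

# Per-base Phred qualities for a decoded sequence: the CTC state posteriors
# given the decoded label are computed by the forward-backward pass, and each
# base's quality is the maximum over frames of its state's posterior —
# a documented heuristic, capped at Q40.
.base_qualities <- function(logp, sequence) {
  n <- nchar(sequence)
  if (n == 0L) return(integer(0))
  cl <- .as_label_classes(sequence)
  res <- .ctc_forward_cpp(logp, cl, FALSE, TRUE)
  if (!res$feasible || is.null(res$state_post))
    return(rep(0L, n))
  sp <- res$state_post
  p <- vapply(seq_len(n), function(j) max(sp[, 2L * j]), 0)
  q <- -10 * log10(pmax(1 - p, 1e-4))
  pmin(pmax(as.integer(round(q)), 0L), 40L)
}

#' Basecall one raw signal
#'
#' Normalizes the signal (med-MAD over the whole read), cuts it into
#' non-overlapping chunks (the trailing partial chunk is zero-padded),
#' runs the encoder in eval mode (no masking, no dropout), decodes each chunk
#' by CTC prefix beam search, and concatenates the chunk basecalls in order.
#'
#' @param model a `squeezecall_model`.
#' @param signal numeric vector of raw current samples.
#' @param beam_width prefix beam width (default 5).
#' @param chunk_len samples per chunk (default 3600).
#' @return List with `sequence`, `quality` (integer Phred scores, one per
#'   base) and `chunk_scores` (per-chunk decoder log-probability scores).
#' @export
basecall_signal <- function(model, signal, beam_width = 5L,
                            chunk_len = 3600L) {
  if (length(signal) < 25L)
    return(list(sequence = "", quality = integer(0), chunk_scores = numeric(0)))
  chunks <- chunk_read(list(signal = signal), chunk_len = chunk_len,
                       mode = "inference",
                       conv_specs = model$config$conv_specs)
  seqs <- character(length(chunks))
  quals <- vector("list", length(chunks))
  scores <- numeric(length(chunks))
  for (i in seq_along(chunks)) {
    ch <- chunks[[i]]
    if (ch$valid_len < 25L) { seqs[i] <- ""; quals[[i]] <- integer(0); next }
    fwd <- .encoder_fwd(model, ch$signal)
    t_valid <- .conv_out_len(ch$valid_len, model$config$conv_specs)
    logp <- fwd$logp[seq_len(min(t_valid, nrow(fwd$logp))), , drop = FALSE]
    dec <- beam_search(logp, width = beam_width)
    seqs[i] <- dec$sequence
    scores[i] <- dec$score
    quals[[i]] <- .base_qualities(logp, dec$sequence)
  }
  list(sequence = paste0(seqs, collapse = ""),
       quality = unlist(quals, use.names = FALSE),
       chunk_scores = scores)
}

#' Basecall a dataset to FASTQ
#'
#' Runs [basecall_signal()] over every read of a dataset directory and writes
#' a FASTQ of basecalls.
#'
#' @param model a `squeezecall_model`.
#' @param dataset a `squiggle_dataset` or a dataset directory path.
#' @param out_fastq output FASTQ path.
#' @param beam_width,chunk_len decoding parameters.
#' @return Invisibly, the per-read list of basecall results.
#' @export
basecall_dataset <- function(model, dataset, out_fastq, beam_width = 5L,
                             chunk_len = 3600L) {
  if (is.character(dataset)) dataset <- read_dataset(dataset)
  results <- lapply(names(dataset$reads), function(id) {
    basecall_signal(model, dataset$reads[[id]]$signal,
                    beam_width = beam_width, chunk_len = chunk_len)
  })
  names(results) <- names(dataset$reads)
  records <- lapply(names(results), function(id) {
    r <- results[[id]]
    list(id = id, sequence = r$sequence, quality = r$quality)
  })
  records <- Filter(function(r) nchar(r$sequence) > 0L, records)
  write_fastq(records, out_fastq)
  invisible(results)
}
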