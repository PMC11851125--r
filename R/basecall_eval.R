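# Read-to-reference evaluation: global edit-distance alignment with full
# traceback, the standard basecalling error decomposition, identity rate,
# homopolymer/heteropolymer accuracy, and the median chunk match rate.

#' Align a basecalled read to its reference
#'
#' Global alignment with unit costs (match 0, mismatch/gap 1) and a full
#' traceback. Operations are reported relative to the reference: an extra
#' read base is an insertion (`I`), a reference base missing from the read is
#' a deletion (`D`). Traceback ties are broken deterministically:
#' match/mismatch first, then deletion, then insertion.
#'
#' @param read basecalled sequence (may be empty).
#' @param reference reference sequence (nonempty).
#' @return An `alignment_report`: counts (`matches`, `mismatches`,
#'   `insertions`, `deletions`), `alignment_length`, `read_length`,
#'   `ref_length` and the operation string `ops` over M/X/I/D.
#' @export
align_read <- function(read, reference) {
  if (nchar(reference) == 0L) stop("reference must be nonempty")
  if (grepl("[^ACGT]", read) || grepl("[^ACGT]", reference))
    stop("sequences must be over {A,C,G,T}")
  a <- .align_cpp(read, reference)
  rep <- structure(
    list(matches = a$matches, mismatches = a$mismatches,
         insertions = a$insertions, deletions = a$deletions,
         alignment_length = nchar(a$ops), read_length = nchar(read),
         ref_length = nchar(reference), ops = a$ops,
         edit_distance = a$distance),
    class = "alignment_report")
  stopifnot(
    rep$alignment_length ==
      rep$matches + rep$mismatches + rep$insertions + rep$deletions,
    rep$read_length == rep$matches + rep$mismatches + rep$insertions,
    rep$ref_length == rep$matches + rep$mismatches + rep$deletions)
  rep
}

#' @export
print.alignment_report <- function(x, ...) {
  cat(sprintf(
    "alignment_report: %d cols | M %d X %d I %d D %d | read %d ref %d\n",
    x$alignment_length, x$matches, x$mismatches, x$insertions, x$deletions,
    x$read_length, x$ref_length))
  invisible(x)
}

#' Deletion / insertion / mismatch / error rates
#'
#' Each count divided by the alignment length; the error rate is the sum of
#' the three.
#'
#' @param report an [align_read()] result.
#' @return Named numeric vector `(deletion, insertion, mismatch, error)`.
#' @export
error_rates <- function(report) {
  stopifnot(inherits(report, "alignment_report"), report$alignment_length > 0L)
  al <- report$alignment_length
  r <- c(deletion = report$deletions / al, insertion = report$insertions / al,
         mismatch = report$mismatches / al)
  c(r, error = sum(r))
}

#' Identity rate
#'
#' The fraction of the basecalled read that aligns as matches:
#' matches / read length. Note the denominator differs from [error_rates()]
#' (alignment length), so identity is not simply 1 minus the error rate.
#'
#' @param report an [align_read()] result with `read_length > 0`.
#' @return Real in `[0, 1]`.
#' @export
identity_rate <- function(report) {
  stopifnot(inherits(report, "alignment_report"))
  if (report$read_length == 0L) stop("identity rate undefined for empty read")
  report$matches / report$read_length
}

# Maximal homopolymer runs (single repeated base) in a reference.
.homopolymer_runs <- function(ref, unit = NULL) {
  r <- rle(strsplit(ref, "")[[1]])
  ends <- cumsum(r$lengths)
  out <- data.frame(start = ends - r$lengths + 1L, end = ends,
                    unit = r$values, length = r$lengths,
                    stringsAsFactors = FALSE)
  if (!is.null(unit)) out <- out[out$unit == unit, , drop = FALSE]
  out
}

# Maximal alternating (2-base tandem) stretches, e.g. ACACA; unit is the
# first two characters, length counted in bases. Only stretches of >= 4
# bases qualify as heteropolymers.
.heteropolymer_runs <- function(ref, unit = NULL) {
  s <- strsplit(ref, "")[[1]]
  n <- length(s)
  runs <- list()
  i <- 1L
  while (i < n) {
    if (s[i] != s[i + 1L]) {
      j <- i + 1L
      while (j < n && s[j + 1L] == s[j - 1L]) j <- j + 1L
      if (j - i + 1L >= 4L)
        runs[[length(runs) + 1L]] <-
          data.frame(start = i, end = j, unit = paste0(s[i], s[i + 1L]),
                     length = j - i + 1L, stringsAsFactors = FALSE)
      i <- j
    } else i <- i + 1L
  }
  out <- if (length(runs)) do.call(rbind, runs)
  else data.frame(start = integer(0), end = integer(0),
                  unit = character(0), length = integer(0))
  if (!is.null(unit)) out <- out[out$unit == unit, , drop = FALSE]
  out
}

# For every alignment column, the reference position it touches (NA for
# insertions, which sit between reference positions).
.run_correct <- function(report, start, end) {
  ops <- strsplit(report$ops, "")[[1]]
  fi <- 0L
  inside_ok <- TRUE
  for (op in ops) {
    if (op == "I") {
      # insertion between reference positions fi and fi+1: corrupts the run
      # when strictly interior
      if (fi >= start && fi < end) inside_ok <- FALSE
    } else {
      fi <- fi + 1L
      if (fi >= start && fi <= end && op != "M") inside_ok <- FALSE
      if (fi > end) break
    }
  }
  inside_ok
}

#' Homopolymer / heteropolymer accuracy
#'
#' Locates every maximal run of the repeat unit in the reference with exactly
#' the given length (homopolymer: a single repeated base, lengths >= 3;
#' heteropolymer: a perfect tandem repeat of a 2-base unit, length counted in
#' bases). A run is called correct iff the read segment aligned to it by the
#' traceback reproduces the run exactly — every run column a match and no
#' interior insertion. Accuracy is correct runs / total runs.
#'
#' @param alignments list of [align_read()] reports; each must carry the
#'   reference it was computed against in `attr(x, "reference")`, or pass
#'   `references`.
#' @param references character vector of reference sequences (one per
#'   alignment).
#' @param length exact run length in bases.
#' @param type `"homopolymer"` or `"heteropolymer"`.
#' @param unit optional: restrict to one repeat unit (a base, e.g. `"A"`, or
#'   a 2-mer, e.g. `"AC"`); default aggregates all units.
#' @return Accuracy in `[0, 1]`; `NA` with a classed warning
#'   (`squeezecall_no_runs`) when the references contain no qualifying run.
#' @export
polymer_accuracy <- function(alignments, references, length,
                             type = c("homopolymer", "heteropolymer"),
                             unit = NULL) {
  type <- match.arg(type)
  if (inherits(alignments, "alignment_report")) alignments <- list(alignments)
  if (type == "homopolymer" && length < 3L)
    stop("homopolymer accuracy is defined for lengths >= 3")
  total <- 0L; correct <- 0L
  for (i in seq_along(alignments)) {
    rep <- alignments[[i]]
    ref <- references[i]
    runs <- if (type == "homopolymer") .homopolymer_runs(ref, unit)
            else .heteropolymer_runs(ref, unit)
    runs <- runs[runs$length == length, , drop = FALSE]
    if (nrow(runs) == 0L) next
    total <- total + nrow(runs)
    for (k in seq_len(nrow(runs)))
      if (.run_correct(rep, runs$start[k], runs$end[k]))
        correct <- correct + 1L
  }
  if (total == 0L) {
    warning(warningCondition(
      sprintf("no %s runs of length %d found", type, length),
      class = "squeezecall_no_runs"))
    return(NA_real_)
  }
  correct / total
}

#' Median chunk match rate
#'
#' Aligns each basecalled chunk to its label and returns the median of
#' matches / alignment length (even counts average the middle two).
#'
#' @param basecalls character vector of chunk basecalls.
#' @param labels character vector of chunk labels (same length).
#' @return Median match rate in `[0, 1]`.
#' @export
chunk_match_rate <- function(basecalls, labels) {
  stopifnot(length(basecalls) == length(labels), length(labels) >= 1L)
  rates <- mapply(function(bc, lab) {
    if (nchar(lab) == 0L) return(if (nchar(bc) == 0L) 1 else 0)
    rep <- align_read(bc, lab)
    rep$matches / rep$alignment_length
  }, basecalls, labels)
  median(rates)
}

#' Evaluate basecalls against references
#'
#' Pairs FASTQ basecalls with FASTA references by record id, aligns each
#' pair, and produces a per-read table plus aggregate summaries mirroring the
#' usual reporting layout: mean/median of each rate, identity, and a
#' homopolymer/heteropolymer accuracy table by run length.
#'
#' @param fastq path to basecalls (FASTQ).
#' @param fasta path to references (FASTA).
#' @param out_csv optional path; when given the per-read table is written
#'   there as CSV.
#' @param polymer_lengths homopolymer lengths for the accuracy table
#'   (default 3:9; heteropolymers use the even lengths 4,6,8,10).
#' @return List with `per_read` (data.table), `summary` (named list) and
#'   `polymer` (data.table).
#' @export
evaluate_basecalls <- function(fastq, fasta, out_csv = NULL,
                               polymer_lengths = 3:9) {
  calls <- read_fastq(fastq)$sequences
  refs <- read_fasta(fasta)
  ids <- intersect(names(calls), names(refs))
  if (length(ids) == 0L) stop("no shared record ids between FASTQ and FASTA")
  reports <- lapply(ids, function(id) align_read(calls[[id]], refs[[id]]))
  per_read <- data.table::rbindlist(lapply(seq_along(ids), function(i) {
    r <- reports[[i]]
    er <- error_rates(r)
    data.table::data.table(
      read_id = ids[i], read_length = r$read_length,
      ref_length = r$ref_length, matches = r$matches,
      mismatches = r$mismatches, insertions = r$insertions,
      deletions = r$deletions, deletion_rate = er[["deletion"]],
      insertion_rate = er[["insertion"]], mismatch_rate = er[["mismatch"]],
      error_rate = er[["error"]],
      identity = if (r$read_length > 0L) identity_rate(r) else NA_real_)
  }))
  if (!is.null(out_csv)) data.table::fwrite(per_read, out_csv)

  summarize <- function(x) c(mean = mean(x, na.rm = TRUE),
                             median = median(x, na.rm = TRUE))
  summary <- list(
    n_reads = length(ids),
    deletion_rate = summarize(per_read$deletion_rate),
    insertion_rate = summarize(per_read$insertion_rate),
    mismatch_rate = summarize(per_read$mismatch_rate),
    error_rate = summarize(per_read$error_rate),
    identity = summarize(per_read$identity))

  hp <- data.table::rbindlist(lapply(polymer_lengths, function(l) {
    acc <- withCallingHandlers(
      polymer_accuracy(reports, refs[ids], l, "homopolymer"),
      squeezecall_no_runs = function(w) invokeRestart("muffleWarning"))
    data.table::data.table(type = "homopolymer", length = l, accuracy = acc)
  }))
  het <- data.table::rbindlist(lapply(c(4L, 6L, 8L, 10L), function(l) {
    acc <- withCallingHandlers(
      polymer_accuracy(reports, refs[ids], l, "heteropolymer"),
      squeezecall_no_runs = function(w) invokeRestart("muffleWarning"))
    data.table::data.table(type = "heteropolymer", length = l, accuracy = acc)
  }))
  list(per_read = per_read, summary = summary,
       polymer = data.table::rbindlist(list(hp, het)))
}
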