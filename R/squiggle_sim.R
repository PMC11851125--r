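#' Build a k-mer pore model
#'
#' A pore model maps every k-mer to the mean current level observed while that
#' k-mer occupies the pore, together with the per-sample Gaussian noise level
#' and the bounds of the uniform integer dwell (samples spent per position).
#' Levels are drawn from a seeded standard normal and then standardized to
#' mean 0, sd 1 across the 4^k k-mers, so simulated signals live on the same
#' scale regardless of k.
#'
#' @param k k-mer order (1..6; the table has 4^k entries).
#' @param seed integer seed for the level table.
#' @param noise_sd per-sample Gaussian noise standard deviation (>= 0).
#' @param dwell_min,dwell_max inclusive bounds of the uniform integer dwell.
#' @return An object of class `pore_model`.
#' @examples
#' pm <- make_pore_model(k = 1, seed = 1)
#' length(pm$level_table)  # 4
#' @export
make_pore_model <- function(k, seed, noise_sd = 0.1,
                            dwell_min = 5L, dwell_max = 10L) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (k > 6L) stop("k > 6 rejected: level table would have 4^k > 4096 entries")
  dwell_min <- as.integer(dwell_min); dwell_max <- as.integer(dwell_max)
  if (dwell_min < 1L || dwell_max < dwell_min)
    stop("invalid dwell bounds: need 1 <= dwell_min <= dwell_max")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  kmers <- .all_kmers(k)
  levels <- withr::with_seed(as.integer(seed), rnorm(length(kmers)))
  levels <- (levels - mean(levels)) / stats::sd(levels)
  structure(
    list(k = k, level_table = setNames(levels, kmers), noise_sd = noise_sd,
         dwell_min = dwell_min, dwell_max = dwell_max, seed = as.integer(seed)),
    class = "pore_model")
}

.all_kmers <- function(k) {
  g <- do.call(expand.grid,
               c(rep(list(BASES), k), list(stringsAsFactors = FALSE)))
  # vary the first position slowest so the order is lexicographic
  apply(g[, rev(seq_len(k)), drop = FALSE], 1L, paste0, collapse = "")
}

#' @export
print.pore_model <- function(x, ...) {
  cat(sprintf("pore_model: k=%d (%d k-mers), noise_sd=%.3g, dwell %d-%d\n",
              x$k, length(x$level_table), x$noise_sd, x$dwell_min, x$dwell_max))
  invisible(x)
}

#' Draw a uniform random DNA sequence
#'
#' @param length sequence length (>= 0).
#' @param seed integer seed.
#' @return A character scalar over {A,C,G,T}.
#' @export
random_sequence <- function(length, seed) {
  length <- as.integer(length)
  if (length < 0L) stop("length must be >= 0")
  if (length == 0L) return("")
  idx <- withr::with_seed(as.integer(seed),
                          sample.int(4L, length, replace = TRUE))
  paste0(BASES[idx], collapse = "")
}

#' Simulate a nanopore read from a pore model
#'
#' For each k-mer position an integer dwell is drawn uniformly from
#' `[dwell_min, dwell_max]`; the signal holds the k-mer's table level for that
#' many samples, plus i.i.d. Gaussian noise. `base_index` records, for every
#' sample, the 1-based index of the central base of the resident k-mer — the
#' exact signal-to-base alignment that real pipelines recover by resquiggling.
#'
#' @param sequence DNA string over {A,C,G,T}, length >= k.
#' @param model a [make_pore_model()] object.
#' @param seed integer seed (dwells and noise).
#' @return An object of class `simulated_read` with fields `sequence`,
#'   `signal`, `base_index`.
#' @export
simulate_read <- function(sequence, model, seed) {
  stopifnot(inherits(model, "pore_model"))
  n <- nchar(sequence)
  if (n < model$k) stop("sequence shorter than the pore model's k")
  if (grepl("[^ACGT]", sequence)) stop("sequence must be over {A,C,G,T}")
  npos <- n - model$k + 1L
  kmers <- substring(sequence, seq_len(npos), seq_len(npos) + model$k - 1L)
  levels <- unname(model$level_table[kmers])
  central <- seq_len(npos) + (model$k - 1L) %/% 2L
  sim <- withr::with_seed(as.integer(seed), {
    dwells <- if (model$dwell_min == model$dwell_max) {
      rep.int(model$dwell_min, npos)
    } else {
      model$dwell_min +
        sample.int(model$dwell_max - model$dwell_min + 1L, npos,
                   replace = TRUE) - 1L
    }
    signal <- rep.int(levels, dwells)
    if (model$noise_sd > 0)
      signal <- signal + rnorm(length(signal), sd = model$noise_sd)
    list(signal = signal, dwells = dwells)
  })
  structure(
    list(sequence = sequence, signal = sim$signal,
         base_index = rep.int(central, sim$dwells), dwells = sim$dwells),
    class = "simulated_read")
}

#' @export
print.simulated_read <- function(x, ...) {
  cat(sprintf("simulated_read: %d bases, %d samples\n",
              nchar(x$sequence), length(x$signal)))
  invisible(x)
}

#' Simulate a dataset of reads and write it to disk
#'
#' Writes a hierarchical on-disk dataset: `manifest.json` (simulation
#' parameters and read table), `reads.fasta` (reference sequences, 80-column
#' wrapped) and `signals.csv` (long format: read_id, signal, base_index).
#'
#' @param n_reads number of reads (>= 1).
#' @param read_length bases per read.
#' @param model a [make_pore_model()] object.
#' @param seed master integer seed; per-read seeds are derived from it.
#' @param out_path output directory (created if missing).
#' @return The dataset, invisibly: a list of `simulated_read` plus the manifest.
#' @export
make_dataset <- function(n_reads, read_length, model, seed, out_path) {
  n_reads <- as.integer(n_reads)
  if (n_reads < 1L) stop("n_reads must be >= 1")
  reads <- lapply(seq_len(n_reads), function(i) {
    sq <- random_sequence(read_length, .sub_seed(seed, 2L * i))
    simulate_read(sq, model, .sub_seed(seed, 2L * i + 1L))
  })
  ids <- sprintf("read_%04d", seq_len(n_reads))
  dir.create(out_path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_path)) stop("cannot create dataset directory: ", out_path)

  write_fasta(setNames(vapply(reads, `[[`, "", "sequence"), ids),
              file.path(out_path, "reads.fasta"))
  sig <- data.table::data.table(
    read_id = rep(ids, vapply(reads, function(r) length(r$signal), 0L)),
    signal = unlist(lapply(reads, `[[`, "signal")),
    base_index = unlist(lapply(reads, `[[`, "base_index")))
  data.table::fwrite(sig, file.path(out_path, "signals.csv"))
  manifest <- list(
    format = "squeezecall-dataset-v1", n_reads = n_reads,
    read_length = read_length, seed = as.integer(seed),
    pore_model = list(k = model$k, noise_sd = model$noise_sd,
                      dwell_min = model$dwell_min, dwell_max = model$dwell_max,
                      seed = model$seed),
    read_ids = ids)
  jsonlite::write_json(manifest, file.path(out_path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(structure(list(reads = setNames(reads, ids), manifest = manifest),
                      class = "squiggle_dataset"))
}

#' Read a dataset written by [make_dataset()]
#'
#' @param path dataset directory.
#' @return A `squiggle_dataset`: named list of `simulated_read` + manifest.
#' @export
read_dataset <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("not a dataset directory (no manifest.json): ", path)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  seqs <- read_fasta(file.path(path, "reads.fasta"))
  sig <- data.table::fread(file.path(path, "signals.csv"))
  split_idx <- split(seq_len(nrow(sig)), sig$read_id)
  reads <- lapply(manifest$read_ids, function(id) {
    rows <- split_idx[[id]]
    structure(list(sequence = unname(seqs[id]),
                   signal = sig$signal[rows],
                   base_index = as.integer(sig$base_index[rows])),
              class = "simulated_read")
  })
  structure(list(reads = setNames(reads, manifest$read_ids),
                 manifest = manifest),
            class = "squiggle_dataset")
}

#' @export
print.squiggle_dataset <- function(x, ...) {
  cat(sprintf("squiggle_dataset: %d reads (k=%d)\n",
              length(x$reads), x$manifest$pore_model$k))
  invisible(x)
}
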