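#' Training configuration
#'
#' @param total_steps total optimization steps (required).
#' @param peak_lr peak learning rate (default 5e-4).
#' @param warmup_steps linear warmup length in steps (default 1000).
#' @param batch_size chunks per update (default 16).
#' @param chunk_len samples per training chunk (default 3600).
#' @param seed integer seed controlling shuffling, masking and dropout.
#' @param val_fraction fraction of chunks held out for validation
#'   (default 0.05).
#' @param eval_every validate every this many steps (0 = only at the end).
#' @param grad_clip global gradient-norm clip (default 5).
#' @return A validated `train_config` list.
#' @export
train_config <- function(total_steps, peak_lr = 5e-4, warmup_steps = 1000L,
                         batch_size = 16L, chunk_len = 3600L, seed = 1L,
                         val_fraction = 0.05, eval_every = 0L,
                         grad_clip = 5) {
  total_steps <- as.integer(total_steps)
  warmup_steps <- as.integer(warmup_steps)
  if (total_steps < 0L || warmup_steps < 1L || batch_size < 1L ||
      chunk_len < 1L || peak_lr <= 0)
    stop("all training sizes must be positive")
  if (total_steps > 0L && warmup_steps > total_steps)
    stop("warmup_steps must not exceed total_steps")
  structure(list(total_steps = total_steps, peak_lr = peak_lr,
                 warmup_steps = warmup_steps,
                 batch_size = as.integer(batch_size),
                 chunk_len = as.integer(chunk_len), seed = as.integer(seed),
                 val_fraction = val_fraction,
                 eval_every = as.integer(eval_every), grad_clip = grad_clip),
            class = "train_config")
}

#' Learning rate at a given step
#'
#' Linear warmup from 0 to `peak_lr` over the first `warmup_steps` updates,
#' then linear decay to exactly 0 at `total_steps`.
#'
#' @param step step in `0..total_steps`.
#' @param config a [train_config()].
#' @return The learning rate.
#' @export
lr_at <- function(step, config) {
  if (any(step < 0L) || any(step > config$total_steps))
    stop("step out of range [0, total_steps]")
  ifelse(step <= config$warmup_steps,
         config$peak_lr * step / config$warmup_steps,
         config$peak_lr * (config$total_steps - step) /
           (config$total_steps - config$warmup_steps))
}

# ---- Adam ------------------------------------------------------------------

.adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

.adam_step <- function(params, grads, st, lr) {
  st$t <- st$t + 1L
  b1 <- st$beta1; b2 <- st$beta2
  bc1 <- 1 - b1^st$t; bc2 <- 1 - b2^st$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + st$eps)
  }
  list(params = params, state = st)
}

.clip_grads <- function(grads, max_norm) {
  if (!is.finite(max_norm) || max_norm <= 0) return(grads)
  nrm <- sqrt(sum(vapply(grads, function(g) sum(g * g), 0)))
  if (nrm > max_norm) grads <- lapply(grads, function(g) g * (max_norm / nrm))
  grads
}

# ---- chunk preparation -----------------------------------------------------

# Flatten a dataset into training chunks (per-read med-MAD normalization,
# non-overlapping cuts, tail dropped) with base labels and per-frame classes.
.dataset_chunks <- function(dataset, chunk_len, conv_specs) {
  chunks <- list()
  for (id in names(dataset$reads)) {
    cs <- chunk_read(dataset$reads[[id]], chunk_len = chunk_len,
                     mode = "train", conv_specs = conv_specs)
    chunks <- c(chunks, cs)
  }
  chunks
}

.split_validation <- function(n, val_fraction, seed) {
  n_val <- max(1L, round(val_fraction * n))
  val <- withr::with_seed(seed, sample.int(n, min(n_val, n)))
  list(train = setdiff(seq_len(n), val), val = sort(val))
}

# ---- training loop ---------------------------------------------------------

#' Train a basecaller on a simulated dataset
#'
#' Seeded single-process loop: reads are normalized and cut into chunks,
#' 5% (configurable) are held out for validation, and the remainder is
#' shuffled every epoch. Each update runs the encoder forward with time-step
#' masking and dropout, computes the combined loss (CTC + intermediate CTC +
#' label-smoothed KL), backpropagates, clips the global gradient norm and
#' applies Adam with the warmup/decay schedule of [lr_at()]. Aborts if the
#' loss turns non-finite; chunks whose label is infeasible for the frame
#' count are skipped with a warning.
#'
#' @param model a [build_model()] object.
#' @param dataset a `squiggle_dataset` (from [make_dataset()] or
#'   [read_dataset()]).
#' @param config a [train_config()].
#' @param weights a [loss_weights()].
#' @param verbose print progress lines.
#' @return List with `model` (trained), `log` (a data.table: step, lr and the
#'   loss components), `val_match_rate` (final validation median chunk match
#'   rate) and `val_history`.
#' @export
train_basecaller <- function(model, dataset, config, weights = loss_weights(),
                             verbose = FALSE) {
  stopifnot(inherits(model, "squeezecall_model"),
            inherits(config, "train_config"))
  chunks <- .dataset_chunks(dataset, config$chunk_len,
                            model$config$conv_specs)
  if (length(chunks) < 2L)
    stop("dataset yields fewer than 2 chunks at chunk_len = ", config$chunk_len)
  sp <- .split_validation(length(chunks), config$val_fraction, config$seed)
  train_idx <- sp$train
  val_chunks <- chunks[sp$val]

  log_rows <- vector("list", config$total_steps)
  val_history <- list()
  if (config$total_steps == 0L)
    return(list(model = model, log = data.table::data.table(),
                val_match_rate = NA_real_, val_history = list()))

  withr::local_seed(config$seed)
  adam <- .adam_init(model$params)
  order_pool <- sample(train_idx)
  pos <- 1L
  for (step in seq_len(config$total_steps)) {
    take <- min(config$batch_size, length(train_idx))
    if (pos + take - 1L > length(order_pool)) {
      order_pool <- sample(train_idx)
      pos <- 1L
    }
    batch <- order_pool[pos:(pos + take - 1L)]
    pos <- pos + take

    comp <- c(total = 0, ctc = 0, inter = 0, kl = 0)
    used <- 0L
    batch_chunks <- chunks[batch]
    # the fast batched path covers the default single half-rate tap; other
    # tap configurations fall back to chunk-by-chunk processing
    cfgN <- model$config$n_half
    batched <- length(model$config$tap_blocks) == 1L &&
      model$config$tap_blocks >= cfgN &&
      model$config$tap_blocks < 2L * cfgN
    if (batched) {
      fwd <- .encoder_fwd_batch(model,
                                lapply(batch_chunks, `[[`, "signal"),
                                training = TRUE)
      d_logits <- vector("list", length(batch_chunks))
      d_taps <- vector("list", length(batch_chunks))
      for (i in seq_along(batch_chunks)) {
        ch <- batch_chunks[[i]]
        pc <- fwd$per_chunk[[i]]
        gr <- .combined_grad_logits(pc$logp, pc$tap_logp, ch$frame_labels,
                                    ch$label, weights,
                                    ctc_norm = "label_length")
        if (!gr$feasible) {
          warning("skipping chunk with infeasible label (", nchar(ch$label),
                  " bases, ", nrow(pc$logp), " frames)")
          d_logits[[i]] <- matrix(0, fwd$T_, ncol(pc$logp))
          d_taps[[i]] <- matrix(0, fwd$T_, ncol(pc$logp))
          next
        }
        d_logits[[i]] <- gr$d_final
        d_taps[[i]] <- gr$d_taps[[1L]]
        comp <- comp + c(gr$total, gr$ctc, gr$inter, gr$kl)
        used <- used + 1L
      }
      if (used == 0L) next
      acc <- .encoder_bwd_batch(model, fwd, d_logits, d_taps)
    } else {
      acc <- NULL
      for (ch in batch_chunks) {
        fwd1 <- .encoder_fwd(model, ch$signal, training = TRUE, keep = TRUE)
        gr <- .combined_grad_logits(fwd1$logp, fwd1$tap_logp,
                                    ch$frame_labels, ch$label, weights,
                                    ctc_norm = "label_length")
        if (!gr$feasible) {
          warning("skipping chunk with infeasible label (", nchar(ch$label),
                  " bases, ", nrow(fwd1$logp), " frames)")
          next
        }
        g <- .encoder_bwd(model, fwd1, gr$d_final, gr$d_taps)
        acc <- if (is.null(acc)) g else {
          for (nm in names(g)) acc[[nm]] <- acc[[nm]] + g[[nm]]
          acc
        }
        comp <- comp + c(gr$total, gr$ctc, gr$inter, gr$kl)
        used <- used + 1L
      }
      if (used == 0L) next
    }
    comp <- comp / used
    if (!is.finite(comp[["total"]]))
      stop("training diverged: non-finite loss at step ", step)
    acc <- lapply(acc, function(g) g / used)
    acc <- .clip_grads(acc, config$grad_clip)
    lr <- lr_at(step, config)
    upd <- .adam_step(model$params, acc, adam, lr)
    model$params <- upd$params
    adam <- upd$state
    log_rows[[step]] <- data.table::data.table(
      step = step, lr = lr, loss = comp[["total"]], ctc = comp[["ctc"]],
      inter = comp[["inter"]], kl = comp[["kl"]])
    if (verbose && (step %% 25L == 0L || step == 1L))
      message(sprintf("step %4d  lr %.2e  loss %8.3f (ctc %.3f inter %.3f kl %.3f)",
                      step, lr, comp[["total"]], comp[["ctc"]],
                      comp[["inter"]], comp[["kl"]]))
    if (config$eval_every > 0L && step %% config$eval_every == 0L &&
        step < config$total_steps) {
      mr <- evaluate_checkpoint(model, val_chunks)
      val_history[[length(val_history) + 1L]] <- list(step = step,
                                                      match_rate = mr)
      if (verbose) message(sprintf("step %4d  val median match rate %.4f",
                                   step, mr))
    }
  }
  mr <- evaluate_checkpoint(model, val_chunks)
  val_history[[length(val_history) + 1L]] <-
    list(step = config$total_steps, match_rate = mr)
  list(model = model, log = data.table::rbindlist(log_rows),
       val_match_rate = mr, val_history = val_history)
}

#' Median chunk match rate of a model on labelled chunks
#'
#' Greedy-decodes every chunk, aligns the basecall to the chunk label and
#' reports the median of matches / alignment length.
#'
#' @param model a `squeezecall_model`.
#' @param chunks list of labelled chunks (from [chunk_read()]), or a
#'   `squiggle_dataset` (all its chunks at the model's default geometry are
#'   used).
#' @param chunk_len chunk length used when `chunks` is a dataset.
#' @return Median match rate in `[0, 1]`.
#' @export
evaluate_checkpoint <- function(model, chunks, chunk_len = 3600L) {
  if (inherits(chunks, "squiggle_dataset"))
    chunks <- .dataset_chunks(chunks, chunk_len, model$config$conv_specs)
  if (length(chunks) == 0L) stop("no chunks to evaluate")
  calls <- vapply(chunks, function(ch) {
    greedy_decode(.encoder_fwd(model, ch$signal)$logp)
  }, "")
  labels <- vapply(chunks, `[[`, "", "label")
  chunk_match_rate(calls, labels)
}

# ---- checkpoints -----------------------------------------------------------

#' Save / load a model checkpoint
#'
#' A checkpoint stores the full parameter list and the encoder configuration;
#' loading restores a model whose forward pass is bit-identical to the saved
#' one.
#'
#' @param model a `squeezecall_model`.
#' @param path file path (.rds).
#' @param meta optional named list stored alongside (training provenance).
#' @export
save_checkpoint <- function(model, path, meta = list()) {
  stopifnot(inherits(model, "squeezecall_model"))
  obj <- list(format = "squeezecall-checkpoint-v1",
              config = unclass(model$config), params = model$params,
              meta = meta)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint` returns the restored `squeezecall_model` (with
#'   attribute `"meta"`).
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "squeezecall-checkpoint-v1"))
    stop("not a squeezecall checkpoint: ", path)
  cfg <- structure(obj$config, class = "encoder_config")
  model <- structure(list(config = cfg, params = obj$params),
                     class = "squeezecall_model")
  attr(model, "meta") <- obj$meta
  model
}
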