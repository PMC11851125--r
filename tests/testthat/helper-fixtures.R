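# Shared fixtures and independent oracles, built in code at test time.

BASES5 <- c("A", "C", "G", "T")

# A small encoder configuration that keeps forward/backward passes fast while
# exercising every code path (two full-rate and two half-rate blocks, taps,
# masking).
tiny_test_config <- function(...) {
  encoder_config("tiny", model_width = 16L, heads = 2L, ff_expansion = 2L,
                 conv_kernel = 3L, dropout = 0,
                 conv_specs = list(c(5L, 1L, 1L, 4L), c(5L, 1L, 1L, 8L),
                                   c(19L, 10L, 1L, 16L)), ...)
}

# Random log-posteriorgram over (A,C,G,T,blank): Dirichlet-ish rows via
# normalized exponentials of Gaussians.
random_posteriorgram <- function(T_, seed, scale = 1.5) {
  withr::with_seed(seed, {
    logits <- matrix(rnorm(T_ * 5, sd = scale), T_, 5)
    logits - apply(logits, 1L, function(r) {
      m <- max(r); m + log(sum(exp(r - m)))
    })
  })
}

# Independent CTC oracle: enumerate every frame-level path, collapse it
# (remove repeats, then blanks), and log-sum-exp the masses of paths that
# collapse to the label. Path tables are cached per T since they do not
# depend on the posteriorgram.
.path_cache <- new.env(parent = emptyenv())
.ctc_paths <- function(T_) {
  key <- as.character(T_)
  if (!is.null(.path_cache[[key]])) return(.path_cache[[key]])
  paths <- as.matrix(do.call(expand.grid, rep(list(1:5), T_)))
  collapsed <- apply(paths, 1L, function(p) {
    v <- rle(p)$values
    paste0(BASES5[v[v != 5L]], collapse = "")
  })
  out <- list(paths = paths, collapsed = collapsed)
  .path_cache[[key]] <- out
  out
}

ctc_oracle_loss <- function(post, label) {
  pc <- .ctc_paths(nrow(post))
  lp <- rowSums(vapply(seq_len(nrow(post)),
                       function(t) post[t, pc$paths[, t]],
                       numeric(nrow(pc$paths))))
  sel <- lp[pc$collapsed == label]
  if (length(sel) == 0L) return(Inf)
  m <- max(sel)
  -(m + log(sum(exp(sel - m))))
}

# Exhaustive argmax of P_CTC over all labels, from the same path table:
# group path masses by collapsed label, pick the best under the project
# tie-breaking (score desc, then shorter, then lexicographic).
ctc_oracle_best <- function(post) {
  pc <- .ctc_paths(nrow(post))
  lp <- rowSums(vapply(seq_len(nrow(post)),
                       function(t) post[t, pc$paths[, t]],
                       numeric(nrow(pc$paths))))
  scores <- vapply(split(lp, pc$collapsed), function(x) {
    m <- max(x); m + log(sum(exp(x - m)))
  }, 0)
  labs <- names(scores)
  ord <- order(-scores, nchar(labs), labs, method = "radix")
  list(sequence = labs[ord[1L]], score = unname(scores[ord[1L]]))
}

# Central-difference gradient of a scalar loss w.r.t. logits.
fd_grad_logits <- function(loss_fn, logits, eps = 1e-5) {
  g <- matrix(0, nrow(logits), ncol(logits))
  for (i in seq_along(logits)) {
    up <- logits; up[i] <- up[i] + eps
    dn <- logits; dn[i] <- dn[i] - eps
    g[i] <- (loss_fn(up) - loss_fn(dn)) / (2 * eps)
  }
  g
}

log_softmax_rows <- function(logits) {
  logits - apply(logits, 1L, function(r) { m <- max(r); m + log(sum(exp(r - m))) })
}

max_rel_err <- function(a, b) {
  max(abs(a - b) / pmax(abs(a) + abs(b), 1e-8))
}
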