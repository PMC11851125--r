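# CTC decoding. All scores are carried in log space; probability-space
# arithmetic would underflow at full chunk length. Tie-breaking is fixed
# project-wide: higher total mass first, then shorter prefix, then
# lexicographic order, so decoding is exactly reproducible.

.order_prefixes <- function(score, prefix) {
  order(-score, nchar(prefix), prefix, method = "radix")
}

#' Greedy CTC decode
#'
#' Per-frame argmax, collapse consecutive repeats, drop blanks.
#'
#' @param post T x 5 matrix of log-probabilities (blank last).
#' @return DNA string.
#' @export
greedy_decode <- function(post) {
  if (nrow(post) == 0L) return("")
  cls <- max.col(post, ties.method = "first")
  r <- rle(cls)$values
  paste0(BASES[r[r != BLANK]], collapse = "")
}

# Group-wise log-sum-exp: combines candidate masses that share a prefix key.
.lse_by <- function(x, f, nlev) {
  m <- rep(-Inf, nlev)
  mx <- tapply(x, f, max)
  m[as.integer(names(mx))] <- mx
  s <- rep(0, nlev)
  sm <- tapply(exp(x - m[f]), f, sum)
  s[as.integer(names(sm))] <- sm
  out <- m + log(s)
  out[!is.finite(m)] <- -Inf
  out
}

#' CTC prefix beam search
#'
#' Standard prefix beam search: each surviving prefix carries separate
#' probability mass for alignment paths ending in blank (`pb`) and paths
#' ending in the prefix's last symbol (`pnb`). At every frame each prefix is
#' extended by every symbol with the blank / repeat-merge bookkeeping, masses
#' of identical prefixes are merged by log-sum-exp, and the top `width`
#' prefixes by total mass survive.
#'
#' @param post T x 5 matrix of log-probabilities (blank last).
#' @param width beam width (default 5).
#' @return List with `sequence` (DNA string) and `score` (the prefix's
#'   accumulated log-probability).
#' @export
beam_search <- function(post, width = 5L) {
  width <- as.integer(width)
  if (width < 1L) stop("width must be >= 1")
  if (nrow(post) == 0L) return(list(sequence = "", score = 0))

  prefixes <- ""
  pb <- 0      # log mass of paths ending in blank
  pnb <- -Inf  # log mass of paths ending in the last symbol
  lastch <- ""

  for (t in seq_len(nrow(post))) {
    lp <- post[t, ]
    tot <- pmax(pb, pnb) + log1p(exp(-abs(pb - pnb)))
    tot[is.infinite(pb) & is.infinite(pnb)] <- -Inf

    # (a) stay on the same prefix via a blank
    k_stay <- prefixes
    pb_stay <- tot + lp[BLANK]
    # (b) stay via repeating the last symbol (merges into the same prefix)
    has_last <- lastch != ""
    k_rep <- prefixes[has_last]
    pnb_rep <- pnb[has_last] + lp[match(lastch[has_last], BASES)]
    # (c) extend by each base
    n <- length(prefixes)
    ext_base <- rep(BASES, each = n)
    k_ext <- paste0(rep(prefixes, times = 4L), ext_base)
    same <- ext_base == rep(lastch, times = 4L)
    pnb_ext <- ifelse(same, rep(pb, times = 4L), rep(tot, times = 4L)) +
      lp[match(ext_base, BASES)]

    keys <- c(k_stay, k_rep, k_ext)
    is_pb <- c(rep(TRUE, length(k_stay)), rep(FALSE, length(k_rep) + length(k_ext)))
    mass <- c(pb_stay, pnb_rep, pnb_ext)
    keep <- is.finite(mass) | is_pb   # always keep the blank-path entries
    keys <- keys[keep]; is_pb <- is_pb[keep]; mass <- mass[keep]

    uk <- unique(keys)
    f <- match(keys, uk)
    new_pb <- .lse_by(ifelse(is_pb, mass, -Inf), f, length(uk))
    new_pnb <- .lse_by(ifelse(is_pb, -Inf, mass), f, length(uk))
    new_tot <- pmax(new_pb, new_pnb) + log1p(exp(-abs(new_pb - new_pnb)))
    new_tot[is.infinite(new_pb) & is.infinite(new_pnb)] <- -Inf

    ord <- .order_prefixes(new_tot, uk)
    keep_n <- seq_len(min(width, length(uk)))
    sel <- ord[keep_n]
    prefixes <- uk[sel]
    pb <- new_pb[sel]
    pnb <- new_pnb[sel]
    lastch <- substring(prefixes, nchar(prefixes), nchar(prefixes))
  }
  tot <- pmax(pb, pnb) + log1p(exp(-abs(pb - pnb)))
  tot[is.infinite(pb) & is.infinite(pnb)] <- -Inf
  best <- .order_prefixes(tot, prefixes)[1L]
  list(sequence = prefixes[best], score = tot[best])
}

#' Exhaustive CTC decode (test oracle)
#'
#' Enumerates every label string of length up to `max_len`, computes its
#' exact CTC log-probability by the forward algorithm, and returns the
#' maximizer under the fixed tie-breaking (score, then length, then
#' lexicographic). Cost grows as 4^max_len; inputs with more than 8 frames
#' are rejected.
#'
#' @param post T x 5 matrix of log-probabilities (T <= 8).
#' @param max_len maximum label length to consider (default T).
#' @return List with `sequence` and `score` (log-probability).
#' @export
exhaustive_best <- function(post, max_len = nrow(post)) {
  T_ <- nrow(post)
  if (T_ > 8L) stop("exhaustive_best is limited to T <= 8 frames")
  cand <- ""
  for (l in seq_len(max_len)) {
    g <- do.call(expand.grid,
                 c(rep(list(BASES), l), list(stringsAsFactors = FALSE)))
    cand <- c(cand,
              apply(g[, rev(seq_len(l)), drop = FALSE], 1L, paste0,
                    collapse = ""))
  }
  scores <- vapply(cand, function(s) {
    cl <- .as_label_classes(s)
    -.ctc_forward_cpp(post, cl, FALSE, FALSE)$loss
  }, 0, USE.NAMES = FALSE)
  best <- .order_prefixes(scores, cand)[1L]
  list(sequence = cand[best], score = scores[best])
}
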