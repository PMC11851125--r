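# Batched encoder path used by the training loop: B equal-length chunks are
# stacked rowwise into one (B*T) x C matrix so that every frame-local layer
# (linear, LayerNorm, activations, GLU, heads) runs as a single BLAS call.
# Only attention, the depthwise convolutions, pooling/upsampling and the mask
# module are segment-aware. Numerically identical to running .encoder_fwd
# chunk by chunk (pinned by tests); it only reduces per-call overhead.

.att_fwd_b <- function(P, nm, x, heads, B, T_) {
  C <- ncol(x)
  dh <- C %/% heads
  lq <- .lin_fwd(P, paste0(nm, ".q"), x)
  lk <- .lin_fwd(P, paste0(nm, ".k"), x)
  lv <- .lin_fwd(P, paste0(nm, ".v"), x)
  O <- matrix(0, nrow(x), C)
  hs <- vector("list", B * heads)
  for (s in seq_len(B)) {
    rows <- (s - 1L) * T_ + seq_len(T_)
    for (h in seq_len(heads)) {
      cols <- (h - 1L) * dh + seq_len(dh)
      Qh <- lq$y[rows, cols, drop = FALSE]
      Kh <- lk$y[rows, cols, drop = FALSE]
      Vh <- lv$y[rows, cols, drop = FALSE]
      A <- .softmax_rows(tcrossprod(Qh, Kh) / sqrt(dh))
      O[rows, cols] <- A %*% Vh
      hs[[(s - 1L) * heads + h]] <- list(A = A, Qh = Qh, Kh = Kh, Vh = Vh)
    }
  }
  lo <- .lin_fwd(P, paste0(nm, ".o"), O)
  list(y = lo$y, lq = lq, lk = lk, lv = lv, lo = lo, hs = hs,
       heads = heads, dh = dh, B = B, T_ = T_)
}

.att_bwd_b <- function(P, nm, cache, dy, G) {
  dO <- .lin_bwd(P, paste0(nm, ".o"), cache$lo, dy, G)
  dh <- cache$dh
  dQ <- matrix(0, nrow(dy), dh * cache$heads)
  dK <- dQ; dV <- dQ
  for (s in seq_len(cache$B)) {
    rows <- (s - 1L) * cache$T_ + seq_len(cache$T_)
    for (h in seq_len(cache$heads)) {
      cols <- (h - 1L) * dh + seq_len(dh)
      st <- cache$hs[[(s - 1L) * cache$heads + h]]
      dOh <- dO[rows, cols, drop = FALSE]
      dA <- tcrossprod(dOh, st$Vh)
      dV[rows, cols] <- crossprod(st$A, dOh)
      dS <- .softmax_bwd_cpp(st$A, dA)
      dQ[rows, cols] <- dS %*% st$Kh / sqrt(dh)
      dK[rows, cols] <- crossprod(dS, st$Qh) / sqrt(dh)
    }
  }
  dx <- .lin_bwd(P, paste0(nm, ".q"), cache$lq, dQ, G)
  dx <- dx + .lin_bwd(P, paste0(nm, ".k"), cache$lk, dK, G)
  dx + .lin_bwd(P, paste0(nm, ".v"), cache$lv, dV, G)
}

.dw_fwd_b <- function(P, nm, x, k, pad, stride, B, T_) {
  y <- .dw_fwd_seg_cpp(x, P[[paste0(nm, ".W")]], P[[paste0(nm, ".b")]],
                       B, T_, pad, stride)
  list(y = y, x = x, k = k, pad = pad, stride = stride, B = B, T_ = T_)
}

.dw_bwd_b <- function(P, nm, cache, dy, G) {
  r <- .dw_bwd_seg_cpp(dy, cache$x, P[[paste0(nm, ".W")]], cache$B,
                       cache$T_, cache$pad, cache$stride)
  .acc(G, paste0(nm, ".W"), r$dW)
  .acc(G, paste0(nm, ".b"), r$db)
  r$dx
}

.convmod_fwd_b <- function(P, nm, x, cfg, B, T_) {
  k <- cfg$conv_kernel
  p1 <- .lin_fwd(P, paste0(nm, ".pw1"), x)
  gl <- .glu_fwd(p1$y)
  dw <- .dw_fwd_b(P, paste0(nm, ".dw"), gl$y, k, (k - 1L) %/% 2L, 1L, B, T_)
  il <- .ln_fwd(P, paste0(nm, ".iln"), dw$y)
  ac <- .silu_fwd(il$y)
  p2 <- .lin_fwd(P, paste0(nm, ".pw2"), ac$y)
  list(y = p2$y, p1 = p1, gl = gl, dw = dw, il = il, ac = ac, p2 = p2)
}

.convmod_bwd_b <- function(P, nm, cache, dy, G) {
  dy <- .lin_bwd(P, paste0(nm, ".pw2"), cache$p2, dy, G)
  dy <- .silu_bwd(cache$ac, dy)
  dy <- .ln_bwd(P, paste0(nm, ".iln"), cache$il, dy, G)
  dy <- .dw_bwd_b(P, paste0(nm, ".dw"), cache$dw, dy, G)
  dy <- .glu_bwd(cache$gl, dy)
  .lin_bwd(P, paste0(nm, ".pw1"), cache$p1, dy, G)
}

.block_fwd_b <- function(P, nm, x, cfg, training, B, T_) {
  dr <- cfg$dropout
  f1 <- .ff_fwd(P, paste0(nm, ".ff1"), x)
  d1 <- .drop_fwd(f1$y, dr, training)
  l1 <- .ln_fwd(P, paste0(nm, ".ff1.ln"), x + 0.5 * d1$y)
  at <- .att_fwd_b(P, paste0(nm, ".att"), l1$y, cfg$heads, B, T_)
  d2 <- .drop_fwd(at$y, dr, training)
  l2 <- .ln_fwd(P, paste0(nm, ".att.ln"), l1$y + d2$y)
  cv <- .convmod_fwd_b(P, paste0(nm, ".cv"), l2$y, cfg, B, T_)
  d3 <- .drop_fwd(cv$y, dr, training)
  l3 <- .ln_fwd(P, paste0(nm, ".cv.ln"), l2$y + d3$y)
  f2 <- .ff_fwd(P, paste0(nm, ".ff2"), l3$y)
  d4 <- .drop_fwd(f2$y, dr, training)
  l4 <- .ln_fwd(P, paste0(nm, ".ff2.ln"), l3$y + 0.5 * d4$y)
  list(y = l4$y, f1 = f1, d1 = d1, l1 = l1, at = at, d2 = d2, l2 = l2,
       cv = cv, d3 = d3, l3 = l3, f2 = f2, d4 = d4, l4 = l4)
}

.block_bwd_b <- function(P, nm, cache, dy, G, cfg) {
  d <- .ln_bwd(P, paste0(nm, ".ff2.ln"), cache$l4, dy, G)
  df <- .ff_bwd(P, paste0(nm, ".ff2"),
                cache$f2, 0.5 * .drop_bwd(cache$d4, d), G)
  d <- .ln_bwd(P, paste0(nm, ".cv.ln"), cache$l3, d + df, G)
  dc <- .convmod_bwd_b(P, paste0(nm, ".cv"),
                       cache$cv, .drop_bwd(cache$d3, d), G)
  d <- .ln_bwd(P, paste0(nm, ".att.ln"), cache$l2, d + dc, G)
  da <- .att_bwd_b(P, paste0(nm, ".att"),
                   cache$at, .drop_bwd(cache$d2, d), G)
  d <- .ln_bwd(P, paste0(nm, ".ff1.ln"), cache$l1, d + da, G)
  df1 <- .ff_bwd(P, paste0(nm, ".ff1"),
                 cache$f1, 0.5 * .drop_bwd(cache$d1, d), G)
  d + df1
}

# Forward over a batch of equal-length signal chunks. Returns per-chunk
# posteriorgrams plus the stacked caches for .encoder_bwd_batch.
.encoder_fwd_batch <- function(model, signals, training = FALSE) {
  P <- model$params; cfg <- model$config
  B <- length(signals)
  cf <- lapply(signals, function(s) .convfront_fwd(P, cfg, s, keep = TRUE))
  T_ <- nrow(cf[[1L]]$y)
  mk <- lapply(cf, function(f)
    apply_time_mask(model, f$y, training = training))
  x <- do.call(rbind, lapply(mk, `[[`, "frames"))
  N <- cfg$n_half
  if (cfg$positional_encoding)
    x <- x + .posenc(T_, ncol(x))[rep(seq_len(T_), B), , drop = FALSE]

  blocks <- vector("list", 2L * N)
  for (b in seq_len(N - 1L)) {
    bc <- .block_fwd_b(P, paste0("b", b), x, cfg, training, B, T_)
    x <- bc$y
    blocks[[b]] <- bc
  }
  x_pre <- x
  pl <- .dw_fwd_b(P, "pool", x, 3L, 1L, 2L, B, T_)
  x <- pl$y
  Th <- nrow(x) %/% B
  tap_half <- NULL
  for (b in N:(2L * N - 1L)) {
    bc <- .block_fwd_b(P, paste0("b", b), x, cfg, training, B, Th)
    x <- bc$y
    if (b == cfg$tap_blocks[1L] && length(cfg$tap_blocks) == 1L)
      tap_half <- x
    blocks[[b]] <- bc
  }
  idx1 <- .upsample_idx(Th, T_)
  idx <- rep(idx1, B) + rep((seq_len(B) - 1L) * Th, each = T_)
  up <- .lin_fwd(P, "up", x[idx, , drop = FALSE])
  x <- up$y + x_pre
  bc <- .block_fwd_b(P, paste0("b", 2L * N), x, cfg, training, B, T_)
  blocks[[2L * N]] <- bc

  hl <- .lin_fwd(P, "head", bc$y)
  logp_all <- .log_softmax(hl$y)
  tap_nm <- as.character(cfg$tap_blocks[1L])
  tap_full <- tap_half[idx, , drop = FALSE]
  tl <- .lin_fwd(P, paste0("ihead", tap_nm), tap_full)
  tap_logp_all <- .log_softmax(tl$y)

  per_chunk <- lapply(seq_len(B), function(s) {
    rows <- (s - 1L) * T_ + seq_len(T_)
    list(logp = logp_all[rows, , drop = FALSE],
         tap_logp = setNames(list(tap_logp_all[rows, , drop = FALSE]),
                             tap_nm))
  })
  list(per_chunk = per_chunk, B = B, T_ = T_, Th = Th,
       cache = list(cf = cf, mk = mk, blocks = blocks, pool = pl, up = up,
                    idx = idx, hl = hl, tl = tl, tap_nm = tap_nm))
}

# d_logits / d_tap_logits: per-chunk lists of gradients w.r.t. head logits.
.encoder_bwd_batch <- function(model, fwd, d_logits, d_tap_logits) {
  P <- model$params; cfg <- model$config
  ca <- fwd$cache
  B <- fwd$B; T_ <- fwd$T_
  N <- cfg$n_half
  G <- new.env(parent = emptyenv())
  d <- .lin_bwd(P, "head", ca$hl, do.call(rbind, d_logits), G)
  d_tap <- .lin_bwd(P, paste0("ihead", ca$tap_nm), ca$tl,
                    do.call(rbind, d_tap_logits), G)
  d <- .block_bwd_b(P, paste0("b", 2L * N), ca$blocks[[2L * N]], d, G, cfg)
  dup <- .lin_bwd(P, "up", ca$up, d, G)
  dhalf <- rowsum(dup, ca$idx)            # collapse nearest-repeat upsampling
  d_tap_half <- rowsum(d_tap, ca$idx)     # tap consumed the upsampled states
  for (b in (2L * N - 1L):N) {
    if (as.character(b) == ca$tap_nm) dhalf <- dhalf + d_tap_half
    dhalf <- .block_bwd_b(P, paste0("b", b), ca$blocks[[b]], dhalf, G, cfg)
  }
  dpre <- d + .dw_bwd_b(P, "pool", ca$pool, dhalf, G)
  if (N > 1L) {
    for (b in (N - 1L):1L)
      dpre <- .block_bwd_b(P, paste0("b", b), ca$blocks[[b]], dpre, G, cfg)
  }
  for (s in seq_len(B)) {
    rows <- (s - 1L) * T_ + seq_len(T_)
    dframes <- dpre[rows, , drop = FALSE]
    mp <- ca$mk[[s]]$mask_positions
    if (length(mp)) {
      .acc(G, "mask.vec", colSums(dframes[mp, , drop = FALSE]))
      dframes[mp, ] <- 0
    }
    .convfront_bwd(P, cfg, ca$cf[[s]]$caches, dframes, G)
  }
  as.list(G)
}
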