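# Neural-network primitives with explicit forward/backward passes.
#
# Hidden states are T x C matrices (rows = frames). Parameters live in a flat
# named list; every layer reads its tensors under a name prefix (`<nm>.W`,
# `<nm>.b`, `<nm>.g`, `<nm>.be`). Backward passes accumulate parameter
# gradients into an environment via `.acc()` and return the input gradient.
# All of this is plain matrix algebra through BLAS; correctness is pinned by
# finite-difference tests.

.acc <- function(G, nm, v) {
  cur <- G[[nm]]
  G[[nm]] <- if (is.null(cur)) v else cur + v
  invisible(NULL)
}

.init_mat <- function(nin, nout) {
  matrix(rnorm(nin * nout, sd = 1 / sqrt(nin)), nin, nout)
}

# ---- linear ----------------------------------------------------------------

.lin_init <- function(P, nm, nin, nout) {
  P[[paste0(nm, ".W")]] <- .init_mat(nin, nout)
  P[[paste0(nm, ".b")]] <- numeric(nout)
  P
}

.lin_fwd <- function(P, nm, x) {
  y <- x %*% P[[paste0(nm, ".W")]]
  y <- y + rep(P[[paste0(nm, ".b")]], each = nrow(y))
  list(y = y, x = x)
}

.lin_bwd <- function(P, nm, cache, dy, G) {
  .acc(G, paste0(nm, ".W"), crossprod(cache$x, dy))
  .acc(G, paste0(nm, ".b"), colSums(dy))
  dy %*% t(P[[paste0(nm, ".W")]])
}

# ---- layer norm (over channels, per frame) ---------------------------------

.ln_init <- function(P, nm, C) {
  P[[paste0(nm, ".g")]] <- rep(1, C)
  P[[paste0(nm, ".be")]] <- numeric(C)
  P
}

.ln_fwd <- function(P, nm, x, eps = 1e-5) {
  .ln_fwd_cpp(x, P[[paste0(nm, ".g")]], P[[paste0(nm, ".be")]], eps)
}

.ln_bwd <- function(P, nm, cache, dy, G) {
  r <- .ln_bwd_cpp(dy, cache$xhat, cache$inv, P[[paste0(nm, ".g")]])
  .acc(G, paste0(nm, ".g"), r$dg)
  .acc(G, paste0(nm, ".be"), r$dbe)
  r$dx
}

# ---- activations -----------------------------------------------------------

.gelu_fwd <- function(x) list(y = .gelu_fwd_cpp(x), x = x)
.gelu_bwd <- function(cache, dy) .gelu_bwd_cpp(dy, cache$x)

.silu_fwd <- function(x) {
  r <- .silu_fwd_cpp(x)
  list(y = r$y, s = r$s, x = x)
}
.silu_bwd <- function(cache, dy) .silu_bwd_cpp(dy, cache$s, cache$x)

# gated linear unit over a T x 2C input: out = a * sigmoid(b)
.glu_fwd <- function(x) {
  C <- ncol(x) %/% 2L
  r <- .glu_fwd_cpp(x)
  list(y = r$y, a = x[, seq_len(C), drop = FALSE], s = r$s)
}
.glu_bwd <- function(cache, dy) .glu_bwd_cpp(dy, cache$a, cache$s)

.drop_fwd <- function(x, p, training) {
  if (!training || p <= 0) return(list(y = x, mask = NULL))
  mask <- matrix((runif(length(x)) >= p) / (1 - p), nrow(x), ncol(x))
  list(y = x * mask, mask = mask)
}
.drop_bwd <- function(cache, dy) if (is.null(cache$mask)) dy else dy * cache$mask

# ---- 1D convolutions (im2col) ----------------------------------------------

.pad_rows <- function(x, pad) {
  if (pad == 0L) return(x)
  z <- matrix(0, pad, ncol(x))
  rbind(z, x, z)
}

.conv_init <- function(P, nm, cin, cout, k) {
  P[[paste0(nm, ".W")]] <- .init_mat(k * cin, cout)
  P[[paste0(nm, ".b")]] <- numeric(cout)
  P
}

.conv_fwd <- function(P, nm, x, k, pad, stride) {
  cin <- ncol(x)
  xp <- .pad_rows(x, pad)
  Lout <- (nrow(x) + 2L * pad - k) %/% stride + 1L
  if (Lout < 1L) stop("input shorter than the convolution receptive field")
  U <- matrix(0, Lout, k * cin)
  for (j in seq_len(k)) {
    rows <- seq.int(j, by = stride, length.out = Lout)
    U[, (j - 1L) * cin + seq_len(cin)] <- xp[rows, , drop = FALSE]
  }
  y <- U %*% P[[paste0(nm, ".W")]]
  y <- y + rep(P[[paste0(nm, ".b")]], each = Lout)
  list(y = y, U = U, k = k, pad = pad, stride = stride,
       Lin = nrow(x), cin = cin)
}

.conv_bwd <- function(P, nm, cache, dy, G) {
  .acc(G, paste0(nm, ".W"), crossprod(cache$U, dy))
  .acc(G, paste0(nm, ".b"), colSums(dy))
  dU <- dy %*% t(P[[paste0(nm, ".W")]])
  Lout <- nrow(dy)
  dxp <- matrix(0, cache$Lin + 2L * cache$pad, cache$cin)
  for (j in seq_len(cache$k)) {
    rows <- seq.int(j, by = cache$stride, length.out = Lout)
    dxp[rows, ] <- dxp[rows, , drop = FALSE] +
      dU[, (j - 1L) * cache$cin + seq_len(cache$cin), drop = FALSE]
  }
  if (cache$pad > 0L)
    dxp <- dxp[cache$pad + seq_len(cache$Lin), , drop = FALSE]
  dxp
}

# depthwise conv: one kernel column per channel, weight k x C
.dw_init <- function(P, nm, C, k) {
  P[[paste0(nm, ".W")]] <- matrix(rnorm(k * C, sd = 1 / sqrt(k)), k, C)
  P[[paste0(nm, ".b")]] <- numeric(C)
  P
}

.dw_fwd <- function(P, nm, x, k, pad, stride) {
  xp <- .pad_rows(x, pad)
  Lout <- (nrow(x) + 2L * pad - k) %/% stride + 1L
  y <- .dw_fwd_cpp(xp, P[[paste0(nm, ".W")]], P[[paste0(nm, ".b")]],
                   Lout, stride)
  list(y = y, xp = xp, k = k, pad = pad, stride = stride,
       Lin = nrow(x), Lout = Lout)
}

.dw_bwd <- function(P, nm, cache, dy, G) {
  r <- .dw_bwd_cpp(dy, cache$xp, P[[paste0(nm, ".W")]], cache$stride)
  .acc(G, paste0(nm, ".W"), r$dW)
  .acc(G, paste0(nm, ".b"), r$db)
  dxp <- r$dxp
  if (cache$pad > 0L)
    dxp <- dxp[cache$pad + seq_len(cache$Lin), , drop = FALSE]
  dxp
}

# ---- multi-head self-attention ---------------------------------------------

.row_max <- function(x) {
  m <- x[, 1L]
  for (j in seq_len(ncol(x))[-1L]) m <- pmax(m, x[, j])
  m
}

.softmax_rows <- function(x) .softmax_rows_cpp(x)

.att_init <- function(P, nm, C) {
  for (s in c("q", "k", "v", "o")) P <- .lin_init(P, paste0(nm, ".", s), C, C)
  P
}

.att_fwd <- function(P, nm, x, heads) {
  C <- ncol(x)
  dh <- C %/% heads
  lq <- .lin_fwd(P, paste0(nm, ".q"), x)
  lk <- .lin_fwd(P, paste0(nm, ".k"), x)
  lv <- .lin_fwd(P, paste0(nm, ".v"), x)
  O <- matrix(0, nrow(x), C)
  hs <- vector("list", heads)
  for (h in seq_len(heads)) {
    cols <- (h - 1L) * dh + seq_len(dh)
    Qh <- lq$y[, cols, drop = FALSE]
    Kh <- lk$y[, cols, drop = FALSE]
    Vh <- lv$y[, cols, drop = FALSE]
    A <- .softmax_rows(tcrossprod(Qh, Kh) / sqrt(dh))
    O[, cols] <- A %*% Vh
    hs[[h]] <- list(A = A, Qh = Qh, Kh = Kh, Vh = Vh)
  }
  lo <- .lin_fwd(P, paste0(nm, ".o"), O)
  list(y = lo$y, lq = lq, lk = lk, lv = lv, lo = lo, hs = hs,
       heads = heads, dh = dh)
}

.att_bwd <- function(P, nm, cache, dy, G) {
  dO <- .lin_bwd(P, paste0(nm, ".o"), cache$lo, dy, G)
  dh <- cache$dh
  T_ <- nrow(dy)
  dQ <- matrix(0, T_, dh * cache$heads)
  dK <- dQ; dV <- dQ
  for (h in seq_len(cache$heads)) {
    cols <- (h - 1L) * dh + seq_len(dh)
    st <- cache$hs[[h]]
    dOh <- dO[, cols, drop = FALSE]
    dA <- tcrossprod(dOh, st$Vh)
    dV[, cols] <- crossprod(st$A, dOh)
    dS <- .softmax_bwd_cpp(st$A, dA)
    dQ[, cols] <- dS %*% st$Kh / sqrt(dh)
    dK[, cols] <- crossprod(dS, st$Qh) / sqrt(dh)
  }
  dx <- .lin_bwd(P, paste0(nm, ".q"), cache$lq, dQ, G)
  dx <- dx + .lin_bwd(P, paste0(nm, ".k"), cache$lk, dK, G)
  dx + .lin_bwd(P, paste0(nm, ".v"), cache$lv, dV, G)
}

# ---- sinusoidal positional encoding ----------------------------------------

.posenc <- function(T_, C) {
  pos <- seq_len(T_) - 1
  i <- seq_len(C %/% 2L) - 1
  ang <- outer(pos, 1 / 10000^(2 * i / C))
  pe <- matrix(0, T_, C)
  pe[, 2 * seq_along(i) - 1] <- sin(ang)
  pe[, 2 * seq_along(i)] <- cos(ang)
  pe
}
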