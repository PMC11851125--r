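#' Encoder configuration
#'
#' Assembles all architecture hyperparameters of the basecalling encoder:
#' the convolution front-end specs, the model width, the number of
#' Squeezeformer blocks (2N), attention heads, feed-forward expansion, the
#' depthwise kernel of the block convolution sublayer, dropout, and the
#' time-step mask parameters.
#'
#' Presets: `"M"` (width 512, 2N = 8 blocks), `"L"` (width 512, 2N = 10),
#' `"tiny"` (width 64, 2N = 4) for desk-scale experiments. Any field can be
#' overridden through `...`.
#'
#' @param preset one of `"tiny"`, `"M"`, `"L"`.
#' @param ... named overrides for any configuration field.
#' @return An object of class `encoder_config`.
#' @examples
#' cfg <- encoder_config("tiny")
#' cfg$n_half      # N = 2, so 4 blocks
#' @export
encoder_config <- function(preset = c("tiny", "M", "L"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    tiny = list(model_width = 64L, n_half = 2L, heads = 4L, conv_kernel = 7L),
    M    = list(model_width = 512L, n_half = 4L, heads = 8L, conv_kernel = 31L),
    L    = list(model_width = 512L, n_half = 5L, heads = 8L, conv_kernel = 31L))
  cfg <- c(base, list(
    preset = preset,
    ff_expansion = 4L,
    dropout = if (preset == "tiny") 0 else 0.1,
    blank_bias = 1.5,
    mask_time_prob = 0.05,
    mask_time_length = 5L,
    positional_encoding = TRUE,
    n_classes = N_CLASSES,
    tap_blocks = NULL,   # defaults to block N
    conv_specs = NULL))
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  if (is.null(cfg$conv_specs))
    cfg$conv_specs <- default_conv_specs(cfg$model_width)
  if (is.null(cfg$tap_blocks)) cfg$tap_blocks <- cfg$n_half
  cfg$model_width <- as.integer(cfg$model_width)
  cfg$n_half <- as.integer(cfg$n_half)
  last_out <- cfg$conv_specs[[length(cfg$conv_specs)]][4]
  if (last_out != cfg$model_width)
    stop("last conv layer out_channels (", last_out,
         ") must equal model_width (", cfg$model_width, ")")
  if (cfg$model_width %% cfg$heads != 0L)
    stop("heads must divide model_width")
  if (cfg$mask_time_prob < 0 || cfg$mask_time_prob > 1)
    stop("mask_time_prob must be in [0, 1]")
  if (cfg$mask_time_length < 1L) stop("mask_time_length must be >= 1")
  if (cfg$conv_kernel %% 2L != 1L) stop("conv_kernel must be odd")
  if (any(cfg$tap_blocks < 1L | cfg$tap_blocks > 2L * cfg$n_half))
    stop("tap_blocks must lie in [1, 2N]")
  structure(cfg, class = "encoder_config")
}

#' @export
print.encoder_config <- function(x, ...) {
  cat(sprintf(paste0(
    "encoder_config '%s': width %d, 2N = %d blocks, %d heads, ",
    "mask %.2g/%d\n"), x$preset, x$model_width, 2L * x$n_half, x$heads,
    x$mask_time_prob, x$mask_time_length))
  invisible(x)
}

# ---- parameter construction ------------------------------------------------

.block_init <- function(P, nm, cfg) {
  C <- cfg$model_width
  fC <- C * cfg$ff_expansion
  for (ff in c("ff1", "ff2")) {
    P <- .lin_init(P, paste0(nm, ".", ff, ".in"), C, fC)
    P <- .lin_init(P, paste0(nm, ".", ff, ".out"), fC, C)
    P <- .ln_init(P, paste0(nm, ".", ff, ".ln"), C)
  }
  P <- .att_init(P, paste0(nm, ".att"), C)
  P <- .ln_init(P, paste0(nm, ".att.ln"), C)
  P <- .lin_init(P, paste0(nm, ".cv.pw1"), C, 2L * C)
  P <- .dw_init(P, paste0(nm, ".cv.dw"), C, cfg$conv_kernel)
  P <- .ln_init(P, paste0(nm, ".cv.iln"), C)
  P <- .lin_init(P, paste0(nm, ".cv.pw2"), C, C)
  P <- .ln_init(P, paste0(nm, ".cv.ln"), C)
  P
}

#' Build a basecaller model
#'
#' Instantiates all trainable parameters of the encoder for a given
#' configuration. Initialization is seeded and deterministic: weight matrices
#' are Gaussian with sd 1/sqrt(fan-in), LayerNorm gains start at 1, and the
#' learned mask vector is uniform on `[0, 1)`.
#'
#' @param config an [encoder_config()].
#' @param seed integer seed for initialization.
#' @return An object of class `squeezecall_model` (config + named parameter
#'   list).
#' @export
build_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "encoder_config"))
  C <- config$model_width
  P <- withr::with_seed(as.integer(seed), {
    P <- list()
    cin <- 1L
    for (i in seq_along(config$conv_specs)) {
      cs <- config$conv_specs[[i]]
      P <- .conv_init(P, paste0("cf", i), cin, cs[4], cs[1])
      P <- .ln_init(P, paste0("cf", i, ".ln"), cs[4])
      cin <- cs[4]
    }
    P[["mask.vec"]] <- runif(C)
    for (b in seq_len(2L * config$n_half))
      P <- .block_init(P, paste0("b", b), config)
    P <- .dw_init(P, "pool", C, 3L)
    P <- .lin_init(P, "up", C, C)
    P <- .lin_init(P, "head", C, config$n_classes)
    # class-prior warm start: CTC output is blank-dominant (one emission per
    # base over many frames), so the blank logit starts elevated
    P[["head.b"]][config$n_classes] <- config$blank_bias
    for (tb in config$tap_blocks) {
      P <- .lin_init(P, paste0("ihead", tb), C, config$n_classes)
      P[[paste0("ihead", tb, ".b")]][config$n_classes] <- config$blank_bias
    }
    P
  })
  structure(list(config = config, params = P), class = "squeezecall_model")
}

#' @export
print.squeezecall_model <- function(x, ...) {
  cat(sprintf("squeezecall_model (%s): %s parameters\n", x$config$preset,
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Count trainable parameters
#'
#' @param x a `squeezecall_model` or an `encoder_config` (which is then
#'   instantiated with a fixed seed; the count does not depend on the seed).
#' @return Integer parameter count.
#' @export
count_parameters <- function(x) {
  if (inherits(x, "encoder_config")) x <- build_model(x, seed = 0L)
  stopifnot(inherits(x, "squeezecall_model"))
  sum(vapply(x$params, length, 0L))
}

# ---- convolution front-end -------------------------------------------------

.convfront_fwd <- function(P, cfg, signal, keep = FALSE) {
  x <- matrix(as.numeric(signal), ncol = 1L)
  caches <- if (keep) vector("list", length(cfg$conv_specs)) else NULL
  for (i in seq_along(cfg$conv_specs)) {
    cs <- cfg$conv_specs[[i]]
    cv <- .conv_fwd(P, paste0("cf", i), x, cs[1], cs[2], cs[3])
    ln <- .ln_fwd(P, paste0("cf", i, ".ln"), cv$y)
    ge <- .gelu_fwd(ln$y)
    x <- ge$y
    if (keep) caches[[i]] <- list(cv = cv, ln = ln, ge = ge)
  }
  list(y = x, caches = caches)
}

.convfront_bwd <- function(P, cfg, caches, dy, G) {
  for (i in rev(seq_along(cfg$conv_specs))) {
    ca <- caches[[i]]
    dy <- .gelu_bwd(ca$ge, dy)
    dy <- .ln_bwd(P, paste0("cf", i, ".ln"), ca$ln, dy, G)
    dy <- .conv_bwd(P, paste0("cf", i), ca$cv, dy, G)
  }
  dy
}

#' Run the convolution front-end
#'
#' Applies the three printed convolution layers (each followed by LayerNorm
#' and GELU) to one signal chunk, producing the encoder's input frames. With
#' the default kernels/paddings/strides a 3,600-sample chunk yields 3,598
#' frames (each layer with kernel 5, padding 1 shaves one frame per side; the
#' kernel-19/padding-10 layer adds one back).
#'
#' @param model a `squeezecall_model`.
#' @param signal numeric vector (one chunk), at least 25 samples.
#' @return A T x width matrix of feature frames.
#' @export
conv_forward <- function(model, signal) {
  if (length(signal) < 25L)
    stop("chunk shorter than the convolution receptive field (25 samples)")
  .convfront_fwd(model$params, model$config, signal)$y
}

# ---- time-step masking -----------------------------------------------------

#' Apply wav2vec-style time-step masking
#'
#' During training, `round(mask_time_prob * T)` start frames are sampled
#' uniformly without replacement and each start masks the following
#' `mask_time_length` consecutive frames (clipped at T). All masked frames are
#' replaced by the single learned mask vector. Outside training this is the
#' identity.
#'
#' @param model a `squeezecall_model`.
#' @param frames T x width feature matrix from [conv_forward()].
#' @param seed optional integer seed; when NULL the current RNG stream is used.
#' @param training logical; masking only happens when TRUE.
#' @return List with `frames` (same shape) and `mask_positions` (sorted
#'   integer vector, empty when not training).
#' @export
apply_time_mask <- function(model, frames, seed = NULL, training = FALSE) {
  cfg <- model$config
  T_ <- nrow(frames)
  if (T_ == 0L) stop("frames must be nonempty")
  n_start <- round(cfg$mask_time_prob * T_)
  if (!training || n_start == 0L)
    return(list(frames = frames, mask_positions = integer(0)))
  starts <- if (is.null(seed)) sample.int(T_, n_start)
            else withr::with_seed(as.integer(seed), sample.int(T_, n_start))
  pos <- unique(sort(unlist(lapply(starts, function(s)
    s:min(s + cfg$mask_time_length - 1L, T_)))))
  frames[pos, ] <- rep(model$params[["mask.vec"]], each = length(pos))
  list(frames = frames, mask_positions = pos, starts = sort(starts))
}

# ---- Squeezeformer block (FMCF, post-layer-norm) ---------------------------

.ff_fwd <- function(P, nm, x) {
  l1 <- .lin_fwd(P, paste0(nm, ".in"), x)
  ac <- .silu_fwd(l1$y)
  l2 <- .lin_fwd(P, paste0(nm, ".out"), ac$y)
  list(y = l2$y, l1 = l1, ac = ac, l2 = l2)
}

.ff_bwd <- function(P, nm, cache, dy, G) {
  dy <- .lin_bwd(P, paste0(nm, ".out"), cache$l2, dy, G)
  dy <- .silu_bwd(cache$ac, dy)
  .lin_bwd(P, paste0(nm, ".in"), cache$l1, dy, G)
}

.convmod_fwd <- function(P, nm, x, cfg) {
  k <- cfg$conv_kernel
  p1 <- .lin_fwd(P, paste0(nm, ".pw1"), x)
  gl <- .glu_fwd(p1$y)
  dw <- .dw_fwd(P, paste0(nm, ".dw"), gl$y, k, (k - 1L) %/% 2L, 1L)
  il <- .ln_fwd(P, paste0(nm, ".iln"), dw$y)
  ac <- .silu_fwd(il$y)
  p2 <- .lin_fwd(P, paste0(nm, ".pw2"), ac$y)
  list(y = p2$y, p1 = p1, gl = gl, dw = dw, il = il, ac = ac, p2 = p2)
}

.convmod_bwd <- function(P, nm, cache, dy, G, cfg) {
  dy <- .lin_bwd(P, paste0(nm, ".pw2"), cache$p2, dy, G)
  dy <- .silu_bwd(cache$ac, dy)
  dy <- .ln_bwd(P, paste0(nm, ".iln"), cache$il, dy, G)
  dy <- .dw_bwd(P, paste0(nm, ".dw"), cache$dw, dy, G)
  dy <- .glu_bwd(cache$gl, dy)
  .lin_bwd(P, paste0(nm, ".pw1"), cache$p1, dy, G)
}

# One block in FMCF order; every sublayer is residual with post-LayerNorm and
# the two feed-forwards carry the macaron half-step scale 0.5.
.block_fwd <- function(P, nm, x, cfg, training) {
  dr <- cfg$dropout
  f1 <- .ff_fwd(P, paste0(nm, ".ff1"), x)
  d1 <- .drop_fwd(f1$y, dr, training)
  l1 <- .ln_fwd(P, paste0(nm, ".ff1.ln"), x + 0.5 * d1$y)
  at <- .att_fwd(P, paste0(nm, ".att"), l1$y, cfg$heads)
  d2 <- .drop_fwd(at$y, dr, training)
  l2 <- .ln_fwd(P, paste0(nm, ".att.ln"), l1$y + d2$y)
  cv <- .convmod_fwd(P, paste0(nm, ".cv"), l2$y, cfg)
  d3 <- .drop_fwd(cv$y, dr, training)
  l3 <- .ln_fwd(P, paste0(nm, ".cv.ln"), l2$y + d3$y)
  f2 <- .ff_fwd(P, paste0(nm, ".ff2"), l3$y)
  d4 <- .drop_fwd(f2$y, dr, training)
  l4 <- .ln_fwd(P, paste0(nm, ".ff2.ln"), l3$y + 0.5 * d4$y)
  list(y = l4$y, f1 = f1, d1 = d1, l1 = l1, at = at, d2 = d2, l2 = l2,
       cv = cv, d3 = d3, l3 = l3, f2 = f2, d4 = d4, l4 = l4)
}

.block_bwd <- function(P, nm, cache, dy, G, cfg) {
  d <- .ln_bwd(P, paste0(nm, ".ff2.ln"), cache$l4, dy, G)
  df <- .ff_bwd(P, paste0(nm, ".ff2"),
                cache$f2, 0.5 * .drop_bwd(cache$d4, d), G)
  d <- .ln_bwd(P, paste0(nm, ".cv.ln"), cache$l3, d + df, G)
  dc <- .convmod_bwd(P, paste0(nm, ".cv"),
                     cache$cv, .drop_bwd(cache$d3, d), G, cfg)
  d <- .ln_bwd(P, paste0(nm, ".att.ln"), cache$l2, d + dc, G)
  da <- .att_bwd(P, paste0(nm, ".att"),
                 cache$at, .drop_bwd(cache$d2, d), G)
  d <- .ln_bwd(P, paste0(nm, ".ff1.ln"), cache$l1, d + da, G)
  df1 <- .ff_bwd(P, paste0(nm, ".ff1"),
                 cache$f1, 0.5 * .drop_bwd(cache$d1, d), G)
  d + df1
}

# ---- temporal U-Net --------------------------------------------------------

.upsample_idx <- function(half_len, full_len) {
  rep(seq_len(half_len), each = 2L)[seq_len(full_len)]
}

.unet_fwd <- function(P, cfg, x, training = FALSE, keep = FALSE) {
  N <- cfg$n_half
  T_full <- nrow(x)
  if (cfg$positional_encoding) x <- x + .posenc(T_full, ncol(x))
  blocks <- vector("list", 2L * N)
  taps <- list()
  for (b in seq_len(N - 1L)) {
    bc <- .block_fwd(P, paste0("b", b), x, cfg, training)
    x <- bc$y
    if (b %in% cfg$tap_blocks) taps[[as.character(b)]] <- x
    blocks[[b]] <- if (keep) bc else NULL
  }
  x_pre <- x
  pl <- .dw_fwd(P, "pool", x, 3L, 1L, 2L)
  x <- pl$y
  half_len <- nrow(x)
  for (b in N:(2L * N - 1L)) {
    bc <- .block_fwd(P, paste0("b", b), x, cfg, training)
    x <- bc$y
    if (b %in% cfg$tap_blocks)
      taps[[as.character(b)]] <- x[.upsample_idx(half_len, T_full), , drop = FALSE]
    blocks[[b]] <- if (keep) bc else NULL
  }
  idx <- .upsample_idx(half_len, T_full)
  up <- .lin_fwd(P, "up", x[idx, , drop = FALSE])
  x <- up$y + x_pre
  bc <- .block_fwd(P, paste0("b", 2L * N), x, cfg, training)
  if ((2L * N) %in% cfg$tap_blocks) taps[[as.character(2L * N)]] <- bc$y
  blocks[[2L * N]] <- if (keep) bc else NULL
  list(y = bc$y, taps = taps, half_len = half_len, T_full = T_full,
       blocks = blocks, pool = if (keep) pl else NULL,
       up = if (keep) up else NULL, idx = idx)
}

# d_taps: named list (block index as name) of gradients w.r.t. the tapped
# (already upsampled, for half-rate taps) states.
.unet_bwd <- function(P, cfg, cache, dy, G, d_taps = list()) {
  N <- cfg$n_half
  add_tap <- function(b, d, upsampled) {
    dt <- d_taps[[as.character(b)]]
    if (is.null(dt)) return(d)
    if (upsampled) dt <- rowsum(dt, cache$idx)
    d + dt
  }
  d <- .block_bwd(P, paste0("b", 2L * N), cache$blocks[[2L * N]], dy, G, cfg)
  # d is the gradient at (up projection + residual)
  dup <- .lin_bwd(P, "up", cache$up, d, G)
  dhalf <- rowsum(dup, cache$idx)          # collapse nearest-repeat upsampling
  for (b in (2L * N - 1L):N) {
    dhalf <- add_tap(b, dhalf, upsampled = TRUE)
    dhalf <- .block_bwd(P, paste0("b", b), cache$blocks[[b]], dhalf, G, cfg)
  }
  dpre <- d + .dw_bwd(P, "pool", cache$pool, dhalf, G)
  if (N > 1L) {
    for (b in (N - 1L):1L) {
      dpre <- add_tap(b, dpre, upsampled = FALSE)
      dpre <- .block_bwd(P, paste0("b", b), cache$blocks[[b]], dpre, G, cfg)
    }
  }
  dpre
}

#' Run the temporal U-Net
#'
#' Blocks 1..N-1 run at the full frame rate; a stride-2 depthwise pooling
#' layer halves the rate; blocks N..2N-1 run at half rate; a light upsampling
#' (nearest-neighbor repeat + pointwise projection) restores the full rate,
#' a residual connection adds the pre-pooling states, and the final block
#' runs at full rate. Tapped block outputs (default: block N) are recorded,
#' upsampled to the full length for intermediate-loss computation.
#'
#' @param model a `squeezecall_model`.
#' @param frames T x width matrix (T >= 2).
#' @return List with `final_states` (T x width), `intermediate_states`
#'   (named list of T x width matrices), and `half_len` (= ceil(T/2)).
#' @export
unet_forward <- function(model, frames) {
  if (nrow(frames) < 2L) stop("need at least 2 frames")
  un <- .unet_fwd(model$params, model$config, frames)
  list(final_states = un$y, intermediate_states = un$taps,
       half_len = un$half_len)
}

# ---- output head -----------------------------------------------------------

.log_softmax <- function(logits) {
  out <- .log_softmax_cpp(logits)
  colnames(out) <- c(BASES, "-")
  out
}

#' Map encoder states to a posteriorgram
#'
#' Per-frame affine map to 5 logits followed by log-softmax; class order is
#' (A, C, G, T, blank) with the blank last.
#'
#' @param model a `squeezecall_model`.
#' @param states T x width matrix of encoder states.
#' @param head `"final"` or the integer index of a tapped block.
#' @return T x 5 matrix of log-probabilities (a posteriorgram).
#' @export
head_logprobs <- function(model, states, head = "final") {
  nm <- if (identical(head, "final")) "head" else paste0("ihead", head)
  if (is.null(model$params[[paste0(nm, ".W")]]))
    stop("no such head: ", head)
  .log_softmax(.lin_fwd(model$params, nm, states)$y)
}

# ---- full encoder ----------------------------------------------------------

# Forward through conv front-end, mask module, U-Net and all heads.
# Returns log-posteriorgrams plus (optionally) every cache needed by
# .encoder_bwd.
.encoder_fwd <- function(model, signal, training = FALSE, keep = FALSE,
                         mask_seed = NULL) {
  P <- model$params; cfg <- model$config
  cf <- .convfront_fwd(P, cfg, signal, keep = keep)
  mk <- apply_time_mask(model, cf$y, seed = mask_seed, training = training)
  un <- .unet_fwd(P, cfg, mk$frames, training = training, keep = keep)
  hl <- .lin_fwd(P, "head", un$y)
  logp <- .log_softmax(hl$y)
  tap_logits <- lapply(names(un$taps), function(b)
    .lin_fwd(P, paste0("ihead", b), un$taps[[b]]))
  names(tap_logits) <- names(un$taps)
  tap_logp <- lapply(tap_logits, function(l) .log_softmax(l$y))
  list(logp = logp, tap_logp = tap_logp, final_states = un$y,
       mask_positions = mk$mask_positions,
       cache = if (keep) list(cf = cf, mask_positions = mk$mask_positions,
                              un = un, hl = hl, tap_logits = tap_logits)
               else NULL)
}

# d_logits / d_tap_logits are gradients w.r.t. the (pre-log-softmax) logits of
# the final and tapped heads. Returns the named gradient list.
.encoder_bwd <- function(model, fwd, d_logits, d_tap_logits = list()) {
  P <- model$params; cfg <- model$config
  ca <- fwd$cache
  G <- new.env(parent = emptyenv())
  dstates <- .lin_bwd(P, "head", ca$hl, d_logits, G)
  d_taps <- list()
  for (b in names(d_tap_logits)) {
    d_taps[[b]] <- .lin_bwd(P, paste0("ihead", b), ca$tap_logits[[b]],
                            d_tap_logits[[b]], G)
  }
  dframes <- .unet_bwd(P, cfg, ca$un, dstates, G, d_taps)
  if (length(ca$mask_positions)) {
    .acc(G, "mask.vec",
         colSums(dframes[ca$mask_positions, , drop = FALSE]))
    dframes[ca$mask_positions, ] <- 0
  }
  .convfront_bwd(P, cfg, ca$cf$caches, dframes, G)
  as.list(G)
}
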