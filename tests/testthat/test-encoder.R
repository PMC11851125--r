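cfg <- tiny_test_config()
model <- build_model(cfg, seed = 3)

test_that("conv front-end follows the printed length arithmetic", {
  # layer-by-layer: L' = floor((L + 2p - k)/s) + 1 for kernels 5/5/19,
  # paddings 1/1/10, strides 1: 3600 -> 3598 -> 3596 -> 3598
  specs <- default_conv_specs(512L)
  expect_identical(squeezecall:::.conv_out_len(3600L, specs), 3598L)
  expect_identical(squeezecall:::.conv_out_len(7200L, specs), 7198L)
  fr <- conv_forward(model, rnorm(360))
  expect_identical(dim(fr), c(358L, 16L))
  expect_error(conv_forward(model, rnorm(10)), "receptive field")
})

test_that("eval-mode encoder forward is deterministic", {
  sig <- rnorm(120)
  f1 <- squeezecall:::.encoder_fwd(model, sig)
  set.seed(99)  # the global RNG must not influence eval mode
  f2 <- squeezecall:::.encoder_fwd(model, sig)
  expect_identical(f1$logp, f2$logp)
  expect_identical(f1$mask_positions, integer(0))
})

test_that("time masking hits round(prob*T) starts and preserves shape", {
  frames <- matrix(rnorm(200 * cfg$model_width), 200)
  mk <- apply_time_mask(model, frames, seed = 5, training = TRUE)
  expect_identical(dim(mk$frames), dim(frames))
  expect_length(mk$starts, round(cfg$mask_time_prob * 200))
  expect_lte(length(mk$mask_positions),
             length(mk$starts) * cfg$mask_time_length)
  # every masked frame equals the learned mask vector
  for (p in mk$mask_positions)
    expect_identical(unname(mk$frames[p, ]), unname(model$params$mask.vec))
  # untouched rows unchanged
  keep <- setdiff(seq_len(200), mk$mask_positions)
  expect_identical(mk$frames[keep, ], frames[keep, ])
  # identity outside training or at prob 0
  expect_identical(apply_time_mask(model, frames, training = FALSE)$frames,
                   frames)
  m0 <- build_model(tiny_test_config(mask_time_prob = 0), seed = 3)
  mk0 <- apply_time_mask(m0, frames, seed = 5, training = TRUE)
  expect_identical(mk0$frames, frames)
  expect_length(mk0$mask_positions, 0L)
})

test_that("masked fraction never exceeds prob * span across seeds", {
  frames <- matrix(rnorm(300 * cfg$model_width), 300)
  for (s in 1:100) {
    mk <- apply_time_mask(model, frames, seed = s, training = TRUE)
    expect_lte(length(mk$mask_positions) / 300,
               cfg$mask_time_prob * cfg$mask_time_length)
  }
})

test_that("the U-Net halves the rate mid-network and restores length T", {
  for (T_ in c(37L, 38L)) {
    frames <- matrix(rnorm(T_ * cfg$model_width), T_)
    out <- unet_forward(model, frames)
    expect_identical(out$half_len, as.integer(ceiling(T_ / 2)))
    expect_identical(nrow(out$final_states), T_)
    expect_identical(ncol(out$final_states), cfg$model_width)
    # default tap: block N, upsampled to full length
    expect_identical(names(out$intermediate_states),
                     as.character(cfg$n_half))
    expect_identical(nrow(out$intermediate_states[[1L]]), T_)
  }
})

test_that("with zeroed weights the U-Net reduces to LayerNorm of its input", {
  m0 <- build_model(tiny_test_config(positional_encoding = FALSE), seed = 3)
  for (nm in names(m0$params)) {
    if (grepl("\\.g$", nm)) m0$params[[nm]] <- rep(1, length(m0$params[[nm]]))
    else m0$params[[nm]] <- m0$params[[nm]] * 0
  }
  x <- matrix(rnorm(30 * 16), 30)
  out <- unet_forward(m0, x)
  ln <- squeezecall:::.ln_fwd_cpp(x, rep(1, 16), rep(0, 16), 1e-5)$y
  expect_equal(out$final_states, ln, tolerance = 1e-3)
})

test_that("the head emits normalized log-distributions with blank last", {
  states <- matrix(rnorm(50 * cfg$model_width), 50)
  lp <- head_logprobs(model, states)
  expect_identical(dim(lp), c(50L, 5L))
  expect_identical(colnames(lp), c("A", "C", "G", "T", "-"))
  expect_true(all(lp <= 0))
  expect_equal(rowSums(exp(lp)), rep(1, 50), tolerance = 1e-6)
  # zero weights -> uniform log(1/5); shifting logits leaves output unchanged
  m0 <- model
  m0$params$head.W <- m0$params$head.W * 0
  m0$params$head.b <- m0$params$head.b * 0
  expect_equal(unname(head_logprobs(m0, states)),
               matrix(log(1 / 5), 50, 5), tolerance = 1e-12)
  expect_equal(squeezecall:::.log_softmax(states[, 1:5]),
               squeezecall:::.log_softmax(states[, 1:5] + 3.7),
               tolerance = 1e-12)
})

test_that("parameter counts are deterministic and monotone in depth", {
  c1 <- count_parameters(tiny_test_config())
  expect_identical(c1, count_parameters(tiny_test_config()))
  c2 <- count_parameters(tiny_test_config(n_half = 3L))
  expect_gt(c2, c1)
  # the L geometry (10 blocks) outweighs M (8 blocks) at equal width
  small <- list(c(5L, 1L, 1L, 4L), c(5L, 1L, 1L, 8L), c(19L, 10L, 1L, 32L))
  cm <- count_parameters(encoder_config("M", model_width = 32L, heads = 4L,
                                        conv_specs = small))
  cl <- count_parameters(encoder_config("L", model_width = 32L, heads = 4L,
                                        conv_specs = small))
  expect_gt(cl, cm)
})

test_that("configs validate their invariants", {
  small <- list(c(5L, 1L, 1L, 4L), c(5L, 1L, 1L, 8L), c(19L, 10L, 1L, 16L))
  expect_error(encoder_config("tiny", model_width = 100L, conv_specs = small),
               "out_channels")
  expect_error(encoder_config("tiny", model_width = 16L, heads = 3L,
                              conv_specs = small), "divide")
  expect_error(tiny_test_config(mask_time_prob = 1.5), "mask_time_prob")
  expect_error(tiny_test_config(tap_blocks = 9L), "tap_blocks")
  # width-consistent conv specs are derived automatically from the width
  expect_identical(encoder_config("tiny", model_width = 128L)$conv_specs[[3]][4],
                   128L)
})

test_that("checkpoints restore bit-identical forward passes", {
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(model, path, meta = list(note = "fixture"))
  back <- load_checkpoint(path)
  sig <- rnorm(120)
  expect_identical(squeezecall:::.encoder_fwd(back, sig)$logp,
                   squeezecall:::.encoder_fwd(model, sig)$logp)
  expect_identical(attr(back, "meta")$note, "fixture")
})

test_that("the batched training path reproduces the per-chunk encoder", {
  set.seed(21)
  sigs <- list(rnorm(100), rnorm(100))
  fb <- squeezecall:::.encoder_fwd_batch(model, sigs, training = FALSE)
  for (i in 1:2) {
    f1 <- squeezecall:::.encoder_fwd(model, sigs[[i]])
    expect_equal(fb$per_chunk[[i]]$logp, f1$logp, tolerance = 1e-12)
    expect_equal(fb$per_chunk[[i]]$tap_logp[[1]], f1$tap_logp[[1]],
                 tolerance = 1e-12)
  }
  # batched backward == sum of per-chunk backwards
  dl <- lapply(1:2, function(i) matrix(rnorm(98 * 5, sd = 0.1), 98))
  dt <- lapply(1:2, function(i) matrix(rnorm(98 * 5, sd = 0.1), 98))
  Gb <- squeezecall:::.encoder_bwd_batch(model, fb, dl, dt)
  Gs <- NULL
  for (i in 1:2) {
    f1 <- squeezecall:::.encoder_fwd(model, sigs[[i]], keep = TRUE)
    g <- squeezecall:::.encoder_bwd(model, f1, dl[[i]], setNames(dt[i], "2"))
    Gs <- if (is.null(Gs)) g else {
      for (nm in names(g)) Gs[[nm]] <- Gs[[nm]] + g[[nm]]
      Gs
    }
  }
  for (nm in names(Gb)) expect_equal(Gb[[nm]], Gs[[nm]], tolerance = 1e-10)
})
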