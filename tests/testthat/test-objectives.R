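test_that("label smoothing reproduces the 5-class worked example", {
  expect_identical(label_smooth(2L, 5L, 0.1),
                   c(0.025, 0.9, 0.025, 0.025, 0.025))
  expect_identical(label_smooth(1L, 5L, 0), c(1, 0, 0, 0, 0))
  for (ci in 1:5)
    expect_equal(sum(label_smooth(ci, 5L, 0.1)), 1, tolerance = 1e-12)
  expect_equal(sum(label_smooth(2L, 7L, 0.3)), 1, tolerance = 1e-12)
  expect_error(label_smooth(2L, 5L, 1), "factor")
  expect_error(label_smooth(6L, 5L), "class_index")
})

test_that("single-frame and empty-label CTC losses have closed forms", {
  post <- random_posteriorgram(1L, seed = 1)
  expect_equal(ctc_loss(post, "A"), -post[1, 1])
  post6 <- random_posteriorgram(6L, seed = 2)
  expect_equal(ctc_loss(post6, ""), -sum(post6[, 5]))
})

test_that("ctc_loss equals exhaustive path enumeration on random instances", {
  set.seed(10)
  for (i in 1:60) {
    T_ <- sample(2:6, 1)
    lab_len <- sample(0:3, 1)
    post <- random_posteriorgram(T_, seed = 100 + i)
    label <- if (lab_len == 0) "" else
      paste0(sample(BASES5, lab_len, replace = TRUE), collapse = "")
    ours <- suppressWarnings(ctc_loss(post, label))
    oracle <- ctc_oracle_loss(post, label)
    if (is.finite(oracle)) expect_equal(ours, oracle, tolerance = 1e-6)
    else expect_identical(ours, Inf)
  }
})

test_that("infeasible labels give +Inf with a classed warning", {
  post <- random_posteriorgram(2L, seed = 3)
  expect_warning(l <- ctc_loss(post, "AAA"),
                 class = "squeezecall_ctc_infeasible")
  expect_identical(l, Inf)
  # repeats need a separating blank: "AA" needs 3 frames
  expect_warning(l2 <- ctc_loss(post, "AA"),
                 class = "squeezecall_ctc_infeasible")
  expect_identical(l2, Inf)
})

test_that("total CTC mass dominates the best single alignment", {
  for (i in 1:20) {
    post <- random_posteriorgram(5L, seed = 200 + i)
    label <- paste0(sample(BASES5, 2), collapse = "")
    # best single path mass via enumeration
    pc <- squeezecall:::.as_label_classes(label)
    paths <- as.matrix(do.call(expand.grid, rep(list(1:5), 5)))
    collapse <- apply(paths, 1, function(p) {
      v <- rle(p)$values
      paste0(BASES5[v[v != 5]], collapse = "")
    })
    lp <- rowSums(vapply(1:5, function(t) post[t, paths[, t]],
                         numeric(nrow(paths))))
    best_path <- max(lp[collapse == label])
    expect_lte(ctc_loss(post, label), -best_path + 1e-12)
  }
})

test_that("intermediate CTC averages per-tap losses with private heads", {
  post_a <- random_posteriorgram(6L, seed = 4)
  post_b <- random_posteriorgram(6L, seed = 5)
  taps <- list(`2` = post_a, `4` = post_b)
  expect_equal(intermediate_ctc(taps, "AC", tap_set = "2"),
               ctc_loss(post_a, "AC"))
  expect_equal(intermediate_ctc(list(`2` = post_a, `4` = post_a), "AC"),
               ctc_loss(post_a, "AC"))
  expect_equal(intermediate_ctc(taps, "AC"),
               (ctc_loss(post_a, "AC") + ctc_loss(post_b, "AC")) / 2,
               tolerance = 1e-9)
  expect_error(intermediate_ctc(taps, "AC", tap_set = c("2", "9")), "missing")
  expect_error(intermediate_ctc(taps, "AC", tap_set = character(0)),
               "nonempty")
})

test_that("KL loss is zero at the target, hand-computable at uniform, and
           invariant under frame duplication", {
  q2 <- label_smooth(2L)
  post_q <- matrix(log(q2), 4, 5, byrow = TRUE)
  expect_equal(kl_loss(post_q, rep(2L, 4)), 0, tolerance = 1e-12)

  post_u <- matrix(log(0.2), 3, 5)
  expected <- sum(q2 * log(q2 / 0.2))
  expect_equal(kl_loss(post_u, rep(2L, 3)), expected, tolerance = 1e-12)

  post <- random_posteriorgram(5L, seed = 6)
  fl <- c(1L, 3L, 2L, 5L, 4L)
  expect_equal(kl_loss(post[rep(1:5, 2), ], rep(fl, 2)), kl_loss(post, fl),
               tolerance = 1e-12)
  # NA frames are skipped with the mean renormalized
  expect_equal(kl_loss(post, c(1L, NA, 2L, NA, NA)),
               kl_loss(post[c(1, 3), ], c(1L, 2L)), tolerance = 1e-12)
  expect_error(kl_loss(post, 1:3), "length")
})

test_that("the KL direction is target-first (pinned numerically)", {
  # asymmetric instance where KL(q||p) != KL(p||q)
  p <- c(0.7, 0.1, 0.1, 0.05, 0.05)
  post <- matrix(log(p), 1, 5)
  q <- label_smooth(2L)
  forward_kl <- sum(q * log(q / p))    # target-first: what kl_loss computes
  reverse_kl <- sum(p * log(p / q))
  expect_equal(kl_loss(post, 2L), forward_kl, tolerance = 1e-12)
  expect_gt(abs(forward_kl - reverse_kl), 0.1)
})

test_that("the combined loss is the stated convex combination", {
  post <- random_posteriorgram(8L, seed = 7)
  taps <- list(`2` = random_posteriorgram(8L, seed = 8))
  fl <- rep(c(1L, 2L), 4)
  label <- "AC"
  w <- loss_weights(gamma = 0.3, beta = 0.35)
  got <- combined_loss(post, taps, fl, label, w)
  expect_equal(got$total,
               0.3 * ctc_loss(post, label) +
                 0.35 * intermediate_ctc(taps, label) +
                 0.35 * kl_loss(post, fl),
               tolerance = 1e-9)
  # gamma=1, beta=0 collapses to the plain CTC loss
  g10 <- combined_loss(post, taps, fl, label, loss_weights(1, 0))
  expect_equal(g10$total, ctc_loss(post, label), tolerance = 1e-12)
  expect_error(loss_weights(0.8, 0.3), "gamma")
})

test_that("analytic loss gradients match central finite differences", {
  set.seed(11)
  logits <- matrix(rnorm(6 * 5), 6, 5)
  label <- "AC"
  fl <- c(1L, 1L, NA, 2L, 2L, 5L)

  an <- squeezecall:::.ctc_grad_logits(log_softmax_rows(logits), label)
  fd <- fd_grad_logits(function(lg) ctc_loss(log_softmax_rows(lg), label),
                       logits)
  expect_lt(max_rel_err(an$grad, fd), 1e-4)

  an_kl <- squeezecall:::.kl_grad_logits(log_softmax_rows(logits), fl)
  fd_kl <- fd_grad_logits(function(lg) kl_loss(log_softmax_rows(lg), fl),
                          logits)
  expect_lt(max_rel_err(an_kl$grad, fd_kl), 1e-4)

  tap_logits <- matrix(rnorm(6 * 5), 6, 5)
  w <- loss_weights(0.3, 0.35)
  an_cb <- squeezecall:::.combined_grad_logits(
    log_softmax_rows(logits), list(`2` = log_softmax_rows(tap_logits)),
    fl, label, w)
  fd_cb <- fd_grad_logits(function(lg)
    combined_loss(log_softmax_rows(lg),
                  list(`2` = log_softmax_rows(tap_logits)), fl, label,
                  w)$total, logits)
  expect_lt(max_rel_err(an_cb$d_final, fd_cb), 1e-4)
  fd_tap <- fd_grad_logits(function(lg)
    combined_loss(log_softmax_rows(logits),
                  list(`2` = log_softmax_rows(lg)), fl, label, w)$total,
    tap_logits)
  expect_lt(max_rel_err(an_cb$d_taps[[1]], fd_tap), 1e-4)
})
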