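make_xy <- function(n = 12, p = 5, seed = 1, noise = 0) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("S_", 0:(p - 1))))
  y <- drop(X %*% c(2, -1, rep(0, p - 2))) + 6 + rnorm(n, sd = noise)
  list(X = X, y = y)
}

test_that("PLS recovers an exact one-column relationship", {
  set.seed(2)
  X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("S_0", "S_1")))
  y <- 3 * X[, 1] + 1
  fit <- fit_pls(X[, 1, drop = FALSE], y, 1)
  r2 <- 1 - sum((y - predict(fit, X[, 1, drop = FALSE]))^2) / sum((y - mean(y))^2)
  expect_equal(r2, 1, tolerance = 1e-9)
})

test_that("PLS tolerates duplicated columns and matches OLS at full rank", {
  d <- make_xy(10, 2, seed = 3, noise = 0.2)
  # collinear design: no crash, finite coefficients
  Xdup <- cbind(d$X, S_9 = d$X[, 1])
  fit <- fit_pls(Xdup, d$y, 2)
  expect_true(all(is.finite(fit$coefficients)))

  # 5x2 toy at full rank: predictions equal ordinary least squares
  d <- make_xy(5, 2, seed = 4, noise = 0.3)
  fit <- fit_pls(d$X, d$y, 2)
  ols <- stats::lm(d$y ~ d$X)
  expect_equal(unname(predict(fit, d$X)), unname(fitted(ols)), tolerance = 1e-8)
  expect_error(fit_pls(d$X, rep(1, 5), 2), "zero variance")
})

test_that("LOO q2 equals a brute-force refit oracle to 1e-10", {
  for (seed in 1:3) {
    d <- make_xy(15, 3, seed = seed, noise = 0.4)
    q2 <- q_squared_loo(d$X, d$y, 3)
    # oracle: n independent lm refits (full rank PLS == OLS)
    press <- sum(vapply(seq_along(d$y), function(i) {
      df <- data.frame(y = d$y[-i], d$X[-i, ])
      m <- stats::lm(y ~ ., df)
      (d$y[i] - stats::predict(m, data.frame(d$X)[i, ]))^2
    }, numeric(1)))
    expect_equal(as.numeric(q2), 1 - press / sum((d$y - mean(d$y))^2),
                 tolerance = 1e-10)
  }
  # reduced-rank path agrees with explicit PLS refits
  d <- make_xy(12, 4, seed = 5, noise = 0.3)
  q2 <- q_squared_loo(d$X, d$y, 2)
  press <- sum(vapply(seq_along(d$y), function(i) {
    f <- fit_pls(d$X[-i, ], d$y[-i], 2)
    (d$y[i] - predict(f, d$X[i, , drop = FALSE]))^2
  }, numeric(1)))
  expect_equal(as.numeric(q2), 1 - press / sum((d$y - mean(d$y))^2),
               tolerance = 1e-10)
})

test_that("external pred_r2 follows the test-set-mean convention", {
  m <- qsar_model("S_0", 0, 6.5) # constant model predicting 6.5
  X <- matrix(c(0, 0), 2, 1, dimnames = list(NULL, "S_0"))
  # predictions equal the test mean -> 0
  expect_equal(as.numeric(pred_r_squared(m, X, c(6, 7))), 0)
  # perfect predictions -> 1
  m2 <- qsar_model("S_0", 1, 0)
  X2 <- matrix(c(6, 7), 2, 1, dimnames = list(NULL, "S_0"))
  expect_equal(as.numeric(pred_r_squared(m2, X2, c(6, 7))), 1)
  expect_error(pred_r_squared(m, X, c(7, 7)), "constant")
})

test_that("F statistic arithmetic, including the reported-scale check", {
  expect_equal(f_statistic(0, 20, 3), 0)
  expect_equal(f_statistic(0.5, 12, 1), 10)
  # r2 = 0.6774 with n = 39, k = 1 lands at the magnitude QSAR reports print
  expect_equal(f_statistic(0.6774, 39, 1), 77.69, tolerance = 1e-3)
  expect_error(f_statistic(1, 10, 2), "r2 = 1")
})

test_that("stepwise selection recovers planted descriptors and honours caps", {
  set.seed(6)
  X <- matrix(rnorm(30 * 8), 30, 8, dimnames = list(NULL, paste0("S_", 0:7)))
  y <- 2 * X[, 3] - 3 * X[, 6] + 5 # noiseless two-descriptor signal
  sel <- stepwise_forward_select(X, y, max_terms = 4)
  expect_true(all(c("S_2", "S_5") %in% sel[1:2])) # labels are 0-based
  expect_lte(length(stepwise_forward_select(X, y, max_terms = 3)), 3L)

  # training r2 is non-decreasing along the selection path
  r2_at <- function(k) {
    f <- fit_pls(X[, sel[seq_len(k)], drop = FALSE], y, k)
    1 - sum((y - predict(f, X[, sel[seq_len(k)], drop = FALSE]))^2) /
      sum((y - mean(y))^2)
  }
  r2s <- vapply(seq_along(sel), r2_at, numeric(1))
  expect_true(all(diff(r2s) >= -1e-12))
})

test_that("pure-noise designs yield non-predictive, often truncated models", {
  q2s <- numeric(20); nterms <- integer(20)
  for (seed in 1:20) {
    set.seed(100 + seed)
    X <- matrix(rnorm(15 * 10), 15, 10, dimnames = list(NULL, paste0("S_", 0:9)))
    y <- rnorm(15)
    sel <- stepwise_forward_select(X, y, max_terms = 4)
    nterms[seed] <- length(sel)
    q2s[seed] <- as.numeric(q_squared_loo(X[, sel, drop = FALSE], y,
                                          min(length(sel), 5L)))
  }
  # selection bias inflates a few runs, but the bulk of noise models sit at
  # or near zero predictivity, far below any planted-signal fit (~0.9)
  expect_lt(stats::median(q2s), 0.4)
  expect_lt(mean(q2s), 0.4)
  expect_gte(sum(q2s < 0.3), 10L)
  # selection frequently stops before the term cap on noise
  expect_gte(sum(nterms < 4L), 5L)
})

test_that("prediction is affine and reports missing labels by name", {
  eq <- qsar_model(c("E_1657", "S_1911", "S_1696"),
                   c(2.83451, 2.68845, -3.97667), 2.80171)
  z <- stats::setNames(rep(0, 3), eq$labels)
  expect_identical(predict(eq, z), 2.80171)
  expect_equal(predict(eq, z + 1), 2.83451 + 2.68845 - 3.97667 + 2.80171,
               tolerance = 1e-12)
  # zero-coefficient model returns the intercept for any input
  m0 <- qsar_model(c("a", "b"), c(0, 0), 1.5)
  expect_equal(predict(m0, c(a = 3, b = -9)), 1.5)
  expect_error(predict(eq, c(E_1657 = 1)), "S_1911")
  # affine in the descriptor row
  row <- stats::setNames(c(1, 2, 3), eq$labels)
  for (a in c(0.5, 2, -1))
    expect_equal(predict(eq, a * row) - eq$intercept,
                 a * (predict(eq, row) - eq$intercept), tolerance = 1e-10)
})

test_that("Y-randomization separates planted signal from chance", {
  d <- make_xy(15, 2, seed = 7, noise = 0.2)
  wins <- 0L
  for (s in 1:20) {
    r <- y_randomization(d$X, d$y, 2, n_perm = 10, seed = s)
    if (r$mu < r$h) wins <- wins + 1L
  }
  expect_gte(wins, 19L) # >= 95% of seeded runs
  r <- y_randomization(d$X, d$y, 2, n_perm = 20, seed = 1)
  expect_equal(r$z, (r$h - r$mu) / r$sigma)
  expect_true(r$best_rand_q2 >= max(r$q2_perm) - 1e-12)
})

test_that("contribution percentages are signed shares summing to 100", {
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  m1 <- qsar_model("a", 2, 0)
  expect_equal(unname(contribution_percentages(m1, X[, 1, drop = FALSE])), 100)
  # equal |coef*sd| with opposite signs -> +50 / -50
  X2 <- cbind(a = X[, 1], b = X[, 1])
  m2 <- qsar_model(c("a", "b"), c(1, -1), 0)
  expect_equal(unname(contribution_percentages(m2, X2)), c(50, -50))
  # three-descriptor case against direct arithmetic
  m3 <- qsar_model(c("a", "b", "c"), c(2, -1, 0.5), 0)
  w <- c(2, -1, 0.5) * apply(X, 2, sd)
  expect_equal(unname(contribution_percentages(m3, X)),
               unname(sign(w) * 100 * abs(w) / sum(abs(w))), tolerance = 1e-12)
  expect_equal(sum(abs(contribution_percentages(m3, X))), 100, tolerance = 1e-12)
  expect_error(contribution_percentages(qsar_model("a", 0, 1), X), "zero")
})

test_that("the qsar() fit assembles a coherent validation block", {
  d <- make_xy(24, 6, seed = 8, noise = 0.15)
  fit <- qsar(d$X[1:20, ], d$y[1:20], x_test = d$X[21:24, ],
              y_test = d$y[21:24], n_perm = 15, seed = 1)
  v <- fit$validation
  expect_true(v$r2 <= 1 && v$q2 <= v$r2 + 1e-9)
  expect_true(v$r2_se >= 0 && v$q2_se >= 0 && v$f_stat >= 0)
  expect_equal(sum(abs(v$contribution_pct)), 100, tolerance = 1e-9)
  expect_gt(v$z_score_q2, 2) # strong planted signal
  expect_equal(length(fit$coefficients), length(fit$labels))
  expect_true(fit$n_latent >= 1 && fit$n_latent <= length(fit$labels))
  # model persistence round trip
  f <- withr::local_tempfile(fileext = ".yaml")
  save_qsar(fit, f)
  back <- load_qsar(f)
  expect_equal(back$coefficients, fit$coefficients, tolerance = 1e-9)
  expect_equal(predict(back, d$X[1:3, fit$labels]),
               predict(fit, d$X[1:3, fit$labels]), tolerance = 1e-9)
})
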