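test_that("PLS recovers an exact one-component relationship", {
  set.seed(11)
  t1 <- rnorm(20)
  p1 <- rnorm(8)
  X <- t1 %*% t(p1)      # rank one: a single latent direction
  y <- 2.5 * t1 + 7      # y carried entirely by that direction
  fit <- fit_pls(X, y, 1)
  expect_equal(fit$stats$r2, 1.0, tolerance = 1e-10)
  expect_lt(fit$stats$rss, 1e-10)
})

test_that("PLS guards its preconditions", {
  set.seed(4)
  X <- matrix(rnorm(10 * 5), 10, 5)
  y <- rnorm(10)
  expect_error(fit_pls(X, y, 10), "samples")          # n_components = n
  expect_error(fit_pls(X, rep(1, 10), 2), "variance") # constant y
  X2 <- cbind(rnorm(10))                              # rank 1
  expect_error(fit_pls(cbind(X2, 2 * X2, -X2), rnorm(10), 3), "rank")
})

test_that("random X with permuted y cannot reach a perfect six-component fit", {
  set.seed(42)
  X <- matrix(rnorm(20 * 50), 20, 50)
  y <- sample(rnorm(20))
  fit <- fit_pls(X, y, 6)
  expect_lt(fit$stats$r2, 1)
})

test_that("latent-space and coefficient predictors agree; r2 is reproduced", {
  ser <- get_series(1)
  g <- build_grid(ser$molecules, spacing = 3.0)
  dm <- build_descriptor_matrix(ser$molecules, g, c("S", "H"))
  fit <- fit_pls(dm, n_components = 3)
  # back-projected coefficients reproduce the latent predictor exactly
  Xs <- sweep(sweep(dm$X, 2, fit$x_mean), 2, fit$col_scale, "/")
  R <- fit$W %*% solve(crossprod(fit$P, fit$W))
  y_latent <- drop(Xs %*% R %*% fit$qvec) + fit$y_mean
  y_coef <- predict(fit, dm$X)
  expect_equal(y_coef, y_latent, tolerance = 1e-10)
  # stored r2 is reproduced from the stored coefficients
  r2 <- 1 - sum((fit$y - y_coef)^2) / sum((fit$y - mean(fit$y))^2)
  expect_equal(r2, fit$stats$r2, tolerance = 1e-10)
  # training statistics tie together
  n <- fit$n_train; a <- fit$n_components
  expect_equal(fit$stats$see, sqrt(fit$stats$rss / (n - a - 1)), tolerance = 1e-12)
  expect_equal(fit$stats$f,
               (fit$stats$r2 / a) / ((1 - fit$stats$r2) / (n - a - 1)),
               tolerance = 1e-12)
})

test_that("LOO q2 equals a brute-force n-refit loop to 1e-12", {
  ser <- get_series(3)
  g <- build_grid(ser$molecules, spacing = 3.0)
  dm <- build_descriptor_matrix(ser$molecules[1:14], g, c("S", "H"))
  y <- dm$y

  # plain-matrix path (single block, no scaling)
  cv <- loo_q2(dm$X, y, max_components = 3)
  for (a in 1:3) {
    press <- 0
    for (i in seq_len(14)) {
      f <- fit_pls(dm$X[-i, , drop = FALSE], y[-i], a)
      press <- press + (y[i] - predict(f, dm$X[i, , drop = FALSE]))^2
    }
    q2_oracle <- 1 - press / sum((y - mean(y))^2)
    expect_equal(cv$q2[a], q2_oracle, tolerance = 1e-12)
    expect_equal(cv$sep[a], sqrt(press / (14 - a - 1)), tolerance = 1e-12)
  }

  # descriptor path (two field blocks, per-fold block rescaling)
  cv2 <- loo_q2(dm, max_components = 2)
  for (a in 1:2) {
    press <- 0
    for (i in seq_len(14)) {
      fold <- dm
      fold$X <- dm$X[-i, , drop = FALSE]
      fold$y <- y[-i]
      f <- fit_pls(fold, n_components = a)
      press <- press + (y[i] - predict(f, dm$X[i, , drop = FALSE]))^2
    }
    expect_equal(cv2$q2[a], 1 - press / sum((y - mean(y))^2),
                 tolerance = 1e-12)
  }
})

test_that("q2 never exceeds r2 at matched component counts", {
  ser <- get_series(5)
  g <- build_grid(ser$molecules, spacing = 3.0)
  dm <- build_descriptor_matrix(ser$molecules, g, c("S", "H"))
  cv <- loo_q2(dm, max_components = 4)
  for (a in 1:4) {
    expect_lt(cv$q2[a], fit_pls(dm, n_components = a)$stats$r2 + 1e-12)
  }
})

test_that("noiseless planted data gives near-perfect q2; permuted y does not", {
  ser0 <- generate_series(series_spec(seed = 1, noise_sd = 0))
  g <- build_grid(ser0$molecules, spacing = 2.0)
  dm <- build_descriptor_matrix(ser0$molecules, g, c("S", "H"))
  cv <- loo_q2(dm, max_components = 6)
  expect_gt(cv$q2_onc, 0.9)

  # permutation null: selected-ONC q2 stays low for at least 95% of
  # permutations; 20 draws keep the test fast
  y <- dm$y
  set.seed(99)
  low <- vapply(1:20, function(b) {
    loo_q2(dm$X, sample(y), max_components = 6)$q2_onc <= 0.3
  }, logical(1))
  expect_gte(sum(low), 19)
})

test_that("pure-noise columns cannot buy q2", {
  ser <- get_series(4)
  g <- build_grid(ser$molecules, spacing = 3.0)
  dm <- build_descriptor_matrix(ser$molecules, g, c("S", "H"))
  base <- loo_q2(dm, max_components = 3)$q2_onc
  set.seed(7)
  gains <- vapply(1:20, function(b) {
    Xn <- cbind(dm$X, matrix(rnorm(nrow(dm$X) * 10, sd = mean(abs(dm$X))),
                             nrow(dm$X)))
    loo_q2(Xn, dm$y, max_components = 3)$q2_onc - base
  }, numeric(1))
  expect_lte(max(gains), 0.05)
})

test_that("bootstrap r2 is deterministic under a seed and exact on perfect fits", {
  set.seed(2)
  X <- matrix(rnorm(15 * 6), 15, 6)
  y <- drop(X %*% rnorm(6))  # exactly representable
  bs1 <- bootstrap_r2(X, y, n_components = 6, n_boot = 30, seed = 5)
  bs2 <- bootstrap_r2(X, y, n_components = 6, n_boot = 30, seed = 5)
  expect_identical(bs1$r2, bs2$r2)
  expect_equal(bs1$bs_r2, 1.0, tolerance = 1e-8)
  expect_equal(bs1$bs_sd, 0.0, tolerance = 1e-8)
})

test_that("bootstrap spread shrinks when generator noise is halved", {
  run <- function(noise) {
    ser <- generate_series(series_spec(seed = 6, noise_sd = noise))
    g <- build_grid(ser$molecules, spacing = 3.0)
    dm <- build_descriptor_matrix(ser$molecules, g, c("S", "H"))
    bootstrap_r2(dm, n_components = 3, n_boot = 40, seed = 8)$bs_sd
  }
  expect_lt(run(0.15), run(0.6))
})

test_that("field-combination search enumerates, ranks and recovers", {
  ser <- get_series(1)
  g <- build_grid(ser$molecules, spacing = 2.0)
  dm <- build_descriptor_matrix(ser$molecules, g, c("S", "E", "H", "D", "A"))

  one <- field_combination_search(dm, "S")
  expect_equal(nrow(one), 1)

  all31 <- field_combination_search(dm, c("S", "E", "H", "D", "A"))
  expect_equal(nrow(all31), 31)
  expect_false(is.unsorted(rev(all31$q2), na.rm = TRUE))

  # activity is planted on steric + hydrophobic structure
  top <- strsplit(all31$combination[1], "+", fixed = TRUE)[[1]]
  expect_true("S" %in% top)
})
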