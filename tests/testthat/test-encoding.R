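test_that("the reward spline basis is non-negative, causal and unit-area", {
  basis <- make_spline_basis(5.15)
  expect_length(basis$kernels, 8)
  for (k in basis$kernels) {
    expect_true(all(k$values >= 0))
    expect_equal(sum(k$values) / 5.15, 1, tolerance = 1e-9)
  }
  supports <- vapply(basis$kernels, `[[`, numeric(1), "support_s")
  expect_equal(range(supports), c(0.5, 8))
})

test_that("kernel selection: single kernel, generative-kernel vote, zero lick wave", {
  set.seed(31)
  # session with a fast indicator so the generative reward kernel is
  # identifiable from the regressions
  cfg <- simulation_config(duration_s = 900, n_cells = 24, n_rewards = 10,
                           calcium_tau_s = 0, noise_sd = 0.3, seed = 31)
  basis3 <- make_spline_basis(cfg$cell_rate_hz, n_kernels = 3,
                              support_range_s = c(0.5, 8))
  spec <- data.frame(class = "reward", w_pupil = 0, w_locomotion = 0,
                     w_reward = stats::runif(24, 0.8, 1.2), noise_sd = 0.3)
  s <- simulate_session(cfg, truth_spec = spec, spline_basis = basis3,
                        true_kernel_index = 2)
  dff <- preprocess_cells(s$cells$raw, s$cells$halo)
  tc <- s$cells$time_s
  tr <- extract_pupil_trace(s$landmarks, 0.9)
  base <- build_predictors(tr, s$behavior$time_s, s$behavior$speed_cmps, tc)
  lick_c <- resample_linear(s$behavior$time_s, as.numeric(s$behavior$lick), tc)
  rr <- build_reward_regressor(lick_c, basis3, dff, base)
  expect_equal(rr$kernel_index, 2)
  expect_equal(sum(rr$votes), 24)

  basis1 <- make_spline_basis(cfg$cell_rate_hz, n_kernels = 1)
  expect_equal(build_reward_regressor(lick_c, basis1, dff, base)$kernel_index, 1)

  expect_warning(rz <- build_reward_regressor(rep(0, length(tc)), basis3,
                                              dff, base),
                 "zero variance")
  expect_true(rz$excluded)
})

test_that("OLS identities: pure predictor, exact two-predictor combination", {
  set.seed(8)
  n <- 400
  X <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n, 3))))[, 2:4] * sqrt(n - 1)
  colnames(X) <- c("pupil", "locomotion", "reward")
  f <- fit_full_model(X[, "pupil"], X)
  expect_equal(f$r2, 1, tolerance = 1e-9)
  expect_equal(unname(f$coefficients), c(1, 0, 0), tolerance = 1e-9)

  y <- 0.6 * X[, 1] + 0.8 * X[, 2]
  f2 <- fit_full_model(y, X)
  expect_equal(f2$r2, 1, tolerance = 1e-9)
  expect_equal(unname(f2$coefficients), c(0.6, 0.8, 0), tolerance = 1e-9)
})

test_that("OLS matches the pseudo-inverse oracle and names collinear predictors", {
  set.seed(9)
  X <- matrix(rnorm(300), 100, 3,
              dimnames = list(NULL, c("pupil", "locomotion", "reward")))
  y <- rnorm(100)
  f <- fit_full_model(y, X)
  o <- ols_pinv(y, X)
  expect_equal(unname(f$coefficients), as.numeric(o$coefficients),
               tolerance = 1e-9)
  expect_equal(f$r2, o$r2, tolerance = 1e-9)

  Xc <- cbind(X, dup = X[, 1])
  expect_error(fit_full_model(y, Xc), regexp = "dup",
               class = "pc_rank_deficient")
  expect_error(fit_full_model(y[1:20], X[1:20, ]), class = "pc_invalid_input")
})

test_that("null cells produce r2 near the analytic expectation p/(n-1)", {
  set.seed(10)
  n <- 600
  p <- 3
  m <- 300
  X <- matrix(rnorm(n * p), n, p)
  r2 <- vapply(seq_len(m),
               function(i) fit_full_model(rnorm(n), X)$r2, numeric(1))
  se <- stats::sd(r2) / sqrt(m)
  expect_lt(abs(mean(r2) - p / (n - 1)), 3 * se)
})

test_that("the r2 filter keeps the boundary value and warns on empty output", {
  res <- data.frame(cell_id = 1:3, r2_full = c(0.04, 0.05, 0.9))
  kept <- suppressMessages(filter_cells(res))
  expect_equal(kept$r2_full, c(0.05, 0.9))
  expect_warning(suppressMessages(
    filter_cells(data.frame(cell_id = 1, r2_full = 0.01))),
    "no cell")
})

test_that("contributions: pure cell, orthogonal 75/25 split, irrelevant predictor", {
  set.seed(12)
  n <- 2000
  # orthonormal predictors, also orthogonal to the intercept (exact partition)
  X <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n, 3))))[, 2:4] * sqrt(n - 1)
  colnames(X) <- c("pupil", "locomotion", "reward")

  vc <- variance_contributions(X[, "pupil"], X)
  expect_equal(vc$contribution[vc$predictor == "pupil"], 100, tolerance = 1e-6)
  expect_equal(sum(vc$contribution[vc$predictor != "pupil"]), 0,
               tolerance = 1e-6)

  y <- sqrt(0.75) * X[, 1] + sqrt(0.25) * X[, 2]
  vc2 <- variance_contributions(y, X)
  expect_equal(vc2$contribution, c(75, 25, 0), tolerance = 1e-6)
})

test_that("classification follows the 20% cutoff contract", {
  contr <- data.frame(contrib_pupil = c(90, 25, 5, 15),
                      contrib_reward = c(5, 25, 90, 15))
  expect_equal(classify_cells(contr),
               c("pupil", "both", "reward", "other"))
  expect_equal(classify_cells(data.frame(contrib_pupil = 25,
                                         contrib_reward = 50)), "both")
})

test_that("nested-model monotonicity holds for every cell and predictor", {
  set.seed(14)
  n <- 500
  X <- matrix(rnorm(n * 3), n, 3,
              dimnames = list(NULL, c("pupil", "locomotion", "reward")))
  Y <- X %*% matrix(runif(3 * 30, -1, 1), 3) + matrix(rnorm(n * 30), n)
  enc <- encode_cells(Y, X)
  for (p in c("pupil", "locomotion", "reward")) {
    expect_true(all(enc[[paste0("r2_minus_", p)]] <= enc$r2_full + 1e-12))
  }
  # contributions floored at zero; raw values reported alongside
  expect_true(all(enc$contrib_pupil >= 0))
  expect_true(all(enc$contrib_pupil_raw <= enc$contrib_pupil + 1e-12))
})

test_that("contribution histograms report only cells above the minor cutoff", {
  enc <- data.frame(contrib_pupil = c(5, 15, 40), contrib_reward = c(50, 2, 12),
                    contrib_locomotion = c(1, 1, 1))
  h <- contribution_histograms(enc, minor_cutoff = 10)
  expect_equal(h$pupil, c(15, 40))
  expect_equal(h$reward, c(50, 12))
  expect_length(h$locomotion, 0)
})
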