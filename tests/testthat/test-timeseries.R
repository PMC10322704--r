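# Frozen oracle values computed with scipy.signal.windows.dpss(64, 4, 7,
# return_ratios=True) (SciPy 1.17).
scipy_dpss64 <- list(
  lambdas = c(0.999999999746, 0.999999975397, 0.99999889519, 0.99996965768,
              0.999436549707, 0.992710115932, 0.937468604926),
  taper1_head = c(3.106368300718e-05, 9.977397693674e-05, 2.392140563208e-04,
                  4.915759072111e-04),
  taper4_head = c(0.005769171853, 0.012299062431, 0.021753126168,
                  0.034427593854)
)

test_that("DPSS tapers match the SciPy oracle and are orthonormal", {
  d <- dpss_tapers(64, nw = 4, k = 7)
  expect_equal(d$eigenvalues, scipy_dpss64$lambdas, tolerance = 1e-9)
  expect_equal(d$tapers[1:4, 1], scipy_dpss64$taper1_head, tolerance = 1e-8)
  expect_equal(d$tapers[1:4, 4], scipy_dpss64$taper4_head, tolerance = 1e-8)
  expect_lt(max(abs(crossprod(d$tapers) - diag(7))), 1e-10)
  expect_error(dpss_tapers(6, 4, 7), class = "pc_trace_too_short")
})

test_that("self-coherence is 1 at every resolved frequency", {
  set.seed(20)
  x <- rnorm(512)
  co <- multitaper_coherence(x, x, rate_hz = 20)
  expect_true(all(co$coherence >= 0.99))
  expect_true(all(co$frequency_hz <= 10))  # Nyquist
})

test_that("coherence is symmetric, scale-invariant and bounded in [0, 1]", {
  set.seed(21)
  x <- rnorm(400)
  y <- 0.5 * x + rnorm(400)
  c1 <- multitaper_coherence(x, y, 10)$coherence
  expect_equal(multitaper_coherence(y, x, 10)$coherence, c1, tolerance = 1e-12)
  expect_equal(multitaper_coherence(3 * x, -2 * y, 10)$coherence, c1,
               tolerance = 1e-12)
  expect_true(all(c1 >= 0 & c1 <= 1))
})

test_that("group coherence clips subjects to a common length and averages", {
  set.seed(22)
  xs <- list(rnorm(300), rnorm(280))
  ys <- list(rnorm(300), rnorm(280))
  g <- multitaper_coherence_group(xs, ys, 10)
  expect_equal(dim(g$subjects), c(2, 141))  # floor(280/2)+1 frequencies
  expect_equal(g$coherence, colMeans(g$subjects))
})

test_that("cross-correlation recovers integer shifts exactly", {
  set.seed(23)
  x <- rnorm(600)
  for (k in c(1, 5, 20)) {
    y <- c(rep(0, k), x[1:(600 - k)])  # x leads y by k samples
    cc <- cross_correlation(zscore(x), zscore(y), max_lag_s = 5, rate_hz = 10)
    expect_equal(cc$peak_lag_s, k / 10)
  }
  self <- cross_correlation(zscore(x), zscore(x), 2, 10)
  expect_equal(self$peak_lag_s, 0)
  expect_equal(self$peak_value, 1, tolerance = 1e-9)
  expect_error(cross_correlation(x, x, 100, 10), class = "pc_invalid_input")
})

test_that("independent traces stay inside the 3/sqrt(n) null envelope", {
  set.seed(1)
  n <- 10000
  x <- rnorm(n)
  y <- rnorm(n)
  cc <- cross_correlation(zscore(x), zscore(y), max_lag_s = 2, rate_hz = 10)
  expect_true(all(abs(cc$cc) < 3 / sqrt(n)))
})

test_that("pupil ON/OFF labels follow correlation sign and the generative weights", {
  t <- seq(0, 99, by = 0.2)
  pupil <- sin(t / 5) + 0.1 * cos(t)
  cells <- cbind(pupil, -pupil)
  cls <- correlate_and_classify(cells, pupil)
  expect_equal(cls$r, c(1, -1), tolerance = 1e-12)
  expect_equal(cls$label, c("ON", "OFF"))
  expect_error(correlate_and_classify(cbind(rep(1, length(t))), pupil),
               class = "pc_zero_variance")

  s <- small_session(seed = 25, duration_s = 240, n_cells = 20)
  tc <- s$cells$time_s
  pupz <- zscore(resample_linear(s$pupil$time_s, s$pupil$radius_px, tc))
  w <- s$truth$weights[, 1]
  strong <- abs(w) > 0.5
  cls2 <- correlate_and_classify(zscore(s$cells$signal[, strong] +
    matrix(rnorm(sum(strong) * length(tc), sd = 0.1), length(tc))), pupz)
  expect_equal(cls2$label, ifelse(w[strong] > 0, "ON", "OFF"))
})

test_that("ON cells lead the pupil by the generator-known conduction delay", {
  s <- lag_session(seed = 5)
  tc <- s$cells$time_s
  dt <- tc[2] - tc[1]
  pupz <- zscore(resample_linear(s$pupil$time_s, s$pupil$radius_px, tc))
  dff <- preprocess_cells(s$cells$raw, s$cells$halo)
  lags <- vapply(seq_len(ncol(dff)), function(i) {
    cross_correlation(dff[, i], pupz, max_lag_s = 10,
                      rate_hz = s$config$cell_rate_hz)$peak_lag_s
  }, numeric(1))
  expect_true(all(lags > 0))                        # cells lead
  expect_lt(abs(mean(lags) - 1), dt)                # known 1 s delay, +-1 sample
})
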