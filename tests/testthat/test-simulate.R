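test_that("reward timing honours the configured interval bounds", {
  cfg <- simulation_config(duration_s = 4500, n_rewards = 50, seed = 1)
  beh <- simulate_behavior(cfg)
  expect_length(beh$reward_times_s, 50)
  gaps <- diff(c(0, beh$reward_times_s))
  expect_true(all(gaps >= 60 & gaps <= 90))
  expect_true(all(beh$reward_times_s > 0 & beh$reward_times_s < 4500))
})

test_that("a session too short for the rewards fails explicitly", {
  cfg <- simulation_config(duration_s = 500, n_rewards = 50, seed = 1)
  expect_error(simulate_behavior(cfg), class = "pc_duration_too_short")
})

test_that("no bouts means exactly zero speed; licks follow rewards only", {
  cfg <- simulation_config(duration_s = 400, n_rewards = 4,
                           run_bout_rate = 0, seed = 4)
  beh <- simulate_behavior(cfg)
  expect_true(all(beh$speed_cmps == 0))
  lick_t <- beh$time_s[beh$lick == 1]
  in_burst <- vapply(lick_t, function(lt) {
    any(lt >= beh$reward_times_s & lt < beh$reward_times_s + cfg$lick_window_s)
  }, logical(1))
  expect_true(all(in_burst))
})

test_that("a fixed seed makes the whole session bit-reproducible", {
  cfg <- simulation_config(duration_s = 150, n_cells = 5, n_rewards = 1,
                           seed = 21)
  s1 <- simulate_session(cfg)
  s2 <- simulate_session(cfg)
  expect_identical(s1$behavior$speed_cmps, s2$behavior$speed_cmps)
  expect_identical(s1$pupil$radius_px, s2$pupil$radius_px)
  expect_identical(s1$cells$raw, s2$cells$raw)
  expect_identical(s1$landmarks$confidence, s2$landmarks$confidence)
  expect_identical(s1$photometry$f_raw, s2$photometry$f_raw)
})

test_that("stimulation epochs are non-overlapping with configured spacing and frequencies", {
  cfg <- simulation_config(duration_s = 1200, n_rewards = 0,
                           stim_frequencies_hz = c(1, 5, 10, 20), seed = 6)
  beh <- simulate_behavior(cfg)
  se <- beh$stim_epochs
  expect_gt(nrow(se), 3)
  expect_true(all(se$offset_s - se$onset_s == 30))
  expect_true(all(diff(se$onset_s) >= 120 & diff(se$onset_s) <= 150))
  expect_true(all(se$frequency_hz %in% c(1, 5, 10, 20)))
  expect_true(all(se$onset_s[-1] >= se$offset_s[-nrow(se)]))  # non-overlap
})

test_that("null drive gives a constant pupil at baseline", {
  cfg <- simulation_config(duration_s = 60, n_rewards = 0, run_bout_rate = 0,
                           arousal_sd = 0, seed = 1,
                           pupil_coupling = c(arousal = 0, locomotion = 0,
                                              reward = 0, stim = 0))
  pup <- simulate_pupil(simulate_behavior(cfg), cfg)
  expect_equal(unique(pup$radius_px), cfg$pupil_baseline_px)
})

test_that("the pupil plant is a first-order filter with the configured time constant", {
  dt <- 0.05
  tau <- 1.5
  step <- c(rep(0, 100), rep(1, 400))
  y <- lowpass1(step, dt, tau)
  # a unit step from rest follows 1 - exp(-t/tau) exactly at the sample times
  expect_equal(y[101:500], 1 - exp(-(1:400) * dt / tau), tolerance = 1e-12)
  # constant input passes through unchanged
  expect_equal(lowpass1(rep(3, 50), dt, tau), rep(3, 50))
})

test_that("drive leads the measured pupil by the configured conduction delay", {
  cfg <- simulation_config(duration_s = 600, n_rewards = 5, seed = 2)
  beh <- simulate_behavior(cfg)
  pup <- simulate_pupil(beh, cfg)
  cc <- cross_correlation(zscore(pup$drive), zscore(pup$radius_px),
                          max_lag_s = 10, rate_hz = 20)
  expect_gt(cc$peak_lag_s, 0)
  # the command -> radius path is an exact 6-sample shift (0.3 s at 20 Hz)
  d <- (pup$radius_px / cfg$pupil_baseline_px - 1) / cfg$pupil_gain
  n <- length(d)
  expect_equal(d[7:n], pup$command[1:(n - 6)], tolerance = 1e-12)
})

test_that("a pure pupil cell with no noise and no kernel equals the pupil predictor", {
  cfg <- simulation_config(duration_s = 300, n_cells = 2, n_rewards = 2,
                           calcium_tau_s = 0, seed = 8)
  beh <- simulate_behavior(cfg)
  pup <- simulate_pupil(beh, cfg)
  spec <- data.frame(class = c("pupil_on", "null"),
                     w_pupil = c(1, 0), w_locomotion = 0, w_reward = 0,
                     noise_sd = 0)
  cells <- simulate_cells(beh, pup, cfg, truth_spec = spec)
  expect_equal(zscore(cells$signal[, 1]), cells$predictors[, "pupil"],
               tolerance = 1e-12)
  # null cell: zero signal, all shares zero, noise share takes the remainder
  expect_true(all(cells$signal[, 2] == 0))
  expect_equal(unname(cells$truth$shares[2, ]), c(0, 0, 0))
})

test_that("variance shares are conserved and match a regression oracle", {
  s <- small_session(seed = 13, n_cells = 20)
  tot <- rowSums(s$truth$shares) + s$truth$noise_share
  expect_equal(tot, rep(1, 20), tolerance = 1e-9)
  expect_true(all(s$truth$shares >= 0))
  # oracle: regress the noiseless signal on the convolved predictors
  CP <- s$cells$convolved_predictors
  for (i in c(1, 7, 15)) {
    sig <- s$cells$signal[, i]
    if (stats::var(sig) == 0) next
    fit <- ols_pinv(sig, CP)
    expect_equal(fit$r2, 1, tolerance = 1e-9)
    expect_equal(as.numeric(fit$coefficients),
                 as.numeric(s$truth$weights[i, ]), tolerance = 1e-6)
    oracle_share <- as.numeric(fit$coefficients) * c(stats::cov(CP, sig)) /
      (stats::var(sig) + s$truth$noise_sd[i]^2)
    expect_equal(unname(s$truth$shares[i, ]), oracle_share, tolerance = 1e-9)
  }
})

test_that("negative noise sd in the truth spec is rejected", {
  cfg <- simulation_config(duration_s = 60, n_cells = 1, n_rewards = 0, seed = 1)
  beh <- simulate_behavior(cfg)
  pup <- simulate_pupil(beh, cfg)
  spec <- data.frame(class = "x", w_pupil = 1, w_locomotion = 0,
                     w_reward = 0, noise_sd = -1)
  expect_error(simulate_cells(beh, pup, cfg, truth_spec = spec),
               class = "pc_invalid_config")
})

test_that("landmarks sit exactly on the circle without jitter; blinks obey blink_rate", {
  cfg <- simulation_config(duration_s = 30, n_rewards = 0,
                           landmark_jitter_px = 0, blink_rate_hz = 0, seed = 3)
  pup <- simulate_pupil(simulate_behavior(cfg), cfg)
  lm <- render_landmarks(pup, cfg)
  d <- sqrt((lm$x - cfg$landmark_center_px[1])^2 +
              (lm$y - cfg$landmark_center_px[2])^2)
  expect_equal(max(abs(d - pup$radius_px)), 0, tolerance = 1e-9)
  expect_true(all(lm$confidence >= cfg$confidence_threshold))
})

test_that("all session clocks are mutually alignable", {
  s <- small_session(seed = 17)
  sup_pupil <- range(s$pupil$time_s)
  sup_cell <- range(s$cells$time_s)
  ev <- s$behavior$reward_times_s
  expect_true(all(ev >= max(sup_pupil[1], sup_cell[1]) &
                    ev <= min(sup_pupil[2], sup_cell[2])))
})
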