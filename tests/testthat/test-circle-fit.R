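test_that("noiseless circles are recovered exactly", {
  fit <- fit_circle(circle_points(3, -2, 5))
  expect_equal(fit$center, c(3, -2), tolerance = 1e-9)
  expect_equal(fit$radius, 5, tolerance = 1e-9)

  fit <- fit_circle(rbind(c(0, 1), c(1, 0), c(0, -1), c(-1, 0)))
  expect_equal(fit$center, c(0, 0), tolerance = 1e-9)
  expect_equal(fit$radius, 1, tolerance = 1e-9)
})

test_that("fit is order-invariant, translation-equivariant, rotation-invariant", {
  set.seed(42)
  for (i in 1:20) {
    p <- circle_points(runif(1, -20, 20), runif(1, -20, 20),
                       runif(1, 1, 15), jitter = 0.3)
    ref <- fit_circle(p)
    perm <- fit_circle(p[sample(8), ])
    expect_equal(perm$radius, ref$radius, tolerance = 1e-9)
    expect_equal(perm$center, ref$center, tolerance = 1e-9)
    shift <- c(runif(1, -5, 5), runif(1, -5, 5))
    tr <- fit_circle(sweep(p, 2, shift, "+"))
    expect_equal(tr$center, ref$center + shift, tolerance = 1e-9)
    expect_equal(tr$radius, ref$radius, tolerance = 1e-9)
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    expect_equal(fit_circle(p %*% R)$radius, ref$radius, tolerance = 1e-9)
  }
})

test_that("degenerate geometry is rejected", {
  collinear <- cbind(1:8, 2 * (1:8) + 1)
  expect_error(fit_circle(collinear), class = "pc_degenerate_geometry")
  expect_error(fit_circle(rbind(c(0, 0), c(1, 1))),
               class = "pc_degenerate_geometry")
})

test_that("Kasa fit agrees with the grid-search geometric oracle on jittered points", {
  set.seed(7)
  for (i in 1:3) {
    p <- circle_points(runif(1, -3, 3), runif(1, -3, 3), 10, jitter = 0.05)
    kasa <- fit_circle(p)
    oracle <- grid_circle_fit(p, resolution = 0.02)
    expect_lt(abs(kasa$radius - oracle$radius), oracle$resolution)
  }
})

test_that("high-confidence frames are fitted directly, never interpolated", {
  fr <- manual_frames(c(10, 11, 12, 11))
  tr <- extract_pupil_trace(fr)
  expect_false(any(tr$interpolated))
  expect_equal(tr$radius_px, c(10, 11, 12, 11), tolerance = 1e-9)
  expect_equal(tr$area_px2, pi * tr$radius_px^2, tolerance = 1e-9)
})

test_that("a low-confidence frame between radius 10 and 12 interpolates to 11", {
  conf <- matrix(1, 3, 8)
  conf[2, ] <- 0.1
  fr <- manual_frames(c(10, 99, 12), conf = conf)  # middle frame garbage
  fr$x[2, ] <- 0
  fr$y[2, ] <- 0
  tr <- extract_pupil_trace(fr, 0.9)
  expect_equal(tr$radius_px[2], 11, tolerance = 1e-9)
  expect_equal(tr$interpolated, c(FALSE, TRUE, FALSE))
})

test_that("leading/trailing gaps take the nearest valid frame", {
  conf <- matrix(1, 4, 8)
  conf[1, ] <- 0.2
  conf[4, ] <- 0.2
  fr <- manual_frames(c(50, 10, 12, 50), conf = conf)
  tr <- extract_pupil_trace(fr, 0.9)
  expect_equal(tr$radius_px[1], 10, tolerance = 1e-9)  # held from frame 2
  expect_equal(tr$radius_px[4], 12, tolerance = 1e-9)  # held from frame 3
  # interpolation never extrapolates beyond flanking values
  expect_true(all(tr$radius_px >= 10 - 1e-9 & tr$radius_px <= 12 + 1e-9))
})

test_that("extraction fails when no frame is fully above threshold", {
  fr <- manual_frames(c(10, 11), conf = matrix(0.5, 2, 8))
  expect_error(extract_pupil_trace(fr, 0.9), class = "pc_no_valid_frames")
})

test_that("render -> fit round-trip with zero jitter recovers radii to 1e-9", {
  cfg <- simulation_config(duration_s = 20, n_rewards = 0,
                           landmark_jitter_px = 0, blink_rate_hz = 0, seed = 2)
  beh <- simulate_behavior(cfg)
  pup <- simulate_pupil(beh, cfg)
  lm <- render_landmarks(pup, cfg)
  tr <- extract_pupil_trace(lm, cfg$confidence_threshold)
  expect_lt(max(abs(tr$radius_px - pup$radius_px)), 1e-9)
  expect_false(any(tr$interpolated))
})

test_that("blink interpolation error stays within the jitter-driven envelope", {
  s <- small_session(seed = 9, duration_s = 120)
  tr <- extract_pupil_trace(s$landmarks, 0.9)
  err <- abs(tr$radius_px - s$pupil$radius_px)
  # non-blink frames: radius error from landmark jitter; the oracle bound is
  # the spread of grid-fit radii over jittered replicates of one frame
  set.seed(1)
  reps <- replicate(200, {
    p <- circle_points(0, 0, 30, jitter = s$config$landmark_jitter_px)
    fit_circle(p)$radius - 30
  })
  bound <- 6 * stats::sd(reps)
  expect_lt(max(err[!s$landmarks$blink]), bound)
})
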