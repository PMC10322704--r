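# Independent oracles and small fixtures, built in code at test time.

# Brute-force geometric circle fit: grid search over the centre (the radius
# that minimises the geometric residual for a fixed centre is the mean
# distance), refined over three stages down to `resolution`.
grid_circle_fit <- function(points, resolution = 0.02) {
  cx <- mean(points[, 1])
  cy <- mean(points[, 2])
  half <- 2
  step <- resolution * 25
  best <- c(cx, cy)
  for (stage in 1:3) {
    gx <- seq(best[1] - half, best[1] + half, by = step)
    gy <- seq(best[2] - half, best[2] + half, by = step)
    g <- expand.grid(cx = gx, cy = gy)
    res <- vapply(seq_len(nrow(g)), function(i) {
      d <- sqrt((points[, 1] - g$cx[i])^2 + (points[, 2] - g$cy[i])^2)
      sum((d - mean(d))^2)
    }, numeric(1))
    best <- as.numeric(g[which.min(res), ])
    half <- step * 2
    step <- max(step / 5, resolution)
  }
  d <- sqrt((points[, 1] - best[1])^2 + (points[, 2] - best[2])^2)
  list(center = best, radius = mean(d), resolution = resolution)
}

# OLS via explicit pseudo-inverse (normal equations), independent of qr()
ols_pinv <- function(y, X) {
  D <- cbind(1, as.matrix(X))
  beta <- solve(t(D) %*% D, t(D) %*% y)
  fitted <- D %*% beta
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  list(coefficients = beta[-1], intercept = beta[1], r2 = r2)
}

# points on a circle at the 8 landmark angles
circle_points <- function(cx, cy, r, n = 8, jitter = 0) {
  a <- (seq_len(n) - 1) * 2 * pi / n
  cbind(cx + r * cos(a), cy + r * sin(a)) +
    matrix(stats::rnorm(2 * n, sd = jitter), n, 2)
}

# small landmark_frames object built by hand
manual_frames <- function(radii, conf = NULL, center = c(0, 0), fps = 20) {
  n <- length(radii)
  a <- (0:7) * pi / 4
  structure(list(
    time_s = (seq_len(n) - 1) / fps,
    x = outer(radii, cos(a)) + center[1],
    y = outer(radii, sin(a)) + center[2],
    confidence = if (is.null(conf)) matrix(1, n, 8) else conf,
    blink = rep(FALSE, n), rate_hz = fps
  ), class = "landmark_frames")
}

# compact session used by several tests (fast to generate)
small_session <- function(seed = 3, duration_s = 300, n_cells = 12,
                          n_rewards = floor(duration_s / 120), ...) {
  simulate_session(simulation_config(duration_s = duration_s,
                                     n_cells = n_cells, n_rewards = n_rewards,
                                     seed = seed, ...))
}

# session designed for lag recovery: pure pupil-coded cells, fast indicator,
# fast-decorrelating arousal, and a 1 s generator-known conduction delay
lag_session <- function(seed = 5, n_cells = 20, duration_s = 900) {
  set.seed(seed)
  spec <- data.frame(class = "pupil_on",
                     w_pupil = stats::runif(n_cells, 0.8, 1.2),
                     w_locomotion = 0, w_reward = 0, noise_sd = 0.3)
  cfg <- simulation_config(duration_s = duration_s, n_cells = n_cells,
                           n_rewards = 0, run_bout_rate = 0,
                           calcium_tau_s = 0, pupil_delay_s = 1,
                           arousal_tau_s = 2, blink_rate_hz = 0, seed = seed)
  simulate_session(cfg, truth_spec = spec)
}
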