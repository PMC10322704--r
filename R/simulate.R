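# Synthetic-session generator. Produces behaviour, pupil, landmark, cell and
# photometry traces with the statistical structure the analysis assumes, plus
# the analytic ground truth used by the recovery tests. Randomness is fanned
# out from config$seed with a fixed per-stage offset so each stage is
# individually reproducible.

seed_offset <- c(behavior = 0L, pupil = 1L, cells = 2L,
                 landmarks = 3L, photometry = 4L)

#' Simulate session behaviour
#'
#' Generates running speed, reward times, the lick square wave and (when
#' `stim_frequencies_hz` is non-empty) optogenetic stimulation epochs, all on
#' the pupil video clock. Inter-reward intervals are uniform on
#' `reward_interval_s`; each reward is followed by a Bernoulli lick burst.
#' Running is a two-state process: rectangular bouts whose interior speed is
#' a smoothly modulated plateau well above the 1 cm/s run threshold, and
#' exactly zero speed between bouts, so the generative switch times are
#' unambiguous ground truth for bout detection.
#'
#' @param config A [simulation_config()].
#' @return An object of class `behavior_traces`: list with `time_s`,
#'   `speed_cmps`, `lick`, `reward_times_s`, `stim_epochs` (data.frame with
#'   onset_s, offset_s, frequency_hz), and ground-truth `bout_onsets_s` /
#'   `bout_offsets_s`.
#' @export
simulate_behavior <- function(config) {
  validate_config(config)
  set.seed(config$seed + seed_offset[["behavior"]])
  t <- clock(config$duration_s, config$pupil_rate_hz)
  n <- length(t)
  dt <- 1 / config$pupil_rate_hz

  # rewards: uniform gaps, rejection-sampled so all events land in-session
  reward_times <- numeric(0)
  if (config$n_rewards > 0) {
    lo <- config$reward_interval_s[1]
    hi <- config$reward_interval_s[2]
    if (config$n_rewards * lo >= config$duration_s) {
      pc_stop(sprintf(
        "duration %.0f s cannot fit %d rewards at the minimum interval %.0f s",
        config$duration_s, config$n_rewards, lo), "pc_duration_too_short")
    }
    for (attempt in 1:1000) {
      gaps <- stats::runif(config$n_rewards, lo, hi)
      cand <- cumsum(gaps)
      if (cand[length(cand)] < config$duration_s) {
        reward_times <- cand
        break
      }
    }
    if (length(reward_times) == 0) {
      pc_stop("could not place rewards inside the session", "pc_duration_too_short")
    }
  }

  # lick bursts after each reward
  lick <- integer(n)
  for (rt in reward_times) {
    idx <- which(t >= rt & t < rt + config$lick_window_s)
    lick[idx] <- stats::rbinom(length(idx), 1, config$lick_prob)
  }

  # running bouts
  speed <- numeric(n)
  bout_on <- numeric(0)
  bout_off <- numeric(0)
  if (config$run_bout_rate > 0) {
    # stereotyped bout archetypes (duration s, plateau speed cm/s): mice run
    # in recognisable bout types, which is what makes k-means bout matching
    # across groups meaningful
    bout_types <- data.frame(dur = c(4, 8, 14), base = c(4, 7, 10))
    mean_gap_s <- 60 / config$run_bout_rate
    cursor <- stats::rexp(1, rate = 1 / mean_gap_s)
    while (TRUE) {
      type <- sample.int(nrow(bout_types), 1)
      dur <- bout_types$dur[type]
      if (cursor + dur >= config$duration_s - 1) break
      i0 <- floor(cursor / dt) + 1
      i1 <- floor((cursor + dur) / dt)
      if (i1 > i0 + 1) {
        base <- bout_types$base[type] + stats::runif(1, -0.3, 0.3)
        m <- i1 - i0 + 1
        wob <- stats::filter(stats::rnorm(m), rep(1 / 8, 8), sides = 2)
        wob[is.na(wob)] <- 0
        prof <- pmax(base * (1 + 0.08 * as.numeric(wob)), 1.5)
        speed[i0:i1] <- prof
        bout_on <- c(bout_on, t[i0])
        bout_off <- c(bout_off, t[i1])
      }
      # at least 10 s of rest between bouts: switch times stay identifiable
      # and the -2..+8 s peri-onset analysis window never spans two bouts
      cursor <- cursor + dur + max(stats::rexp(1, rate = 1 / mean_gap_s), 10)
    }
  }

  # optogenetic stimulation epochs (randomised frequency order in blocks)
  stim <- data.frame(onset_s = numeric(0), offset_s = numeric(0),
                     frequency_hz = numeric(0))
  if (length(config$stim_frequencies_hz) > 0) {
    onsets <- numeric(0)
    cursor <- stats::runif(1, 30, 60)
    while (cursor + config$stim_duration_s < config$duration_s) {
      onsets <- c(onsets, cursor)
      cursor <- cursor + stats::runif(1, config$stim_interval_s[1],
                                      config$stim_interval_s[2])
    }
    if (length(onsets) > 0) {
      nf <- length(config$stim_frequencies_hz)
      freqs <- unlist(lapply(seq_len(ceiling(length(onsets) / nf)),
                             function(i) config$stim_frequencies_hz[sample.int(nf)]))
      stim <- data.frame(onset_s = onsets,
                         offset_s = onsets + config$stim_duration_s,
                         frequency_hz = freqs[seq_along(onsets)])
    }
  }

  structure(list(time_s = t, speed_cmps = speed, lick = lick,
                 reward_times_s = reward_times, stim_epochs = stim,
                 bout_onsets_s = bout_on, bout_offsets_s = bout_off,
                 config = config),
            class = "behavior_traces")
}

#' Simulate the pupil trace
#'
#' The pupil radius is a first-order low-pass filter (time constant
#' `pupil_tau_s`) of a net drive composed of a latent Ornstein--Uhlenbeck
#' arousal process, locomotion coupling, post-reward transients and (when
#' present) optogenetic drive scaled by train frequency. The filtered drive
#' is the central pupil command (`command`); the measured radius is the
#' command shifted by the conduction delay `pupil_delay_s`. Cells encode the
#' undelayed command, so net cell activation precedes dilation by a
#' generator-known lag.
#'
#' @param behavior Output of [simulate_behavior()].
#' @param config The same [simulation_config()].
#' @return Object of class `pupil_sim`: list with `time_s`, `radius_px`,
#'   the undelayed `command`, latent `arousal` and the composite `drive`.
#' @export
simulate_pupil <- function(behavior, config) {
  set.seed(config$seed + seed_offset[["pupil"]])
  t <- behavior$time_s
  n <- length(t)
  dt <- 1 / config$pupil_rate_hz

  # latent arousal: OU with stationary sd arousal_sd
  a <- exp(-dt / config$arousal_tau_s)
  if (config$arousal_sd > 0) {
    innov <- stats::rnorm(n, sd = config$arousal_sd * sqrt(1 - a^2))
    x0 <- stats::rnorm(1, sd = config$arousal_sd)
    arousal <- as.numeric(stats::filter(innov, a, method = "recursive",
                                        init = x0))
  } else {
    arousal <- numeric(n)
  }

  # post-reward transient: alpha kernel, unit peak at 2 s
  tau_r <- 2
  kt <- seq(0, 6 * tau_r, by = dt)
  alpha_kernel <- (kt / tau_r) * exp(1 - kt / tau_r)
  reward_delta <- numeric(n)
  reward_delta[pmin(floor(behavior$reward_times_s / dt) + 1, n)] <- 1
  reward_drive <- conv_causal(reward_delta, alpha_kernel)

  stim_drive <- numeric(n)
  if (nrow(behavior$stim_epochs) > 0) {
    for (i in seq_len(nrow(behavior$stim_epochs))) {
      idx <- which(t >= behavior$stim_epochs$onset_s[i] &
                     t < behavior$stim_epochs$offset_s[i])
      stim_drive[idx] <- behavior$stim_epochs$frequency_hz[i] / 20
    }
  }

  w <- config$pupil_coupling
  drive <- w[["arousal"]] * arousal +
    w[["locomotion"]] * behavior$speed_cmps / 10 +
    w[["reward"]] * reward_drive +
    w[["stim"]] * stim_drive

  command <- lowpass1(drive, dt, config$pupil_tau_s)
  dsamp <- round((config$pupil_delay_s %||% 0) * config$pupil_rate_hz)
  delayed <- if (dsamp > 0) {
    c(rep(command[1], dsamp), command[seq_len(n - dsamp)])
  } else {
    command
  }
  radius <- config$pupil_baseline_px * (1 + config$pupil_gain * delayed)
  radius <- pmax(radius, 1e-6)

  structure(list(time_s = t, radius_px = radius, command = command,
                 arousal = arousal, drive = drive),
            class = "pupil_sim")
}

#' Designed ground-truth cell classes
#'
#' Builds the per-cell generative weights on the (pupil, locomotion, reward)
#' predictors. Classes set the dominant weight: pupil-ON (positive pupil
#' weight), pupil-OFF (negative pupil weight), reward-dominant,
#' locomotion-dominant, mixed pupil+reward, and null (no weights; pure
#' noise). Coding is distributed, not categorical: every positively-coded
#' cell additionally carries small graded background weights on all three
#' predictors, so true variance shares vary continuously across the
#' population (pupil-OFF cells stay pure so all analytic shares remain
#' non-negative).
#'
#' @param n_cells Number of cells.
#' @param noise_sd Noise standard deviation applied to every cell (z-scale).
#' @return data.frame with columns `class`, `w_pupil`, `w_locomotion`,
#'   `w_reward`, `noise_sd`.
#' @export
default_truth_spec <- function(n_cells, noise_sd = 0.5) {
  props <- c(pupil_on = 0.25, pupil_off = 0.10, reward = 0.20,
             locomotion = 0.12, mixed = 0.20, null = 0.13)
  counts <- floor(props * n_cells)
  counts["pupil_on"] <- counts["pupil_on"] + (n_cells - sum(counts))
  cls <- rep(names(counts), counts)
  w <- matrix(0, n_cells, 3,
              dimnames = list(NULL, c("w_pupil", "w_locomotion", "w_reward")))
  amp <- function(k) stats::runif(k, 0.7, 1.3)
  w[cls == "pupil_on", 1] <- amp(sum(cls == "pupil_on"))
  w[cls == "pupil_off", 1] <- -amp(sum(cls == "pupil_off"))
  w[cls == "reward", 3] <- amp(sum(cls == "reward"))
  w[cls == "locomotion", 2] <- amp(sum(cls == "locomotion"))
  nmix <- sum(cls == "mixed")
  w[cls == "mixed", 1] <- stats::runif(nmix, 0.5, 1)
  w[cls == "mixed", 3] <- stats::runif(nmix, 0.5, 1)
  graded <- cls != "null" & cls != "pupil_off"
  w[graded, ] <- w[graded, ] +
    matrix(stats::runif(3 * sum(graded), 0.05, 0.35), sum(graded), 3)
  data.frame(class = cls, w, noise_sd = noise_sd)
}

#' Simulate cell fluorescence with analytic ground truth
#'
#' Each cell's activity is `(weights . z-scored predictors)` convolved with a
#' unit-sum exponential calcium kernel, plus white noise. Predictors are the
#' undelayed pupil command (the central signal the cells encode; the measured
#' radius is its delayed copy) and running speed linearly interpolated onto
#' the cell clock
#' and z-scored, and the lick square wave convolved with one kernel of the
#' reward spline basis (the "true" kernel, recorded in the ground truth).
#' Raw fluorescence adds a baseline, a shared slow contamination trace and
#' scaling; the halo trace carries the contamination plus a small leak of the
#' cell signal, so neuropil correction is exercised realistically.
#'
#' True variance shares are computed analytically from the realised convolved
#' predictors via the covariance decomposition
#' `share_j = w_j * cov(cp_j, s) / (var(s) + noise_sd^2)` with
#' `noise_share = noise_sd^2 / (var(s) + noise_sd^2)`, which sums to 1
#' exactly.
#'
#' @param behavior Output of [simulate_behavior()].
#' @param pupil Output of [simulate_pupil()].
#' @param config The [simulation_config()].
#' @param truth_spec Optional data.frame as from [default_truth_spec()].
#' @param spline_basis Optional reward spline basis (see
#'   [make_spline_basis()]); defaults to the package basis at the cell rate.
#' @param true_kernel_index Index of the basis kernel used to generate the
#'   reward response.
#' @return Object of class `cell_sim`: list with `time_s` (cell clock), `raw`
#'   and `halo` (n x cells matrices), `signal` (noiseless z-scale activity),
#'   `predictors` (convolution inputs), and `truth` (class `ground_truth`).
#' @export
simulate_cells <- function(behavior, pupil, config, truth_spec = NULL,
                           spline_basis = NULL, true_kernel_index = 4) {
  set.seed(config$seed + seed_offset[["cells"]])
  tc <- clock(config$duration_s, config$cell_rate_hz)
  nc <- length(tc)
  dtc <- 1 / config$cell_rate_hz
  if (is.null(truth_spec)) {
    truth_spec <- default_truth_spec(config$n_cells, config$noise_sd)
  }
  if (any(truth_spec$noise_sd < 0)) {
    pc_stop("negative noise variance in truth_spec", "pc_invalid_config")
  }
  if (is.null(spline_basis)) {
    spline_basis <- make_spline_basis(config$cell_rate_hz)
  }

  pupil_src <- pupil$command %||% pupil$radius_px
  pupil_c <- zscore_or_zero(resample_linear(pupil$time_s, pupil_src, tc))
  loco_c <- zscore_or_zero(resample_linear(behavior$time_s,
                                           behavior$speed_cmps, tc))
  lick_c <- resample_linear(behavior$time_s, behavior$lick, tc)
  reward_c <- zscore_or_zero(
    conv_causal(lick_c, spline_basis$kernels[[true_kernel_index]]$values))
  P <- cbind(pupil = pupil_c, locomotion = loco_c, reward = reward_c)

  ck <- calcium_kernel(config$calcium_tau_s, dtc)
  CP <- apply(P, 2, conv_causal, k = ck)

  W <- as.matrix(truth_spec[, c("w_pupil", "w_locomotion", "w_reward")])
  signal <- CP %*% t(W)

  n_cells <- nrow(truth_spec)
  shares <- matrix(0, n_cells, 3,
                   dimnames = list(NULL, c("pupil", "locomotion", "reward")))
  noise_share <- numeric(n_cells)
  for (i in seq_len(n_cells)) {
    s <- signal[, i]
    total <- stats::var(s) + truth_spec$noise_sd[i]^2
    if (total <= 0) {
      noise_share[i] <- 1
    } else {
      shares[i, ] <- W[i, ] * c(stats::cov(CP, s)) / total
      noise_share[i] <- truth_spec$noise_sd[i]^2 / total
    }
  }

  # true class labels at the 20% cutoff, on shares renormalised to the
  # explained (non-noise) part -- the same scale as model contributions
  expl <- rowSums(shares)
  rel <- shares
  rel[expl > 0, ] <- 100 * shares[expl > 0, ] / expl[expl > 0]
  label_true <- classify_cells(data.frame(contrib_pupil = rel[, "pupil"],
                                          contrib_reward = rel[, "reward"]))
  label_true[expl == 0] <- "other"

  noise <- matrix(stats::rnorm(nc * n_cells), nc, n_cells) *
    rep(truth_spec$noise_sd, each = nc)

  # raw fluorescence: baseline + scaled activity + shared slow contamination
  f0 <- stats::runif(n_cells, 150, 250)
  amp <- 30
  contamination <- 40 * exp(-tc / 900) + 8 * sin(2 * pi * tc / 400)
  leak <- 0.05
  raw <- sweep(amp * (signal + noise), 2, f0, "+") + contamination
  halo <- contamination + leak * amp * signal +
    matrix(stats::rnorm(nc * n_cells, sd = 1), nc, n_cells)

  truth <- structure(list(
    weights = W, noise_sd = truth_spec$noise_sd, shares = shares,
    noise_share = noise_share, label_true = label_true,
    class = truth_spec$class, true_kernel_index = true_kernel_index
  ), class = "ground_truth")

  structure(list(time_s = tc, raw = raw, halo = halo, signal = signal,
                 predictors = P, convolved_predictors = CP, truth = truth),
            class = "cell_sim")
}

#' Render pupil landmarks
#'
#' Places 8 points at 45-degree steps on a circle of the instantaneous pupil
#' radius around a fixed centre, adds Gaussian jitter, and assigns per-point
#' likelihoods. Blinks are Poisson episodes during which all likelihoods drop
#' below the extraction threshold (the extraction path only sees confidence,
#' so lid geometry is not modelled).
#'
#' @param pupil Output of [simulate_pupil()] (or any list with `time_s` and
#'   positive `radius_px`).
#' @param config The [simulation_config()].
#' @return Object of class `landmark_frames`: list with `time_s`, `x`, `y`,
#'   `confidence` (each an n x 8 matrix) and logical `blink` per frame.
#' @export
render_landmarks <- function(pupil, config) {
  set.seed(config$seed + seed_offset[["landmarks"]])
  if (any(pupil$radius_px <= 0)) {
    pc_stop("pupil radii must be positive", "pc_invalid_config")
  }
  n <- length(pupil$time_s)
  angles <- (0:7) * pi / 4
  cx <- config$landmark_center_px[1]
  cy <- config$landmark_center_px[2]
  x <- outer(pupil$radius_px, cos(angles)) + cx
  y <- outer(pupil$radius_px, sin(angles)) + cy
  if (config$landmark_jitter_px > 0) {
    x <- x + matrix(stats::rnorm(n * 8, sd = config$landmark_jitter_px), n, 8)
    y <- y + matrix(stats::rnorm(n * 8, sd = config$landmark_jitter_px), n, 8)
  }
  confidence <- matrix(stats::runif(n * 8, 0.95, 1), n, 8)
  blink <- rep(FALSE, n)
  if (config$blink_rate_hz > 0) {
    n_blinks <- stats::rpois(1, config$blink_rate_hz * config$duration_s)
    if (n_blinks > 0) {
      onsets <- stats::runif(n_blinks, 0, config$duration_s - 0.5)
      durs <- stats::runif(n_blinks, 0.15, 0.4)
      for (i in seq_len(n_blinks)) {
        idx <- which(pupil$time_s >= onsets[i] &
                       pupil$time_s < onsets[i] + durs[i])
        blink[idx] <- TRUE
      }
      nb <- sum(blink)
      confidence[blink, ] <- matrix(
        stats::runif(nb * 8, 0.05, 0.9 * config$confidence_threshold), nb, 8)
    }
  }
  structure(list(time_s = pupil$time_s, x = x, y = y,
                 confidence = confidence, blink = blink,
                 rate_hz = config$pupil_rate_hz),
            class = "landmark_frames")
}

#' Simulate a complete session
#'
#' Runs [simulate_behavior()], [simulate_pupil()], [simulate_cells()] and
#' [render_landmarks()], and adds a bulk photometry trace: the population
#' mean cell signal on the pupil clock, under an additive slow bleaching
#' trend (for convex-hull detrending) plus measurement noise.
#'
#' @param config A [simulation_config()].
#' @param truth_spec,spline_basis,true_kernel_index Passed to
#'   [simulate_cells()].
#' @return Object of class `pupil_session` bundling all components.
#' @export
simulate_session <- function(config, truth_spec = NULL, spline_basis = NULL,
                             true_kernel_index = 4) {
  behavior <- simulate_behavior(config)
  pupil <- simulate_pupil(behavior, config)
  cells <- simulate_cells(behavior, pupil, config, truth_spec = truth_spec,
                          spline_basis = spline_basis,
                          true_kernel_index = true_kernel_index)
  landmarks <- render_landmarks(pupil, config)

  set.seed(config$seed + seed_offset[["photometry"]])
  pop <- rowMeans(cells$signal)
  pop_p <- resample_linear(cells$time_s, pop, behavior$time_s)
  f_raw <- 2 * exp(-behavior$time_s / 700) + 0.3 * pop_p +
    stats::rnorm(length(pop_p), sd = 0.02)

  structure(list(config = config, behavior = behavior, pupil = pupil,
                 cells = cells, landmarks = landmarks,
                 photometry = list(time_s = behavior$time_s, f_raw = f_raw,
                                   population_signal = pop_p),
                 truth = cells$truth),
            class = "pupil_session")
}
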