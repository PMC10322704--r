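#' Configuration for a synthetic recording session
#'
#' Collects every parameter of the synthetic-session generator. Defaults
#' reproduce the recorded study conditions: a 20 Hz pupil camera, a 5.15 Hz
#' volumetric two-photon cell clock, milkshake rewards at random 60--90 s
#' intervals with 50 rewards per session, and 30 s optogenetic trains (when
#' enabled) every 120--150 s.
#'
#' @param duration_s Session length in seconds. The default (4800 s) is the
#'   shortest round length that comfortably fits 50 rewards at the maximum
#'   90 s spacing.
#' @param pupil_rate_hz Pupil video frame rate (Hz).
#' @param cell_rate_hz Imaging volume rate (Hz).
#' @param n_cells Number of simulated cells.
#' @param reward_interval_s Length-2 vector; inter-reward intervals are drawn
#'   uniformly from this range (seconds).
#' @param n_rewards Number of rewards in the session.
#' @param run_bout_rate Running-bout rate in bouts per minute.
#' @param calcium_tau_s Decay constant of the calcium kernel (seconds).
#' @param noise_sd Per-cell white-noise standard deviation on the z-scale.
#' @param blink_rate_hz Blink rate (events per second).
#' @param landmark_jitter_px Gaussian jitter applied to each landmark (px).
#' @param seed Integer seed; fixes every random draw in the session.
#' @param pupil_tau_s Time constant of the first-order pupil plant (seconds),
#'   so pupil size lags its net drive.
#' @param pupil_delay_s Pure conduction delay between the central pupil
#'   command and measured dilation (seconds); this is the generator-known
#'   neural-lead lag, since cells encode the undelayed command.
#' @param arousal_tau_s Correlation time of the latent Ornstein--Uhlenbeck
#'   arousal process (seconds).
#' @param arousal_sd Stationary standard deviation of the arousal process.
#' @param pupil_baseline_px Baseline pupil radius (pixels).
#' @param pupil_gain Fractional radius change per unit of filtered drive.
#' @param pupil_coupling Named numeric: weights of arousal, locomotion,
#'   reward and optogenetic drive on the pupil.
#' @param stim_frequencies_hz Optogenetic train frequencies (Hz); empty
#'   disables stimulation. The recorded protocol used 1, 5, 10 and 20 Hz in
#'   randomised order.
#' @param stim_duration_s Stimulation train length (seconds).
#' @param stim_interval_s Length-2 vector of onset-to-onset spacing (seconds).
#' @param lick_window_s Duration of the post-reward lick burst (seconds).
#' @param lick_prob Per-frame probability of the lick detector being high
#'   within the burst window.
#' @param confidence_threshold Landmark likelihood below which a point is
#'   treated as unusable (blink emulation drops confidence below this).
#' @param landmark_center_px Length-2 pupil centre in image coordinates (px).
#' @return An object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(duration_s = 4800,
                              pupil_rate_hz = 20,
                              cell_rate_hz = 5.15,
                              n_cells = 60,
                              reward_interval_s = c(60, 90),
                              n_rewards = 50,
                              run_bout_rate = 2,
                              calcium_tau_s = 1.6,
                              noise_sd = 0.5,
                              blink_rate_hz = 0.05,
                              landmark_jitter_px = 0.5,
                              seed = 1L,
                              pupil_tau_s = 1.5,
                              pupil_delay_s = 0.3,
                              arousal_tau_s = 30,
                              arousal_sd = 1,
                              pupil_baseline_px = 30,
                              pupil_gain = 0.12,
                              pupil_coupling = c(arousal = 1, locomotion = 0.5,
                                                 reward = 0.7, stim = 1),
                              stim_frequencies_hz = numeric(0),
                              stim_duration_s = 30,
                              stim_interval_s = c(120, 150),
                              lick_window_s = 4,
                              lick_prob = 0.7,
                              confidence_threshold = 0.9,
                              landmark_center_px = c(100, 80)) {
  cfg <- list(
    duration_s = duration_s, pupil_rate_hz = pupil_rate_hz,
    cell_rate_hz = cell_rate_hz, n_cells = as.integer(n_cells),
    reward_interval_s = reward_interval_s, n_rewards = as.integer(n_rewards),
    run_bout_rate = run_bout_rate, calcium_tau_s = calcium_tau_s,
    noise_sd = noise_sd, blink_rate_hz = blink_rate_hz,
    landmark_jitter_px = landmark_jitter_px, seed = as.integer(seed),
    pupil_tau_s = pupil_tau_s, pupil_delay_s = pupil_delay_s,
    arousal_tau_s = arousal_tau_s,
    arousal_sd = arousal_sd, pupil_baseline_px = pupil_baseline_px,
    pupil_gain = pupil_gain, pupil_coupling = pupil_coupling,
    stim_frequencies_hz = stim_frequencies_hz,
    stim_duration_s = stim_duration_s, stim_interval_s = stim_interval_s,
    lick_window_s = lick_window_s, lick_prob = lick_prob,
    confidence_threshold = confidence_threshold,
    landmark_center_px = landmark_center_px
  )
  validate_config(cfg)
  class(cfg) <- "simulation_config"
  cfg
}

validate_config <- function(cfg) {
  stop_if <- function(bad, msg) if (bad) pc_stop(msg, "pc_invalid_config")
  stop_if(cfg$duration_s <= 0, "duration_s must be positive")
  stop_if(cfg$pupil_rate_hz <= 0 || cfg$cell_rate_hz <= 0,
          "sampling rates must be positive")
  stop_if(cfg$n_cells < 1, "n_cells must be >= 1")
  stop_if(length(cfg$reward_interval_s) != 2 ||
            cfg$reward_interval_s[1] > cfg$reward_interval_s[2] ||
            cfg$reward_interval_s[1] <= 0,
          "reward_interval_s must be positive bounds (lower <= upper)")
  stop_if(cfg$n_rewards < 0, "n_rewards must be >= 0")
  stop_if(cfg$run_bout_rate < 0, "run_bout_rate must be >= 0")
  stop_if(cfg$noise_sd < 0, "noise_sd (a standard deviation) must be >= 0")
  stop_if(cfg$blink_rate_hz < 0, "blink_rate_hz must be >= 0")
  stop_if(cfg$landmark_jitter_px < 0, "landmark_jitter_px must be >= 0")
  stop_if(cfg$arousal_sd < 0, "arousal_sd must be >= 0")
  stop_if(cfg$pupil_delay_s < 0, "pupil_delay_s must be >= 0")
  stop_if(cfg$pupil_baseline_px <= 0, "pupil_baseline_px must be positive")
  stop_if(length(cfg$stim_interval_s) != 2 ||
            cfg$stim_interval_s[1] > cfg$stim_interval_s[2],
          "stim_interval_s must be bounds (lower <= upper)")
  stop_if(length(cfg$stim_frequencies_hz) > 0 &&
            cfg$stim_interval_s[1] <= cfg$stim_duration_s,
          "stim interval must exceed stim duration (non-overlapping epochs)")
  stop_if(cfg$confidence_threshold <= 0 || cfg$confidence_threshold >= 1,
          "confidence_threshold must be in (0, 1)")
  invisible(cfg)
}
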