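#!/usr/bin/env Rscript
# Generate the reference synthetic session (60 cells, 30 min, 5.15 Hz volume
# rate, rewards at 60-90 s intervals) and store it as plain-text files.

library(pupilcoding)
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L

cfg <- simulation_config(duration_s = 1800, n_cells = 60, n_rewards = 20,
                         seed = seed)
session <- simulate_session(cfg)
manifest <- write_session(session, "results/session")

cat("Simulated session:\n")
cat(sprintf("  %d pupil frames at %g Hz, %d cell samples at %g Hz\n",
            length(session$pupil$time_s), cfg$pupil_rate_hz,
            length(session$cells$time_s), cfg$cell_rate_hz))
cat(sprintf("  %d rewards, %d running bouts, %.1f%% blink frames\n",
            length(session$behavior$reward_times_s),
            length(session$behavior$bout_onsets_s),
            100 * mean(session$landmarks$blink)))
cat(sprintf("  ground-truth classes: %s\n",
            paste(names(table(session$truth$class)),
                  table(session$truth$class), collapse = ", ")))
cat("  written to", dirname(manifest), "\n")
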