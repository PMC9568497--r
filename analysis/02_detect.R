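#!/usr/bin/env Rscript
# Step 2: event detection and trial exclusions.
#
# Regenerates the oculomotor-arm traces deterministically (same TRACE_SEED
# as 01_simulate.R), runs the lambda-sigma microsaccade detector plus the
# saccade/blink detector on every trace, applies the exclusion rules
# (blink during video, fixation break), and scores detection against the
# simulator's ground truth.
#
# Outputs: events.csv, kept_trials.csv, exclusion_report.csv.

library(gazecue)

TRACE_SEED <- 20
trials <- read_trial_table("results/trace_trials.csv")
sim <- simulate_traces_for_trials(trials, trace_sim_config(),
                                  seed = TRACE_SEED)

events <- do.call(rbind, lapply(sim$traces, detect_trial))
write_event_table(events, "results/events.csv")

excl <- apply_trial_exclusions(trials, events, sim$traces)
write_trial_table(excl$trials[!excl$trials$excluded, ],
                  "results/kept_trials.csv")
write.csv(excl$report, "results/exclusion_report.csv", row.names = FALSE)

truth <- read_event_table("results/truth_events.csv")
m <- match_events(truth, events, tol_ms = 5)
cat(sprintf("detected %d events in %d traces\n", nrow(events),
            length(sim$traces)))
cat(sprintf("ground-truth recovery %.1f%%, spurious %.1f%%, amplitude r = %.4f\n",
            100 * m$recovery, 100 * m$spurious,
            cor(m$pairs$amp_true, m$pairs$amp_det)))
cat(sprintf("excluded %d/%d trials (%.1f%% blink-in-video)\n",
            sum(excl$trials$excluded), nrow(trials),
            100 * excl$report$fraction[excl$report$reason == "blink_in_video"]))
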