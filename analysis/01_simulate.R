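#!/usr/bin/env Rscript
# Step 1: simulate the experiment.
#
# Generates the behavioral cohort (30 subjects x 3 conditions x 2 SOAs x 60
# trials, 50% target presence, 50% cue validity) with the published
# condition-by-SOA sensitivity cueing structure, plus an oculomotor arm of
# fixational gaze traces (6 subjects x 30 trials) with ground-truth events.
#
# Outputs under results/: trials.csv (full cohort), trace_trials.csv (the
# oculomotor subset with timeline anchors), truth_events.csv (injected
# events), and samples_demo.csv (raw 1000 Hz samples for 4 trials, as a
# format example; the full trace set is regenerated deterministically from
# TRACE_SEED by later steps instead of being stored).

library(gazecue)

SEED <- 1
TRACE_SEED <- 20                      # shared with 02_detect.R
dir.create("results", showWarnings = FALSE)

trials <- simulate_behavior(behavior_sim_config(), seed = SEED)
write_trial_table(trials, "results/trials.csv")
cat("simulated", nrow(trials), "behavioral trials for",
    length(unique(trials$subject)), "subjects\n")

set.seed(SEED + 1)
sub <- trials[trials$subject %in% sprintf("s%02d", 1:6), ]
sub <- do.call(rbind, lapply(split(sub, sub$subject),
                             function(d) d[sample.int(nrow(d), 30), ]))
tl <- do.call(rbind, lapply(sub$soa_ms, make_timeline))
sub <- cbind(sub[setdiff(names(sub), names(tl))], tl)
write_trial_table(sub, "results/trace_trials.csv")

sim <- simulate_traces_for_trials(sub, trace_sim_config(), seed = TRACE_SEED)
write_event_table(sim$truth, "results/truth_events.csv")
write_gaze_samples(sim$traces[1:2], "results/samples_demo.csv")
cat("simulated", length(sim$traces), "gaze traces carrying",
    sum(sim$truth$kind == "microsaccade"), "injected microsaccades and",
    sum(sim$truth$kind == "blink"), "blinks\n")
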