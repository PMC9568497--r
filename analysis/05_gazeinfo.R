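#!/usr/bin/env Rscript
# Step 5: gaze information carried by annotations.
#
# Simulates annotation sets per condition (the headless-bodies condition
# gets a larger annotator error, mimicking the poorer gaze information of
# body-only cues), computes the mean Euclidean estimation error in pixels
# and degrees, and compares it against the across-video frame-permutation
# baseline. Also tabulates the head-angle-to-distance conversion used to
# interpret the angular sizes of gazers.
#
# Outputs: gaze_information.csv, head_distance_table.csv.

library(gazecue)

SEED <- 5
ann <- rbind(
  simulate_annotations(12, 4, error_sd_px = 15, condition = "intact",
                       seed = SEED),
  simulate_annotations(12, 4, error_sd_px = 15, condition = "floating_heads",
                       seed = SEED + 1),
  simulate_annotations(12, 4, error_sd_px = 45, condition = "headless_bodies",
                       seed = SEED + 2))
gi <- gaze_information(ann, n_perm = 1000, seed = SEED + 3)
write.csv(gi, "results/gaze_information.csv", row.names = FALSE)
print(gi[, c("condition", "mean_error_px", "mean_error_deg",
             "baseline_mean_px")], digits = 4, row.names = FALSE)
cat("observed error below the permutation baseline in all conditions:",
    all(gi$mean_error_px < gi$baseline_mean_px), "\n")

# real-world viewing distance implied by a 0.24 m head at various angles
angles <- c(2.75, 1.37, 0.92, 0.69, 0.55, 0.46)
hd <- data.frame(head_angle_deg = angles,
                 distance_m = head_angle_to_distance(angles))
write.csv(hd, "results/head_distance_table.csv", row.names = FALSE)
cat("a 0.24 m adult head spans 0.46-2.75 deg at 30 m down to 5 m\n")
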