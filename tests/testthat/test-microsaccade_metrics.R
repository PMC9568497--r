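mk_trials <- function(n, soa = 200, cue = "right") {
  tl <- make_timeline(soa, jitter_sd_ms = 0)
  cbind(data.frame(subject = "s01", trial = sprintf("t%02d", seq_len(n)),
                   condition = "intact", soa_ms = soa, target_present = TRUE,
                   cue_validity = "valid", cue_direction = cue,
                   response = "present", excluded = FALSE,
                   exclusion_reason = "none"),
        tl[rep(1, n), ], row.names = NULL)
}

mk_event <- function(trial, onset, dx = 0.2, dy = 0, kind = "microsaccade") {
  data.frame(subject = "s01", trial = trial, kind = kind, onset_ms = onset,
             offset_ms = onset + 20, dx_deg = dx, dy_deg = dy,
             amplitude_deg = sqrt(dx^2 + dy^2),
             direction_rad = atan2(dy, dx), peak_velocity_deg_s = 12)
}

test_that("alignment subtracts the anchor and round-trips", {
  trials <- mk_trials(2)
  ev <- mk_event("t01", 900)
  a_video <- align_events(ev, trials, "video_onset")
  expect_equal(a_video$onset_rel_ms, 900)          # video onset is 0
  a_arr <- align_events(ev, trials, "array_onset")
  expect_equal(a_arr$onset_rel_ms, 900 - trials$array_onset_ms[1])
  # re-aligning to video restores the original time
  back <- align_events(a_arr, trials, "video_onset")
  expect_equal(back$onset_rel_ms, 900)
  expect_error(align_events(mk_event("zzz", 1), trials), "zzz")
})

test_that("rate curves normalize counts by trials and bin width", {
  trials <- mk_trials(1)
  ev <- align_events(mk_event("t01", 150), trials, "video_onset")
  rc <- rate_curve(ev, trials, span_ms = c(0, 1000), bin_ms = 100,
                   smooth_ms = 0)
  # one event in one trial in a 100-ms bin -> 10 Hz in that bin, 0 elsewhere
  expect_equal(rc$rate_hz[rc$bin_center_ms == 150], 10)
  expect_equal(sum(rc$rate_hz), 10)

  # no events -> all-zero curve
  rc0 <- rate_curve(ev[0, ], trials, span_ms = c(0, 1000), bin_ms = 100,
                    smooth_ms = 0)
  expect_true(all(rc0$rate_hz == 0))
})

test_that("a homogeneous Poisson process recovers its rate at every bin", {
  set.seed(181)
  n_trials <- 500
  rate <- 1.5
  trials <- mk_trials(n_trials)
  span <- c(0, 2000)
  evs <- lapply(seq_len(n_trials), function(i) {
    k <- rpois(1, rate * diff(span) / 1000)
    if (k == 0) return(NULL)
    mk_event(sprintf("t%02d", i), sort(runif(k, span[1], span[2])))
  })
  ev <- do.call(rbind, evs[!vapply(evs, is.null, logical(1))])
  ev <- align_events(ev, trials, "video_onset")
  rc <- rate_curve(ev, trials, span_ms = span, bin_ms = 100, smooth_ms = 0)
  # single subject: Poisson SE per bin
  se <- sqrt(rate / (n_trials * 0.1))
  expect_true(all(abs(rc$rate_hz - rate) < 4 * se))
  # integral of the curve x trials reproduces the event count
  expect_equal(sum(rc$rate_hz * 0.1) * n_trials, nrow(ev))
})

test_that("toward-cue stats follow the horizontal-sign rule with conservation", {
  trials <- mk_trials(3, cue = "right")
  ev <- rbind(mk_event("t01", 500, dx = 0.2),     # toward
              mk_event("t01", 600, dx = -0.1),    # away
              mk_event("t02", 550, dx = 0.3),     # toward
              mk_event("t02", 650, dx = 0),       # neither
              mk_event("t03", 2500, dx = -0.4))   # outside window
  ev <- align_events(ev, trials, "video_onset")
  st <- toward_cue_window_stats(ev, trials, window_ms = c(0, 1000))
  expect_equal(st$n_events, 4)
  expect_equal(st$n_toward, 2)
  expect_equal(st$n_away, 1)
  expect_equal(st$n_zero, 1)
  expect_equal(st$n_toward + st$n_away + st$n_zero, st$n_events)
  # per-trial proportions: t01 -> 1/2, t02 -> 1/1; aggregate mean 0.75
  expect_equal(st$prop_toward, 0.75)
  # per-trial signed degrees: t01 -> +0.2 - 0.1 = 0.1, t02 -> 0.3
  expect_equal(st$mean_deg_toward, mean(c(0.1, 0.3)))

  # all events rightward with a right cue -> proportion 1
  ev_r <- align_events(rbind(mk_event("t01", 100), mk_event("t02", 100)),
                       trials, "video_onset")
  expect_equal(toward_cue_window_stats(ev_r, trials,
                                       window_ms = c(0, 1000))$prop_toward, 1)

  # flipping the cue flips toward/away
  trials_l <- mk_trials(3, cue = "left")
  ev_l <- align_events(rbind(mk_event("t01", 100), mk_event("t02", 100)),
                       trials_l, "video_onset")
  expect_equal(toward_cue_window_stats(ev_l, trials_l,
                                       window_ms = c(0, 1000))$prop_toward, 0)
})

test_that("sliding windows stride by step_ms across the span", {
  trials <- mk_trials(1)
  ev <- align_events(mk_event("t01", 500), trials, "video_onset")
  st <- toward_cue_window_stats(ev, trials, window_ms = 400, step_ms = 200,
                                span_ms = c(0, 1200))
  expect_equal(st$midpoint_ms, c(200, 400, 600, 800, 1000))
  expect_equal(st$n_events, c(0, 1, 1, 0, 0))
})

test_that("amplitude summaries report arcminute medians and strict fractions", {
  ev <- rbind(mk_event("t01", 100, dx = 0.1), mk_event("t01", 200, dx = 0.2),
              mk_event("t01", 300, dx = 0.3))
  s <- amplitude_summary(ev)
  expect_equal(s$median_arcmin, 0.2 * 60)
  expect_equal(s$fraction_below_threshold, 1)

  # strictly-less-than at the boundary
  s2 <- amplitude_summary(mk_event("t01", 100, dx = 0.5), threshold_deg = 0.5)
  expect_equal(s2$fraction_below_threshold, 0)

  expect_warning(s3 <- amplitude_summary(mk_event("t01", 1)[0, ]), "no microsaccades")
  expect_equal(s3$n, 0)
  expect_true(is.na(s3$median_arcmin))
})

test_that("direction density maps mirror left-cue trials onto +x", {
  trials_r <- mk_trials(1, cue = "right")
  ev <- align_events(mk_event("t01", 100, dx = 0.2, dy = 0), trials_r,
                     "video_onset")
  m_r <- direction_density_map(ev)
  occupied <- which(m_r$density > 0, arr.ind = TRUE)
  expect_equal(nrow(occupied), 1)
  expect_gt(m_r$x_centers[occupied[1, "col"]], 0)
  expect_equal(sum(m_r$density), 1)

  # a toward-cue displacement under a left cue (dx < 0) mirrors onto +x
  trials_l <- mk_trials(1, cue = "left")
  ev_l <- align_events(mk_event("t01", 100, dx = -0.2, dy = 0), trials_l,
                       "video_onset")
  m_l <- direction_density_map(ev_l)
  expect_equal(m_l$density, m_r$density)

  # globally flipping cues and x-components leaves the map invariant
  ev2 <- ev
  ev2$dx_deg <- -ev2$dx_deg
  ev2$cue_direction <- "left"
  expect_equal(direction_density_map(ev2)$density, m_r$density)
})

test_that("symmetric simulated directions give an x-symmetric density map", {
  set.seed(191)
  n <- 5000
  ang <- runif(n, -pi, pi)
  amp <- rlnorm(n, log(0.26), 0.6)
  ev <- data.frame(subject = "s01", trial = "t01", kind = "microsaccade",
                   onset_ms = 1, offset_ms = 2, dx_deg = amp * cos(ang),
                   dy_deg = amp * sin(ang), amplitude_deg = amp,
                   direction_rad = ang, peak_velocity_deg_s = 10,
                   cue_direction = "right")
  m <- direction_density_map(ev, grid_deg = 1, bin_deg = 0.5)
  flipped <- m$density[, rev(seq_len(ncol(m$density)))]
  expect_lt(sum(abs(m$density - flipped)) / 2, 0.05)
})
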