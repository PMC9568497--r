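make_flat_trace <- function(n = 600, x = 0, y = 0, trial = "t1") {
  gaze_trace("s01", trial, t_ms = 0:(n - 1), x_deg = rep(x, n),
             y_deg = rep(y, n))
}

test_that("velocity estimates are exact on constant and linear traces", {
  tr <- make_flat_trace()
  vel <- compute_velocity(tr)
  expect_true(all(vel$vx == 0))
  expect_true(all(vel$speed == 0))

  # linear ramp x(t) = c * t -> vx = c everywhere (including shrunken edges)
  c_deg_s <- 3.7
  n <- 200
  tr <- gaze_trace("s01", "t1", 0:(n - 1), x_deg = c_deg_s * (0:(n - 1)) / 1000,
                   y_deg = rep(0, n))
  vel <- compute_velocity(tr)
  expect_equal(vel$vx, rep(c_deg_s, n), tolerance = 1e-9)
  expect_equal(vel$vy, rep(0, n))
})

test_that("vectorized velocity matches the per-sample direct-summation oracle", {
  set.seed(101)
  for (window in c(3, 5, 7)) {
    n <- 200
    tr <- gaze_trace("s01", "t1", 0:(n - 1), x_deg = cumsum(rnorm(n, 0, 0.01)),
                     y_deg = cumsum(rnorm(n, 0, 0.01)))
    vel <- compute_velocity(tr, window)
    ref <- ref_velocity(tr, window)
    expect_equal(vel$vx, ref$vx, tolerance = 1e-9)
    expect_equal(vel$vy, ref$vy, tolerance = 1e-9)
    expect_equal(vel$speed, ref$speed, tolerance = 1e-9)
    expect_equal(vel$accel, ref$accel, tolerance = 1e-9)
  }
})

test_that("the robust threshold matches brute-force medians and is homogeneous", {
  set.seed(111)
  vx <- rnorm(500); vy <- rnorm(500, 0, 2)
  eta <- estimate_threshold(vx, vy, lambda = 6)
  sx <- sqrt(median(vx^2) - median(vx)^2)
  sy <- sqrt(median(vy^2) - median(vy)^2)
  expect_equal(unname(eta), c(6 * sx, 6 * sy))

  # alternating +/-1: median(v) = 0, median(v^2) = 1 -> eta = lambda
  v_alt <- rep(c(1, -1), 50)
  eta2 <- estimate_threshold(v_alt, v_alt, lambda = 6)
  expect_equal(unname(eta2), c(6, 6))

  # homogeneity: scaling velocities by c scales eta by c
  eta3 <- estimate_threshold(3 * vx, 3 * vy, lambda = 6)
  expect_equal(unname(eta3), 3 * unname(eta), tolerance = 1e-12)

  expect_error(estimate_threshold(rep(1, 100), rep(1, 100)), "degenerate")
  expect_error(estimate_threshold(1:5, 1:5), ">= 10")
})

test_that("a single injected event is detected with accurate onset and amplitude", {
  set.seed(121)
  cfg <- trace_sim_config(ms_rate_hz = 0, blink_prob_per_trial = 0,
                          ms_duration_ms = 20)
  tl <- make_timeline(200, jitter_sd_ms = 0)
  sim <- simulate_trace(cfg, tl, "right")
  tr <- sim$trace
  # inject one 0.3-deg rightward 20-ms event at 1000 ms by construction
  ramp <- pmin(pmax((tr$t_ms - 1000) / 20, 0), 1)
  step <- ramp - sin(2 * pi * ramp) / (2 * pi)
  tr$x_deg <- tr$x_deg + 0.3 * step
  ev <- detect_microsaccades(tr)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$kind, "microsaccade")
  expect_lt(abs(ev$onset_ms - 1000), 3 + 1e-9)
  expect_lt(abs(ev$amplitude_deg - 0.3) / 0.3, 0.10)
  expect_gt(ev$dx_deg, 0)
})

test_that("a noiseless flat trace yields no events and flags degeneracy", {
  tr <- make_flat_trace()
  expect_warning(ev <- detect_microsaccades(tr), "degenerate")
  expect_equal(nrow(ev), 0)
  expect_true(isTRUE(attr(ev, "degenerate")))
})

test_that("vectorized detection equals the literal reference loop on random traces", {
  for (seed in 1:10) {
    sim <- random_trace(1000 + seed)
    got <- suppressWarnings(detect_microsaccades(sim$trace))
    ref <- ref_detect_microsaccades(sim$trace)
    if (is.null(ref) || nrow(ref) == 0) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(nrow(got), nrow(ref))
      expect_equal(got$onset_ms, ref$onset_ms)
      expect_equal(got$offset_ms, ref$offset_ms)
      expect_equal(got$kind, ref$kind)
      expect_equal(got$amplitude_deg, ref$amplitude_deg, tolerance = 1e-9)
    }
  }
})

test_that("large fast excursions register as saccades, blinks when the pupil drops", {
  n <- 1000
  t <- 0:(n - 1)
  # 10-deg displacement over 30 ms: peak speed ~667 deg/s, accel >> 9500
  ramp <- pmin(pmax((t - 500) / 30, 0), 1)
  x <- 10 * (ramp - sin(2 * pi * ramp) / (2 * pi)) + rnorm(n, 0, 1e-4)
  tr <- gaze_trace("s01", "t1", t, x, rnorm(n, 0, 1e-4))
  ev <- detect_saccades_and_blinks(tr)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$kind, "saccade")
  expect_gt(ev$peak_velocity_deg_s, 35)

  # the same excursion with missing pupil inside it is a blink
  pv <- rep(TRUE, n); pv[505:525] <- FALSE
  tr_b <- gaze_trace("s01", "t1", t, x, rnorm(n, 0, 1e-4), pupil_valid = pv)
  ev_b <- detect_saccades_and_blinks(tr_b)
  expect_equal(ev_b$kind, "blink")

  # slow drift never crosses the saccade criterion
  tr_slow <- gaze_trace("s01", "t1", t, 0.2 * t / 1000, rep(0, n))
  expect_equal(nrow(detect_saccades_and_blinks(tr_slow)), 0)
})

test_that("detected event counts are non-increasing in lambda", {
  for (seed in 1:8) {
    sim <- random_trace(2000 + seed, blink_prob = 0)
    counts <- vapply(c(4, 6, 8), function(l) {
      nrow(suppressWarnings(
        detect_microsaccades(sim$trace, detector_params(lambda = l))))
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("detected events never overlap after merging", {
  for (seed in 1:5) {
    sim <- random_trace(3000 + seed)
    ev <- detect_trial(sim$trace)
    if (nrow(ev) > 1) {
      expect_true(all(ev$onset_ms[-1] > ev$offset_ms[-nrow(ev)]))
    }
  }
})

test_that("fixation checks use the strict 1.5-degree abort rule", {
  tr <- make_flat_trace(x = 0.5)
  expect_true(check_fixation(tr))
  # exactly on the boundary is kept ("more than 1.5 deg" aborts)
  expect_true(check_fixation(make_flat_trace(x = 1.5)))
  expect_false(check_fixation(make_flat_trace(x = 1.6)))
  # invalid-pupil samples do not count against fixation
  n <- 600
  tr2 <- gaze_trace("s01", "t1", 0:(n - 1), c(rep(0, 300), rep(2, 300)),
                    rep(0, n), pupil_valid = c(rep(TRUE, 300), rep(FALSE, 300)))
  expect_true(check_fixation(tr2))
})

test_that("blink-in-video trials are excluded and reported as a fraction", {
  trials <- simulate_behavior(behavior_sim_config(n_subjects = 2,
                                                  n_trials_per_condition = 100),
                              seed = 131, timelines = TRUE)
  trials <- trials[1:100, ]
  # blinks during the video in exactly 2 of 100 trials
  ev <- data.frame(subject = "s01", trial = trials$trial[c(10, 20)],
                   kind = "blink", onset_ms = 500, offset_ms = 600,
                   dx_deg = 0, dy_deg = 0, amplitude_deg = 0,
                   direction_rad = 0, peak_velocity_deg_s = 300)
  res <- apply_trial_exclusions(trials, ev)
  expect_equal(sum(res$trials$excluded), 2)
  expect_equal(res$report$fraction[res$report$reason == "blink_in_video"], 0.02)

  # a blink entirely after the array offset does not exclude
  late <- ev[1, ]
  late$onset_ms <- trials$array_offset_ms[10] + 50
  late$offset_ms <- late$onset_ms + 100
  res2 <- apply_trial_exclusions(trials, late)
  expect_equal(sum(res2$trials$excluded), 0)

  # no blinks anywhere -> no exclusions
  res3 <- apply_trial_exclusions(trials, ev[0, ])
  expect_equal(sum(res3$trials$excluded), 0)

  # unknown trial id in the event table is a join error
  bad <- ev
  bad$trial[1] <- "nope"
  expect_error(apply_trial_exclusions(trials, bad), "unknown trial")
})
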