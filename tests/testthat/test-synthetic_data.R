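test_that("timelines honor the anchor means and the SOA arithmetic", {
  tl200 <- make_timeline(200, jitter_sd_ms = 0)
  expect_equal(tl200$head_motion_onset_ms, 400)
  expect_equal(tl200$head_motion_offset_ms, 1800)
  expect_equal(tl200$body_motion_onset_ms, 600)
  expect_equal(tl200$body_motion_offset_ms, 1700)
  expect_equal(tl200$array_onset_ms, tl200$gaze_completion_ms + 200)
  expect_equal(tl200$array_offset_ms - tl200$array_onset_ms, 800)

  tl500 <- make_timeline(500, jitter_sd_ms = 0)
  expect_equal(tl500$array_onset_ms - tl500$gaze_completion_ms, 500)

  expect_error(make_timeline(300), "200 or 500")

  # Monte-Carlo: jittered head onsets center on 400 ms
  set.seed(21)
  onsets <- vapply(1:1000, function(i) make_timeline(200)$head_motion_onset_ms,
                   numeric(1))
  se <- sd(onsets) / sqrt(length(onsets))
  expect_lt(abs(mean(onsets) - 400), 3 * se + 1e-9)
  # invariants hold under jitter
  tls <- do.call(rbind, lapply(1:50, function(i) make_timeline(500)))
  expect_true(all(tls$head_motion_onset_ms < tls$head_motion_offset_ms))
  expect_true(all(tls$gaze_completion_ms ==
                    pmax(tls$head_motion_offset_ms, tls$body_motion_offset_ms)))
})

test_that("a noiseless config yields a constant trace and empty truth", {
  cfg <- trace_sim_config(drift_sd_deg_per_sqrt_s = 0, ms_rate_hz = 0,
                          noise_sd_deg = 0, blink_prob_per_trial = 0)
  tl <- make_timeline(200, jitter_sd_ms = 0)
  sim <- simulate_trace(cfg, tl, "right")
  expect_equal(diff(range(sim$trace$x_deg)), 0)
  expect_equal(diff(range(sim$trace$y_deg)), 0)
  expect_equal(nrow(sim$truth), 0)
})

test_that("injected events carry their exact displacement and main-sequence peak velocity", {
  set.seed(31)
  cfg <- trace_sim_config(drift_sd_deg_per_sqrt_s = 0, noise_sd_deg = 0,
                          ms_rate_hz = 1.5, blink_prob_per_trial = 0)
  tl <- make_timeline(500, jitter_sd_ms = 0)
  sim <- simulate_trace(cfg, tl, "right")
  tr <- sim$trace
  for (i in seq_len(nrow(sim$truth))) {
    ev <- sim$truth[i, ]
    i0 <- which(tr$t_ms == round(ev$onset_ms))  # nearest sample at onset
    i0 <- if (length(i0)) i0 else which.min(abs(tr$t_ms - ev$onset_ms))
    i1 <- which.min(abs(tr$t_ms - ev$offset_ms))
    # net displacement across the event span matches the truth record
    expect_equal(tr$x_deg[i1 + 1] - tr$x_deg[max(i0 - 1, 1)], ev$dx_deg,
                 tolerance = 0.02)
    expect_equal(ev$amplitude_deg, sqrt(ev$dx_deg^2 + ev$dy_deg^2),
                 tolerance = 1e-12)
    # raised-cosine + slope 60/s: peak velocity = 60 * amplitude
    expect_equal(ev$peak_velocity_deg_s, 60 * ev$amplitude_deg,
                 tolerance = 1e-9)
  }
})

test_that("injected event counts follow the configured Poisson rate", {
  set.seed(41)
  cfg <- trace_sim_config(ms_rate_hz = 1.5, blink_prob_per_trial = 0)
  tl <- make_timeline(500, jitter_sd_ms = 0)
  dur <- tl$array_offset_ms / 1000
  n_trials <- 500
  total <- sum(vapply(seq_len(n_trials), function(i) {
    nrow(simulate_trace(cfg, tl, "right")$truth)
  }, numeric(1)))
  lambda <- 1.5 * dur * n_trials
  expect_lt(abs(total - lambda), 3 * sqrt(lambda))
})

test_that("injected amplitudes follow the configured lognormal and cue bias", {
  set.seed(51)
  cfg <- trace_sim_config(toward_cue_prob = 0.7, blink_prob_per_trial = 0,
                          ms_rate_hz = 2.5)
  tl <- make_timeline(200, jitter_sd_ms = 0)
  truths <- list()
  while (sum(vapply(truths, nrow, numeric(1))) < 5000) {
    truths[[length(truths) + 1L]] <- simulate_trace(cfg, tl, "right")$truth
  }
  tr <- do.call(rbind, truths)
  amp <- tr$amplitude_deg
  ks <- suppressWarnings(
    ks.test(amp, plnorm, meanlog = log(0.26), sdlog = 0.6))
  expect_lt(unname(ks$statistic), 0.05)

  # sub-0.5-deg fraction brackets the published 79.6%
  expect_gt(mean(amp < 0.5), 0.70)
  expect_lt(mean(amp < 0.5), 0.90)

  # horizontal sign toward the cue converges to toward_cue_prob (99% CI)
  p_hat <- mean(tr$dx_deg > 0)
  n <- nrow(tr)
  expect_lt(abs(p_hat - 0.7), 2.576 * sqrt(0.7 * 0.3 / n))
})

test_that("behavioral generator honors the symmetric null and the criterion limit", {
  null_cfg <- behavior_sim_config(
    n_subjects = 10, n_trials_per_condition = 40, dprime_mean = 0,
    dprime_sd = 0, criterion = 0,
    cue_effect_dprime = list(intact = c("200" = 0, "500" = 0),
                             floating_heads = c("200" = 0, "500" = 0),
                             headless_bodies = c("200" = 0, "500" = 0)))
  trials <- simulate_behavior(null_cfg, seed = 61)
  present <- trials$target_present
  hit <- mean(trials$response[present] == "present")
  fa <- mean(trials$response[!present] == "present")
  n_p <- sum(present)
  expect_lt(abs(hit - 0.5), 3 * sqrt(0.25 / n_p))
  expect_lt(abs(fa - 0.5), 3 * sqrt(0.25 / (nrow(trials) - n_p)))

  # criterion -> +Inf: everything is "absent"
  strict <- behavior_sim_config(n_subjects = 2, n_trials_per_condition = 8,
                                criterion = Inf)
  t2 <- simulate_behavior(strict, seed = 62)
  expect_true(all(t2$response == "absent"))

  expect_error(behavior_sim_config(cue_effect_dprime = list()),
               "must not be empty")
  expect_error(behavior_sim_config(n_subjects = 1), ">= 2 subjects")
})

test_that("design cells are balanced at the published proportions", {
  trials <- simulate_behavior(behavior_sim_config(), seed = 71)
  expect_equal(nrow(trials), 30 * 3 * 2 * 60)
  one <- trials[trials$subject == "s01" & trials$condition == "intact" &
                  trials$soa_ms == 200, ]
  expect_equal(nrow(one), 60)
  expect_equal(sum(one$target_present), 30)
  expect_equal(sum(one$cue_validity == "valid"), 15)
  expect_equal(sum(one$cue_validity == "invalid"), 15)
})

test_that("configured sensitivity is recovered through the SDT module", {
  cfg <- behavior_sim_config(
    dprime_mean = 1, dprime_sd = 0, criterion = 0.5,
    cue_effect_dprime = list(intact = c("200" = 0, "500" = 0),
                             floating_heads = c("200" = 0, "500" = 0),
                             headless_bodies = c("200" = 0, "500" = 0)))
  trials <- simulate_behavior(cfg, seed = 81)
  sdt <- tabulate_sdt(trials)
  d_all <- c(sdt$dprime_valid, sdt$dprime_invalid)
  se <- sd(d_all) / sqrt(length(d_all))
  expect_lt(abs(mean(d_all) - 1), 3 * se + 0.05)
})

test_that("a configured cueing effect is recovered within 3 SE at paper scale", {
  cfg <- behavior_sim_config(
    cue_effect_dprime = list(intact = c("200" = 0.4, "500" = 0.4),
                             floating_heads = c("200" = 0.4, "500" = 0.4),
                             headless_bodies = c("200" = 0.4, "500" = 0.4)))
  trials <- simulate_behavior(cfg, seed = 91)
  eff <- cueing_effects(tabulate_sdt(trials))
  g <- eff$group
  for (i in seq_len(nrow(g))) {
    expect_lt(abs(g$mean_delta_dprime[i] - 0.4), 3 * g$se_delta_dprime[i])
  }
})
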