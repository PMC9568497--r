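#' Configuration for fixational-trace simulation
#'
#' Parameters of the synthetic eye-position generator: Brownian fixational
#' drift, Poisson-timed microsaccades with lognormal amplitudes riding a
#' linear main sequence, an optional blink, and additive sensor noise.
#'
#' Defaults emulate a clean tower-mount 1000 Hz recording. The amplitude
#' median (0.26 deg = 15.6 arcmin) matches published fixational statistics,
#' and the lognormal spread 0.6 places roughly 86% of amplitudes below
#' 0.5 deg. The drift and sensor-noise scales are set low enough that the
#' lambda-sigma threshold of a quiet trace sits near 1 deg/s, so the
#' detector's threshold-crossing latency stays within a few milliseconds
#' of the injected onset across the amplitude distribution. The main-sequence slope of 60 /s yields a peak velocity of
#' about 16 deg/s for a median event — comfortably above the detection
#' threshold of a quiet trace but far below the 35 deg/s saccade criterion.
#' With a raised-cosine velocity profile the slope pins the event duration
#' at `2000 / main_seq_slope_per_s` ms (33.3 ms by default); overriding
#' `ms_duration_ms` keeps the displacement exact but makes the realised
#' peak velocity `2 * amplitude / duration` instead.
#'
#' @param drift_sd_deg_per_sqrt_s Diffusion scale of fixational drift
#'   (deg per sqrt-second).
#' @param ms_rate_hz Poisson rate of microsaccades (events/s).
#' @param amp_median_deg Median microsaccade amplitude (deg).
#' @param amp_sigma_log Lognormal log-scale spread of amplitudes.
#' @param toward_cue_prob Probability that an event's horizontal component
#'   points toward the cued side.
#' @param main_seq_slope_per_s Peak velocity / amplitude ratio (1/s).
#' @param ms_duration_ms Event duration; `NULL` derives it from the slope.
#' @param noise_sd_deg Additive white sensor noise per sample (deg).
#' @param blink_prob_per_trial Probability of one blink during the trial.
#' @return An object of class `trace_sim_config`.
#' @export
trace_sim_config <- function(drift_sd_deg_per_sqrt_s = 0.01,
                             ms_rate_hz = 1.5,
                             amp_median_deg = 0.26,
                             amp_sigma_log = 0.6,
                             toward_cue_prob = 0.6,
                             main_seq_slope_per_s = 60,
                             ms_duration_ms = NULL,
                             noise_sd_deg = 5e-4,
                             blink_prob_per_trial = 0.011) {
  if (is.null(ms_duration_ms)) ms_duration_ms <- 2000 / main_seq_slope_per_s
  cfg <- list(drift_sd_deg_per_sqrt_s = drift_sd_deg_per_sqrt_s,
              ms_rate_hz = ms_rate_hz,
              amp_median_deg = amp_median_deg,
              amp_sigma_log = amp_sigma_log,
              toward_cue_prob = toward_cue_prob,
              main_seq_slope_per_s = main_seq_slope_per_s,
              ms_duration_ms = ms_duration_ms,
              noise_sd_deg = noise_sd_deg,
              blink_prob_per_trial = blink_prob_per_trial)
  probs <- c(cfg$toward_cue_prob, cfg$blink_prob_per_trial)
  if (any(probs < 0 | probs > 1)) {
    stop("trace_sim_config: probabilities must lie in [0, 1]", call. = FALSE)
  }
  pos <- c(cfg$ms_rate_hz, cfg$amp_median_deg, cfg$amp_sigma_log,
           cfg$main_seq_slope_per_s, cfg$ms_duration_ms)
  if (any(pos < 0)) {
    stop("trace_sim_config: rates, scales and durations must be >= 0",
         call. = FALSE)
  }
  structure(cfg, class = "trace_sim_config")
}

#' Draw a trial timeline
#'
#' Anchors of one trial: the video starts at 0 ms; head motion spans about
#' 400-1800 ms and body motion about 600-1700 ms (jittered around those
#' means); the gaze cue is complete when both motions have ended; the
#' target/distractor array appears `soa_ms` after cue completion and stays
#' on for 800 ms.
#'
#' @param soa_ms Stimulus-onset asynchrony, 200 or 500 ms.
#' @param jitter_sd_ms SD of Gaussian jitter applied to motion anchors.
#' @param means_ms Named anchor means (head/body motion on/offsets), ms.
#' @return A one-row data.frame of timeline anchors.
#' @export
make_timeline <- function(soa_ms = c(200, 500), jitter_sd_ms = 100,
                          means_ms = c(head_on = 400, head_off = 1800,
                                       body_on = 600, body_off = 1700)) {
  soa_ms <- as.numeric(soa_ms)
  if (length(soa_ms) > 1) soa_ms <- soa_ms[1]
  if (!soa_ms %in% c(200, 500)) {
    stop("make_timeline: soa_ms must be 200 or 500", call. = FALSE)
  }
  for (i in seq_len(100L)) {
    a <- means_ms + stats::rnorm(4, 0, jitter_sd_ms)
    ok <- a["head_on"] >= 0 && a["body_on"] >= 0 &&
      a["head_on"] < a["head_off"] && a["body_on"] < a["body_off"]
    if (ok) {
      gc_ms <- max(a["head_off"], a["body_off"])
      return(data.frame(
        video_onset_ms = 0,
        head_motion_onset_ms = unname(a["head_on"]),
        head_motion_offset_ms = unname(a["head_off"]),
        body_motion_onset_ms = unname(a["body_on"]),
        body_motion_offset_ms = unname(a["body_off"]),
        gaze_completion_ms = unname(gc_ms),
        array_onset_ms = unname(gc_ms + soa_ms),
        array_offset_ms = unname(gc_ms + soa_ms + 800)))
    }
  }
  stop("make_timeline: could not draw a valid timeline in 100 attempts; ",
       "jitter_sd_ms too large for the anchor means", call. = FALSE)
}

.empty_truth <- function() {
  data.frame(subject = character(0), trial = character(0), kind = character(0),
             onset_ms = numeric(0), offset_ms = numeric(0),
             dx_deg = numeric(0), dy_deg = numeric(0),
             amplitude_deg = numeric(0), direction_rad = numeric(0),
             peak_velocity_deg_s = numeric(0))
}

# smooth ballistic step: fraction of displacement completed at phase s in [0,1]
# (integral of a raised-cosine velocity profile; C1, zero endpoint velocity)
.raised_cosine_step <- function(s) s - sin(2 * pi * s) / (2 * pi)

#' Simulate one trial's gaze trace with ground-truth events
#'
#' The trace is fixational drift (a scaled Gaussian random walk) plus
#' Poisson-timed microsaccades with raised-cosine velocity profiles and
#' lognormal amplitudes, optional blink (a fast vertical excursion with the
#' pupil flagged invalid, emulating tracker output during lid closure), and
#' additive white sensor noise. Every injected event is returned with its
#' exact onset, offset, displacement and peak velocity.
#'
#' @param cfg A [trace_sim_config()].
#' @param timeline Output of [make_timeline()]; the default trace length is
#'   its `array_offset_ms`.
#' @param cue_direction `"left"` or `"right"`.
#' @param duration_ms Trace length in ms; must cover the array offset.
#' @param subject_id,trial_id Identifiers stamped on the outputs.
#' @param sample_rate_hz Sampling rate.
#' @return A list with elements `trace` (a [gaze_trace()]) and `truth`
#'   (a data.frame of injected events).
#' @export
simulate_trace <- function(cfg, timeline, cue_direction = c("right", "left"),
                           duration_ms = NULL, subject_id = "s01",
                           trial_id = "t001", sample_rate_hz = 1000) {
  cue_direction <- match.arg(cue_direction)
  if (is.null(duration_ms)) duration_ms <- timeline$array_offset_ms
  if (duration_ms < timeline$array_offset_ms) {
    stop("simulate_trace: duration_ms must cover the array offset",
         call. = FALSE)
  }
  dt_ms <- 1000 / sample_rate_hz
  n <- floor(duration_ms / dt_ms) + 1L
  t_ms <- (seq_len(n) - 1L) * dt_ms
  dt_s <- dt_ms / 1000

  x <- cumsum(stats::rnorm(n, 0, cfg$drift_sd_deg_per_sqrt_s * sqrt(dt_s)))
  y <- cumsum(stats::rnorm(n, 0, cfg$drift_sd_deg_per_sqrt_s * sqrt(dt_s)))

  dur_ms <- cfg$ms_duration_ms
  truth <- .empty_truth()

  # Poisson microsaccade onsets; whole set redrawn if events would overlap
  n_ev <- stats::rpois(1, cfg$ms_rate_hz * duration_ms / 1000)
  onsets <- numeric(0)
  if (n_ev > 0) {
    lo <- dt_ms
    hi <- duration_ms - dur_ms - dt_ms
    if (hi <= lo) n_ev <- 0L
    for (try in seq_len(200L)) {
      if (n_ev == 0L) break
      cand <- sort(stats::runif(n_ev, lo, hi))
      if (n_ev == 1L || all(diff(cand) > dur_ms + 50)) {
        onsets <- cand
        break
      }
    }
    if (n_ev > 0L && length(onsets) == 0L) {
      # rate too high for non-overlapping placement; thin to what fits
      onsets <- seq(lo, hi, by = dur_ms + 50)[seq_len(min(n_ev, floor((hi - lo) / (dur_ms + 50))))]
    }
  }

  cue_sign <- if (cue_direction == "right") 1 else -1
  for (o in onsets) {
    amp <- stats::rlnorm(1, meanlog = log(cfg$amp_median_deg),
                         sdlog = cfg$amp_sigma_log)
    toward <- stats::runif(1) < cfg$toward_cue_prob
    sgn <- if (toward) cue_sign else -cue_sign
    theta <- stats::runif(1, -pi / 2, pi / 2)   # elevation; horizontal sign fixed by sgn
    ux <- sgn * cos(theta)
    uy <- sin(theta)
    ramp <- pmin(pmax((t_ms - o) / dur_ms, 0), 1)
    step <- .raised_cosine_step(ramp)
    x <- x + amp * ux * step
    y <- y + amp * uy * step
    truth <- rbind(truth, data.frame(
      subject = subject_id, trial = trial_id, kind = "microsaccade",
      onset_ms = o, offset_ms = o + dur_ms,
      dx_deg = amp * ux, dy_deg = amp * uy, amplitude_deg = amp,
      direction_rad = atan2(uy, ux),
      peak_velocity_deg_s = 2 * amp / (dur_ms / 1000)))
  }

  pupil_valid <- rep(TRUE, n)
  if (stats::runif(1) < cfg$blink_prob_per_trial) {
    # 100-ms blink: 6-deg downward excursion (35 ms down, 30 hold, 35 up)
    b_on <- stats::runif(1, 50, max(51, duration_ms - 150))
    idx <- t_ms >= b_on & t_ms <= b_on + 100
    down <- .raised_cosine_step(pmin(pmax((t_ms - b_on) / 35, 0), 1))
    up <- .raised_cosine_step(pmin(pmax((t_ms - b_on - 65) / 35, 0), 1))
    y <- y - 6 * (down - up)
    pupil_valid[idx] <- FALSE
    truth <- rbind(truth, data.frame(
      subject = subject_id, trial = trial_id, kind = "blink",
      onset_ms = b_on, offset_ms = b_on + 100,
      dx_deg = 0, dy_deg = 0, amplitude_deg = 0, direction_rad = 0,
      peak_velocity_deg_s = 2 * 6 / 0.035))
  }

  x <- x + stats::rnorm(n, 0, cfg$noise_sd_deg)
  y <- y + stats::rnorm(n, 0, cfg$noise_sd_deg)

  truth <- truth[order(truth$onset_ms), , drop = FALSE]
  rownames(truth) <- NULL
  list(trace = gaze_trace(subject_id, trial_id, t_ms, x, y, pupil_valid,
                          sample_rate_hz = sample_rate_hz),
       truth = truth)
}

#' Configuration for behavioral-trial simulation
#'
#' An equal-variance signal-detection observer with subject-level
#' heterogeneity: each subject's base sensitivity is drawn from a truncated
#' normal, and a condition-by-SOA cueing effect shifts sensitivity by plus
#' or minus half the configured amount on valid/invalid trials.
#'
#' Defaults follow the published design: 30 subjects, 120 trials per
#' condition (60 per SOA), 50% target presence, 50% cue validity among
#' present trials, mean sensitivity 0.95 with criterion 0.75 (false-alarm
#' rate near 0.23), and the published valid-minus-invalid sensitivity
#' shifts per condition and SOA — sustained for the intact condition,
#' transient (large at 200 ms, near zero at 500 ms) for floating heads and
#' headless bodies.
#'
#' @param n_subjects Number of subjects.
#' @param n_trials_per_condition Trials per condition (split over 2 SOAs).
#' @param dprime_mean,dprime_sd Population sensitivity distribution.
#' @param criterion Decision threshold on the internal-signal axis.
#' @param cue_effect_dprime Named list `cond -> c("200" = ..., "500" = ...)`
#'   of additive valid-minus-invalid sensitivity shifts.
#' @param p_target Probability a trial is target-present.
#' @param p_valid Cue validity among target-present trials.
#' @return An object of class `behavior_sim_config`.
#' @export
behavior_sim_config <- function(n_subjects = 30,
                                n_trials_per_condition = 120,
                                dprime_mean = 0.95,
                                dprime_sd = 0.4,
                                criterion = 0.75,
                                cue_effect_dprime = list(
                                  intact = c("200" = 0.31, "500" = 0.41),
                                  floating_heads = c("200" = 0.29, "500" = 0.05),
                                  headless_bodies = c("200" = 0.22, "500" = 0.07)),
                                p_target = 0.5,
                                p_valid = 0.5) {
  if (n_subjects < 2) stop("behavior_sim_config: need >= 2 subjects", call. = FALSE)
  if (dprime_sd < 0) stop("behavior_sim_config: dprime_sd must be >= 0", call. = FALSE)
  if (length(cue_effect_dprime) == 0) {
    stop("behavior_sim_config: cue_effect_dprime must not be empty", call. = FALSE)
  }
  probs <- c(p_target, p_valid)
  if (any(probs < 0 | probs > 1)) {
    stop("behavior_sim_config: probabilities must lie in [0, 1]", call. = FALSE)
  }
  missing <- setdiff(.conditions, names(cue_effect_dprime))
  if (length(missing)) {
    stop("behavior_sim_config: cue_effect_dprime missing condition(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(list(n_subjects = n_subjects,
                 n_trials_per_condition = n_trials_per_condition,
                 dprime_mean = dprime_mean, dprime_sd = dprime_sd,
                 criterion = criterion, cue_effect_dprime = cue_effect_dprime,
                 p_target = p_target, p_valid = p_valid),
            class = "behavior_sim_config")
}

#' Simulate a cohort of behavioral trials
#'
#' Each subject completes `n_trials_per_condition` trials per condition,
#' split evenly over the two SOAs with exact 50/50 target presence and cue
#' validity (matching a counterbalanced design). On target-present trials
#' the internal signal is Normal(d_s +/- cue_effect/2, 1) for valid/invalid
#' cues; target-absent signals are Normal(0, 1); the response is "present"
#' when the signal exceeds the criterion.
#'
#' @param cfg A [behavior_sim_config()].
#' @param seed Optional integer seed.
#' @param timelines If TRUE, attach jittered timeline anchors per trial
#'   (needed when traces or event alignment will be simulated).
#' @return A trial data.frame (one row per trial).
#' @export
simulate_behavior <- function(cfg, seed = NULL, timelines = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  soas <- c(200, 500)
  conds <- names(cfg$cue_effect_dprime)
  n_cell <- round(cfg$n_trials_per_condition / length(soas))
  n_present <- round(n_cell * cfg$p_target)
  n_absent <- n_cell - n_present
  n_valid <- round(n_present * cfg$p_valid)

  # subject base sensitivities, truncated at zero
  d_s <- stats::rnorm(cfg$n_subjects, cfg$dprime_mean, cfg$dprime_sd)
  while (any(d_s < 0)) {
    d_s[d_s < 0] <- stats::rnorm(sum(d_s < 0), cfg$dprime_mean, cfg$dprime_sd)
  }

  cell_present <- c(rep(TRUE, n_present), rep(FALSE, n_absent))
  cell_validity <- c(rep("valid", n_valid),
                     rep("invalid", n_present - n_valid),
                     rep("not_applicable", n_absent))
  rows <- vector("list", cfg$n_subjects * length(conds) * length(soas))
  k <- 0L
  for (s in seq_len(cfg$n_subjects)) {
    for (cond in conds) {
      for (soa in soas) {
        k <- k + 1L
        ce <- cfg$cue_effect_dprime[[cond]][[as.character(soa)]]
        mu <- ifelse(cell_present,
                     d_s[s] + ifelse(cell_validity == "valid", ce / 2, -ce / 2),
                     0)
        signal <- stats::rnorm(n_cell, mu, 1)
        rows[[k]] <- data.frame(
          subject = sprintf("s%02d", s),
          trial = sprintf("s%02d_%s_%d_%03d", s, cond, soa, seq_len(n_cell)),
          condition = cond, soa_ms = soa,
          target_present = cell_present,
          cue_validity = cell_validity,
          cue_direction = sample(c("left", "right"), n_cell, replace = TRUE),
          response = ifelse(signal > cfg$criterion, "present", "absent"),
          excluded = FALSE, exclusion_reason = "none")
      }
    }
  }
  trials <- do.call(rbind, rows)
  if (timelines) {
    tl <- do.call(rbind, lapply(trials$soa_ms, make_timeline))
    trials <- cbind(trials, tl)
  }
  rownames(trials) <- NULL
  .validate_trials(trials)
}

#' Simulate gaze traces for a set of trials
#'
#' Produces one fixational trace (with ground-truth events) per trial row,
#' using each trial's timeline and cue direction. Trials must carry
#' timeline columns (see [simulate_behavior()] with `timelines = TRUE`).
#'
#' @param trials Trial data.frame with timeline anchors.
#' @param cfg A [trace_sim_config()].
#' @param seed Optional integer seed.
#' @return A list with `traces` (list of [gaze_trace()]) and `truth`
#'   (data.frame of all injected events).
#' @export
simulate_traces_for_trials <- function(trials, cfg = trace_sim_config(),
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!"array_offset_ms" %in% names(trials)) {
    stop("simulate_traces_for_trials: trials lack timeline anchors", call. = FALSE)
  }
  out <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    out[[i]] <- simulate_trace(cfg, trials[i, ], trials$cue_direction[i],
                               subject_id = trials$subject[i],
                               trial_id = trials$trial[i])
  }
  list(traces = lapply(out, `[[`, "trace"),
       truth = do.call(rbind, lapply(out, `[[`, "truth")))
}

#' Simulate a gaze-annotation set
#'
#' Stand-in for human annotations of the gazed location in video frames:
#' each video has one true gazed-head location per frame, and each
#' annotator reports it with isotropic Gaussian error. Used to exercise the
#' gaze-information metrics (estimation error and permutation baseline).
#'
#' @param n_videos Number of videos (trials).
#' @param n_frames Frames annotated per video.
#' @param n_annotators Annotators per frame.
#' @param error_sd_px Annotator error SD in pixels.
#' @param condition Condition label stamped on the rows.
#' @param geometry A [screen_geometry()] bounding the points.
#' @param seed Optional integer seed.
#' @return Annotation data.frame with columns `video_id`, `condition`,
#'   `frame_index`, `annotator_id`, `ax_px`, `ay_px`, `tx_px`, `ty_px`.
#' @export
simulate_annotations <- function(n_videos = 10, n_frames = 5,
                                 n_annotators = 3, error_sd_px = 20,
                                 condition = "intact",
                                 geometry = screen_geometry(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  margin <- 0.15
  for (v in seq_len(n_videos)) {
    tx <- stats::runif(1, margin * geometry$width_px, (1 - margin) * geometry$width_px)
    ty <- stats::runif(1, margin * geometry$height_px, (1 - margin) * geometry$height_px)
    for (f in seq_len(n_frames)) {
      ax <- pmin(pmax(tx + stats::rnorm(n_annotators, 0, error_sd_px), 0),
                 geometry$width_px)
      ay <- pmin(pmax(ty + stats::rnorm(n_annotators, 0, error_sd_px), 0),
                 geometry$height_px)
      rows[[length(rows) + 1L]] <- data.frame(
        video_id = sprintf("v%02d", v), condition = condition,
        frame_index = f, annotator_id = sprintf("a%d", seq_len(n_annotators)),
        ax_px = ax, ay_px = ay, tx_px = tx, ty_px = ty)
    }
  }
  do.call(rbind, rows)
}
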