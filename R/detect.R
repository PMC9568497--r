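#' Detector parameters
#'
#' Settings of the velocity-threshold event detector. The microsaccade
#' threshold is `lambda` times a median-based robust estimate of the
#' velocity SD within each trial (per component); saccades additionally
#' require speed above `saccade_velocity_deg_s` with peak acceleration
#' above `saccade_accel_deg_s2`. "Intervals longer than 12 ms" is applied
#' conservatively in both readings: events must last at least
#' `min_duration_ms`, and events separated by less than `merge_gap_ms` are
#' merged.
#'
#' @param lambda Threshold multiplier on the robust velocity SD.
#' @param min_duration_ms Minimum event duration (offset - onset), ms.
#' @param saccade_velocity_deg_s Scalar speed criterion for saccades.
#' @param saccade_accel_deg_s2 Peak-acceleration criterion for saccades.
#' @param velocity_window_samples Moving-average derivative span (odd).
#' @param merge_gap_ms Events closer than this merge into one.
#' @param fixation_radius_deg Fixation-break radius.
#' @param criterion `"elliptical"` tests (vx/ex)^2 + (vy/ey)^2 > 1 per
#'   component; `"scalar"` tests speed against lambda times the robust SD
#'   of speed.
#' @param max_amplitude_deg Optional microsaccade amplitude cap; events
#'   above it are labelled saccades. `NULL` (default) disables the cap.
#' @return An object of class `detector_params`.
#' @export
detector_params <- function(lambda = 6, min_duration_ms = 12,
                            saccade_velocity_deg_s = 35,
                            saccade_accel_deg_s2 = 9500,
                            velocity_window_samples = 5,
                            merge_gap_ms = 12,
                            fixation_radius_deg = 1.5,
                            criterion = c("elliptical", "scalar"),
                            max_amplitude_deg = NULL) {
  criterion <- match.arg(criterion)
  vals <- c(lambda, min_duration_ms, saccade_velocity_deg_s,
            saccade_accel_deg_s2, velocity_window_samples, merge_gap_ms,
            fixation_radius_deg)
  if (any(vals <= 0)) stop("detector_params: all values must be > 0", call. = FALSE)
  if (velocity_window_samples %% 2 != 1 || velocity_window_samples < 3) {
    stop("detector_params: velocity_window_samples must be odd and >= 3",
         call. = FALSE)
  }
  structure(list(lambda = lambda, min_duration_ms = min_duration_ms,
                 saccade_velocity_deg_s = saccade_velocity_deg_s,
                 saccade_accel_deg_s2 = saccade_accel_deg_s2,
                 velocity_window_samples = velocity_window_samples,
                 merge_gap_ms = merge_gap_ms,
                 fixation_radius_deg = fixation_radius_deg,
                 criterion = criterion,
                 max_amplitude_deg = max_amplitude_deg),
            class = "detector_params")
}

#' Per-sample velocity, speed and acceleration of a gaze trace
#'
#' Velocities use a centered moving-average derivative: with half-width
#' k = (window - 1) / 2,
#' `v_n = (sum_{j=1..k} x_{n+j} - sum_{j=1..k} x_{n-j}) / (k (k+1) dt)`,
#' which for the default 5-sample window is the classic
#' `(x_{n+2} + x_{n+1} - x_{n-1} - x_{n-2}) / (6 dt)` filter. Samples near
#' the trace boundary use a shrunken symmetric window, and the first/last
#' samples use one-sided differences. Acceleration is the centered
#' difference of speed.
#'
#' @param trace A [gaze_trace()].
#' @param window Odd number of samples in the derivative span.
#' @return A data.frame with columns `vx`, `vy`, `speed` (deg/s) and
#'   `accel` (deg/s^2), one row per sample.
#' @export
compute_velocity <- function(trace, window = 5) {
  stopifnot(inherits(trace, "gaze_trace"))
  if (window %% 2 != 1 || window < 3) {
    stop("compute_velocity: window must be odd and >= 3", call. = FALSE)
  }
  n <- length(trace$t_ms)
  if (n < window) stop("compute_velocity: trace shorter than window", call. = FALSE)
  dt_s <- 1 / trace$sample_rate_hz
  k <- (window - 1) %/% 2

  deriv <- function(p) {
    v <- numeric(n)
    # interior: full or shrunken symmetric window
    cums <- cumsum(p)
    for (kk in seq_len(k)) {
      # samples whose maximal symmetric half-width is exactly kk
      lo <- kk + 1L
      hi <- n - kk
      idx <- if (kk < k) c(lo, hi) else lo:hi
      idx <- idx[idx >= lo & idx <= hi]
      if (!length(idx)) next
      fwd <- cums[idx + kk] - cums[idx]
      bwd <- cums[idx - 1L] - c(0, cums)[idx - kk]
      v[idx] <- (fwd - bwd) / (kk * (kk + 1) * dt_s)
    }
    v[1] <- (p[2] - p[1]) / dt_s
    v[n] <- (p[n] - p[n - 1]) / dt_s
    v
  }
  vx <- deriv(trace$x_deg)
  vy <- deriv(trace$y_deg)
  speed <- sqrt(vx^2 + vy^2)
  accel <- numeric(n)
  accel[2:(n - 1)] <- (speed[3:n] - speed[1:(n - 2)]) / (2 * dt_s)
  accel[1] <- (speed[2] - speed[1]) / dt_s
  accel[n] <- (speed[n] - speed[n - 1]) / dt_s
  data.frame(vx = vx, vy = vy, speed = speed, accel = accel)
}

#' Robust within-trial velocity threshold
#'
#' The per-component detection threshold: `lambda` times the median-based
#' robust scale `sigma = sqrt(median(v^2) - median(v)^2)` of each velocity
#' component, computed within the trial.
#'
#' @param vx,vy Per-sample velocity components (deg/s).
#' @param lambda Threshold multiplier.
#' @return Named vector `c(eta_x, eta_y)` in deg/s.
#' @export
estimate_threshold <- function(vx, vy, lambda = 6) {
  keep <- is.finite(vx) & is.finite(vy)
  vx <- vx[keep]; vy <- vy[keep]
  if (length(vx) < 10) {
    stop("estimate_threshold: need >= 10 finite samples", call. = FALSE)
  }
  sx <- sqrt(max(stats::median(vx^2) - stats::median(vx)^2, 0))
  sy <- sqrt(max(stats::median(vy^2) - stats::median(vy)^2, 0))
  if (sx <= 0 || sy <= 0) {
    stop("estimate_threshold: degenerate trial (zero robust velocity scale)",
         call. = FALSE)
  }
  c(eta_x = lambda * sx, eta_y = lambda * sy)
}

# runs of TRUE in a logical vector -> matrix of (start, end) indices
.runs_of <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

# indices within k samples of an invalid-pupil sample
.near_invalid <- function(pupil_valid, k) {
  bad <- !pupil_valid
  if (!any(bad)) return(bad)
  n <- length(bad)
  out <- bad
  for (j in seq_len(k)) {
    out <- out | c(rep(FALSE, j), bad[seq_len(n - j)]) |
      c(bad[(j + 1):n], rep(FALSE, j))
  }
  out
}

.summarize_event <- function(trace, vel, i0, i1, kind) {
  data.frame(subject = trace$subject_id, trial = trace$trial_id, kind = kind,
             onset_ms = trace$t_ms[i0], offset_ms = trace$t_ms[i1],
             dx_deg = trace$x_deg[i1] - trace$x_deg[i0],
             dy_deg = trace$y_deg[i1] - trace$y_deg[i0],
             amplitude_deg = sqrt((trace$x_deg[i1] - trace$x_deg[i0])^2 +
                                    (trace$y_deg[i1] - trace$y_deg[i0])^2),
             direction_rad = atan2(trace$y_deg[i1] - trace$y_deg[i0],
                                   trace$x_deg[i1] - trace$x_deg[i0]),
             peak_velocity_deg_s = max(vel$speed[i0:i1]))
}

# merge run list (sample indices) when separated by < gap_samples
.merge_runs <- function(runs, gap_samples) {
  if (nrow(runs) <= 1) return(runs)
  out <- runs[1, , drop = FALSE]
  for (i in 2:nrow(runs)) {
    if (runs[i, "start"] - out[nrow(out), "end"] - 1L < gap_samples) {
      out[nrow(out), "end"] <- runs[i, "end"]
    } else {
      out <- rbind(out, runs[i, , drop = FALSE])
    }
  }
  out
}

.classify_event <- function(trace, vel, i0, i1, params) {
  if (any(!trace$pupil_valid[i0:i1])) return("blink")
  sac <- max(vel$speed[i0:i1]) > params$saccade_velocity_deg_s &&
    max(abs(vel$accel[i0:i1])) > params$saccade_accel_deg_s2
  if (sac) return("saccade")
  if (!is.null(params$max_amplitude_deg)) {
    amp <- sqrt((trace$x_deg[i1] - trace$x_deg[i0])^2 +
                  (trace$y_deg[i1] - trace$y_deg[i0])^2)
    if (amp > params$max_amplitude_deg) return("saccade")
  }
  "microsaccade"
}

#' Detect microsaccades (velocity-threshold criterion)
#'
#' Candidate samples exceed the trial-wise lambda-sigma threshold
#' (elliptical per-component test by default); runs of candidates lasting
#' at least `min_duration_ms` become events, events closer than
#' `merge_gap_ms` merge, and each event is summarized by its net
#' displacement, amplitude, direction and peak velocity. Events containing
#' invalid-pupil samples are classified as blinks; events that also meet
#' the saccade velocity-plus-acceleration criteria are labelled saccades.
#' Samples within the derivative half-window of an invalid-pupil span
#' cannot seed events.
#'
#' A degenerate trial (zero robust velocity scale) yields an empty event
#' table with a warning and attribute `degenerate = TRUE`.
#'
#' @param trace A [gaze_trace()].
#' @param params A [detector_params()].
#' @return Event data.frame (possibly zero rows), ordered by onset.
#' @export
detect_microsaccades <- function(trace, params = detector_params()) {
  vel <- compute_velocity(trace, params$velocity_window_samples)
  eta <- tryCatch(
    if (params$criterion == "elliptical") {
      estimate_threshold(vel$vx, vel$vy, params$lambda)
    } else {
      s <- sqrt(max(stats::median(vel$speed^2) - stats::median(vel$speed)^2, 0))
      if (s <= 0) stop("degenerate")
      c(eta_s = params$lambda * s)
    },
    error = function(e) NULL)
  empty <- .empty_truth()
  if (is.null(eta)) {
    warning("detect_microsaccades: degenerate velocity scale in trial ",
            trace$trial_id, "; no events detected")
    attr(empty, "degenerate") <- TRUE
    return(empty)
  }
  crit <- if (params$criterion == "elliptical") {
    (vel$vx / eta["eta_x"])^2 + (vel$vy / eta["eta_y"])^2 > 1
  } else {
    vel$speed > eta["eta_s"]
  }
  k <- (params$velocity_window_samples - 1) %/% 2
  crit <- crit & !.near_invalid(trace$pupil_valid, k)
  crit[is.na(crit)] <- FALSE
  .events_from_mask(trace, vel, crit, params)
}

.events_from_mask <- function(trace, vel, mask, params,
                              require_accel = FALSE) {
  dt_ms <- 1000 / trace$sample_rate_hz
  runs <- .runs_of(mask)
  if (nrow(runs)) {
    dur <- (runs[, "end"] - runs[, "start"]) * dt_ms
    runs <- runs[dur >= params$min_duration_ms, , drop = FALSE]
  }
  if (nrow(runs)) {
    runs <- .merge_runs(runs, gap_samples = ceiling(params$merge_gap_ms / dt_ms))
  }
  if (require_accel && nrow(runs)) {
    keep <- apply(runs, 1, function(r) {
      max(abs(vel$accel[r["start"]:r["end"]])) > params$saccade_accel_deg_s2
    })
    runs <- runs[keep, , drop = FALSE]
  }
  if (!nrow(runs)) return(.empty_truth())
  out <- do.call(rbind, lapply(seq_len(nrow(runs)), function(i) {
    i0 <- runs[i, "start"]; i1 <- runs[i, "end"]
    kind <- if (require_accel) {
      if (any(!trace$pupil_valid[i0:i1])) "blink" else "saccade"
    } else {
      .classify_event(trace, vel, i0, i1, params)
    }
    .summarize_event(trace, vel, i0, i1, kind)
  }))
  rownames(out) <- NULL
  out
}

#' Detect saccades and blinks (scalar velocity + acceleration criteria)
#'
#' Runs of samples with speed above `saccade_velocity_deg_s` lasting at
#' least `min_duration_ms` qualify as saccades when the peak absolute
#' acceleration within the run exceeds `saccade_accel_deg_s2`. Any such
#' event containing invalid-pupil samples is a blink (the tracker reports
#' a missing pupil during a saccade-like excursion).
#'
#' @param trace A [gaze_trace()].
#' @param params A [detector_params()].
#' @return Event data.frame of saccades and blinks.
#' @export
detect_saccades_and_blinks <- function(trace, params = detector_params()) {
  vel <- compute_velocity(trace, params$velocity_window_samples)
  mask <- vel$speed > params$saccade_velocity_deg_s
  .events_from_mask(trace, vel, mask, params, require_accel = TRUE)
}

#' Detect all ocular events in one trial
#'
#' Combines the lambda-sigma microsaccade detector with the scalar saccade
#' and blink detector: events from the former take precedence; saccade or
#' blink events from the latter are added when they do not overlap an
#' already-detected event (this catches blinks whose samples are masked
#' out of the microsaccade candidate set).
#'
#' @param trace A [gaze_trace()].
#' @param params A [detector_params()].
#' @return Event data.frame ordered by onset.
#' @export
detect_trial <- function(trace, params = detector_params()) {
  ev <- suppressWarnings(detect_microsaccades(trace, params))
  sb <- detect_saccades_and_blinks(trace, params)
  if (nrow(sb)) {
    overlaps <- vapply(seq_len(nrow(sb)), function(i) {
      any(sb$onset_ms[i] <= ev$offset_ms & sb$offset_ms[i] >= ev$onset_ms)
    }, logical(1))
    ev <- rbind(ev, sb[!overlaps, , drop = FALSE])
  }
  ev <- ev[order(ev$onset_ms), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Check fixation maintenance
#'
#' TRUE when every valid-pupil sample stays within `radius_deg` of the
#' screen center (fixations exactly on the boundary are kept: the abort
#' rule is "more than" the radius).
#'
#' @param trace A [gaze_trace()] in centered degrees.
#' @param radius_deg Abort radius.
#' @return Logical scalar.
#' @export
check_fixation <- function(trace, radius_deg = 1.5) {
  r <- sqrt(trace$x_deg^2 + trace$y_deg^2)
  all(r[trace$pupil_valid] <= radius_deg)
}

#' Apply trial-exclusion rules
#'
#' Excludes trials with a blink event overlapping the video presentation
#' (video onset through array offset) and trials with a fixation break,
#' and reports counts and fractions per reason.
#'
#' @param trials Trial data.frame with timeline anchors.
#' @param events Event data.frame covering the same trials.
#' @param traces Optional list of [gaze_trace()] (named by trial or in
#'   trial order) for the fixation check; skipped when NULL.
#' @param params A [detector_params()] (fixation radius).
#' @return A list with `trials` (exclusion flags filled in) and `report`
#'   (data.frame of counts and fractions per reason).
#' @export
apply_trial_exclusions <- function(trials, events, traces = NULL,
                                   params = detector_params()) {
  if (nrow(events) && !all(events$trial %in% trials$trial)) {
    stop("apply_trial_exclusions: event table references unknown trial id(s): ",
         paste(utils::head(setdiff(events$trial, trials$trial)), collapse = ", "),
         call. = FALSE)
  }
  if (!"array_offset_ms" %in% names(trials)) {
    stop("apply_trial_exclusions: trials lack timeline anchors", call. = FALSE)
  }
  trials$excluded <- FALSE
  trials$exclusion_reason <- "none"

  blinks <- events[events$kind == "blink", , drop = FALSE]
  if (nrow(blinks)) {
    for (i in seq_len(nrow(blinks))) {
      j <- match(blinks$trial[i], trials$trial)
      in_video <- blinks$onset_ms[i] <= trials$array_offset_ms[j] &&
        blinks$offset_ms[i] >= trials$video_onset_ms[j]
      if (in_video && !trials$excluded[j]) {
        trials$excluded[j] <- TRUE
        trials$exclusion_reason[j] <- "blink_in_video"
      }
    }
  }
  if (!is.null(traces)) {
    ids <- vapply(traces, function(tr) tr$trial_id, character(1))
    for (i in seq_along(traces)) {
      j <- match(ids[i], trials$trial)
      if (is.na(j) || trials$excluded[j]) next
      if (!check_fixation(traces[[i]], params$fixation_radius_deg)) {
        trials$excluded[j] <- TRUE
        trials$exclusion_reason[j] <- "fixation_break"
      }
    }
  }
  n <- nrow(trials)
  report <- data.frame(
    reason = .exclusion_reasons,
    n = vapply(.exclusion_reasons,
               function(r) sum(trials$exclusion_reason == r), numeric(1)))
  report$fraction <- report$n / n
  list(trials = trials, report = report)
}

#' Match detected events against ground truth
#'
#' Greedy one-to-one matching of detected to injected events by onset
#' proximity, used to score the detector against the simulator's truth.
#'
#' @param truth,detected Event data.frames (same trial set).
#' @param tol_ms Maximum |onset difference| for a match.
#' @param kind Event kind to score (default microsaccades).
#' @return A list with `recovery` (fraction of truth matched), `spurious`
#'   (fraction of detections unmatched), and `pairs` (data.frame of
#'   matched truth/detected amplitudes and onsets).
#' @export
match_events <- function(truth, detected, tol_ms = 5, kind = "microsaccade") {
  tr <- truth[truth$kind == kind, , drop = FALSE]
  de <- detected[detected$kind == kind, , drop = FALSE]
  pairs <- list()
  used <- rep(FALSE, nrow(de))
  for (i in seq_len(nrow(tr))) {
    cand <- which(!used & de$trial == tr$trial[i] &
                    abs(de$onset_ms - tr$onset_ms[i]) <= tol_ms)
    if (length(cand)) {
      j <- cand[which.min(abs(de$onset_ms[cand] - tr$onset_ms[i]))]
      used[j] <- TRUE
      pairs[[length(pairs) + 1L]] <- data.frame(
        trial = tr$trial[i],
        onset_true = tr$onset_ms[i], onset_det = de$onset_ms[j],
        amp_true = tr$amplitude_deg[i], amp_det = de$amplitude_deg[j])
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else NULL
  n_match <- if (is.null(pairs)) 0L else nrow(pairs)
  list(recovery = if (nrow(tr)) n_match / nrow(tr) else NA_real_,
       spurious = if (nrow(de)) (nrow(de) - n_match) / nrow(de) else NA_real_,
       pairs = pairs)
}
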