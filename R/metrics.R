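#' Align event onsets to a trial anchor
#'
#' Adds `onset_rel_ms` = onset minus the requested timeline anchor of the
#' event's trial. Events are never dropped; callers window them as needed.
#'
#' @param events Event data.frame.
#' @param trials Trial data.frame with timeline anchors.
#' @param anchor `"video_onset"`, `"head_motion_onset"` or `"array_onset"`.
#' @return `events` with columns `onset_rel_ms`, `cue_direction`,
#'   `cue_validity`, `condition`, `soa_ms` joined in.
#' @export
align_events <- function(events, trials,
                         anchor = c("video_onset", "head_motion_onset",
                                    "array_onset")) {
  anchor <- match.arg(anchor)
  col <- paste0(anchor, "_ms")
  if (!col %in% names(trials)) {
    stop("align_events: trials lack anchor column ", col, call. = FALSE)
  }
  j <- match(events$trial, trials$trial)
  if (anyNA(j)) {
    stop("align_events: anchor undefined for trial(s) ",
         paste(utils::head(unique(events$trial[is.na(j)])), collapse = ", "),
         call. = FALSE)
  }
  events$onset_rel_ms <- events$onset_ms - trials[[col]][j]
  for (v in c("cue_direction", "cue_validity", "condition", "soa_ms", "subject")) {
    if (v %in% names(trials) && !v %in% names(events)) {
      events[[v]] <- trials[[v]][j]
    }
  }
  events
}

#' Microsaccade rate curve
#'
#' Per subject, event onsets are counted in uniform bins and normalized by
#' (number of contributing trials x bin width in seconds), then smoothed
#' with a centered boxcar. The group curve is the across-subject mean with
#' a 95% t-interval. Bins within half a smoothing window of the span edges
#' are masked (the boxcar would be acausal there).
#'
#' @param events Aligned events (see [align_events()]); only rows with
#'   `kind == "microsaccade"` are used.
#' @param trials Trial data.frame (defines trial counts per subject).
#' @param span_ms Length-2 analysis span in aligned time.
#' @param bin_ms Bin width.
#' @param smooth_ms Boxcar width (0 disables smoothing).
#' @return Data.frame with `bin_center_ms`, `rate_hz`, `ci_low`, `ci_high`,
#'   `n_subjects`, plus attribute `per_subject` (matrix subjects x bins).
#' @export
rate_curve <- function(events, trials, span_ms = c(0, 1000), bin_ms = 1,
                       smooth_ms = 100) {
  ev <- events[events$kind == "microsaccade", , drop = FALSE]
  breaks <- seq(span_ms[1], span_ms[2], by = bin_ms)
  centers <- breaks[-length(breaks)] + bin_ms / 2
  subjects <- sort(unique(trials$subject))
  n_trials <- vapply(subjects, function(s) sum(trials$subject == s), numeric(1))
  per_subj <- t(vapply(seq_along(subjects), function(i) {
    e <- ev[ev$subject == subjects[i], , drop = FALSE]
    counts <- graphics::hist(e$onset_rel_ms[e$onset_rel_ms >= span_ms[1] &
                                              e$onset_rel_ms < span_ms[2]],
                             breaks = breaks, plot = FALSE)$counts
    r <- counts / (n_trials[i] * bin_ms / 1000)
    if (smooth_ms > 0) {
      w <- max(1L, round(smooth_ms / bin_ms))
      if (w %% 2 == 0) w <- w + 1L
      r <- stats::filter(r, rep(1 / w, w), sides = 2)
      r <- as.numeric(r)  # edge bins -> NA (acausal), masked
    }
    r
  }, numeric(length(centers))))
  mean_rate <- colMeans(per_subj)
  se <- apply(per_subj, 2, stats::sd) / sqrt(length(subjects))
  tcrit <- stats::qt(0.975, df = max(length(subjects) - 1, 1))
  out <- data.frame(bin_center_ms = centers, rate_hz = mean_rate,
                    ci_low = mean_rate - tcrit * se,
                    ci_high = mean_rate + tcrit * se,
                    n_subjects = length(subjects))
  attr(out, "per_subject") <- per_subj
  out
}

#' Toward-cue direction bias in sliding windows
#'
#' Within each window of aligned time, an event counts as "toward" the cue
#' when the sign of its horizontal displacement matches the cued side
#' (right cue: dx > 0; left cue: dx < 0); dx = 0 counts as neither. The
#' per-trial proportion toward is n_toward / (n_toward + n_away) over
#' trials with at least one nonzero-dx event in the window, and the
#' per-trial signed degrees toward the cue is the sum of +/-dx with + when
#' toward. Aggregates are means over contributing trials.
#'
#' @param events Aligned events carrying `dx_deg` and `cue_direction`.
#' @param trials Trial data.frame (defines the trial universe and count of
#'   zero-event trials).
#' @param window_ms Length-2 window `(start, end)` in aligned time for a
#'   single-window summary, or the window width when `step_ms` is given.
#' @param step_ms Stride for sliding windows over `span_ms`; NULL for one
#'   fixed window.
#' @param span_ms Span covered by sliding windows.
#' @return Data.frame with one row per window: `window_start_ms`,
#'   `window_end_ms`, `midpoint_ms`, event and trial counts, `n_toward`,
#'   `n_away`, `n_zero`, `prop_toward` and `mean_deg_toward`.
#' @export
toward_cue_window_stats <- function(events, trials, window_ms = c(400, 800),
                                    step_ms = NULL, span_ms = NULL) {
  ev <- events[events$kind == "microsaccade", , drop = FALSE]
  if (!"onset_rel_ms" %in% names(ev)) {
    stop("toward_cue_window_stats: events must be aligned first", call. = FALSE)
  }
  if (is.null(step_ms)) {
    windows <- matrix(window_ms, ncol = 2)
  } else {
    width <- if (length(window_ms) == 2) diff(window_ms) else window_ms
    if (is.null(span_ms)) stop("toward_cue_window_stats: span_ms required with step_ms",
                               call. = FALSE)
    starts <- seq(span_ms[1], span_ms[2] - width, by = step_ms)
    windows <- cbind(starts, starts + width)
  }
  out <- do.call(rbind, lapply(seq_len(nrow(windows)), function(i) {
    w0 <- windows[i, 1]; w1 <- windows[i, 2]
    e <- ev[ev$onset_rel_ms >= w0 & ev$onset_rel_ms < w1, , drop = FALSE]
    sgn_cue <- ifelse(e$cue_direction == "right", 1, -1)
    toward <- sign(e$dx_deg) == sgn_cue & e$dx_deg != 0
    away <- sign(e$dx_deg) == -sgn_cue & e$dx_deg != 0
    signed <- abs(e$dx_deg) * ifelse(toward, 1, ifelse(away, -1, 0))
    bytrial <- split(data.frame(toward, away, signed), e$trial)
    props <- vapply(bytrial, function(d) {
      nt <- sum(d$toward); na <- sum(d$away)
      if (nt + na == 0) NA_real_ else nt / (nt + na)
    }, numeric(1))
    degs <- vapply(bytrial, function(d) sum(d$signed), numeric(1))
    contributing <- !is.na(props)
    data.frame(window_start_ms = w0, window_end_ms = w1,
               midpoint_ms = (w0 + w1) / 2,
               n_events = nrow(e), n_toward = sum(toward),
               n_away = sum(away), n_zero = sum(!toward & !away),
               n_trials_with_events = sum(contributing),
               n_trials_total = nrow(trials),
               prop_toward = if (any(contributing)) mean(props[contributing]) else NA_real_,
               mean_deg_toward = if (length(degs)) mean(degs) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

#' Microsaccade amplitude summary
#'
#' Median amplitude in arcminutes, the fraction of amplitudes strictly
#' below a threshold, and a fixed-bin histogram for reporting.
#'
#' @param events Event data.frame; only microsaccades are used.
#' @param threshold_deg Cutoff for the below-threshold fraction.
#' @param bin_deg Histogram bin width; amplitudes above `max_deg` pool into
#'   the last bin.
#' @param max_deg Upper edge of the histogram.
#' @return A list with `n`, `median_arcmin`, `fraction_below_threshold`,
#'   and `histogram` (data.frame of bin edges and counts). Empty input
#'   yields `n = 0` with NA summaries and a warning.
#' @export
amplitude_summary <- function(events, threshold_deg = 0.5, bin_deg = 0.05,
                              max_deg = 2) {
  amp <- events$amplitude_deg[events$kind == "microsaccade"]
  if (!length(amp)) {
    warning("amplitude_summary: no microsaccades")
    return(list(n = 0L, median_arcmin = NA_real_,
                fraction_below_threshold = NA_real_, histogram = NULL))
  }
  edges <- seq(0, max_deg, by = bin_deg)
  counts <- graphics::hist(pmin(amp, max_deg - bin_deg / 2), breaks = edges,
                           plot = FALSE)$counts
  list(n = length(amp),
       median_arcmin = stats::median(amp) * 60,
       fraction_below_threshold = mean(amp < threshold_deg),
       histogram = data.frame(bin_low_deg = edges[-length(edges)],
                              bin_high_deg = edges[-1], count = counts))
}

#' Cue-aligned microsaccade direction density map
#'
#' 2D density of event displacements (dx, dy) with left-cue trials
#' mirrored in x so that "toward the cue" is always +x; normalized to sum
#' to 1.
#'
#' @param events Events carrying `dx_deg`, `dy_deg`, `cue_direction`.
#' @param grid_deg Half-extent of the square grid.
#' @param bin_deg Cell size.
#' @return A list with `density` (matrix, rows = y bins bottom-to-top,
#'   cols = x bins), `x_centers`, `y_centers`, `n_events`. Empty selection
#'   yields a zero map with a warning.
#' @export
direction_density_map <- function(events, grid_deg = 1, bin_deg = 0.1) {
  ev <- events[events$kind == "microsaccade", , drop = FALSE]
  edges <- seq(-grid_deg, grid_deg, by = bin_deg)
  centers <- edges[-length(edges)] + bin_deg / 2
  nb <- length(centers)
  dens <- matrix(0, nrow = nb, ncol = nb)
  if (!nrow(ev)) {
    warning("direction_density_map: no events in selection")
    return(list(density = dens, x_centers = centers, y_centers = centers,
                n_events = 0L))
  }
  mirror <- ifelse(ev$cue_direction == "left", -1, 1)
  dx <- ev$dx_deg * mirror
  dy <- ev$dy_deg
  keep <- dx >= -grid_deg & dx < grid_deg & dy >= -grid_deg & dy < grid_deg
  ix <- findInterval(dx[keep], edges, rightmost.closed = FALSE)
  iy <- findInterval(dy[keep], edges, rightmost.closed = FALSE)
  for (i in seq_along(ix)) dens[iy[i], ix[i]] <- dens[iy[i], ix[i]] + 1
  if (sum(dens) > 0) dens <- dens / sum(dens)
  list(density = dens, x_centers = centers, y_centers = centers,
       n_events = sum(keep))
}
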