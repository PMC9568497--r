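#' Construct a gaze trace
#'
#' A gaze trace is one trial's uniformly sampled eye-position stream in
#' centered degree coordinates (+x rightward, +y upward), with a per-sample
#' pupil-validity flag. Timestamps must be strictly increasing and uniform
#' at the stated sampling rate.
#'
#' @param subject_id,trial_id Identifiers.
#' @param t_ms Sample timestamps in milliseconds.
#' @param x_deg,y_deg Eye position in degrees relative to screen center.
#' @param pupil_valid Logical vector; FALSE marks missing-pupil samples.
#' @param sample_rate_hz Sampling rate (default 1000).
#' @param tol_ms Tolerance on timestamp uniformity, milliseconds.
#' @return An object of class `gaze_trace`.
#' @export
gaze_trace <- function(subject_id, trial_id, t_ms, x_deg, y_deg,
                       pupil_valid = rep(TRUE, length(t_ms)),
                       sample_rate_hz = 1000, tol_ms = 1e-6) {
  n <- length(t_ms)
  if (n < 5L) {
    stop("gaze_trace: need at least 5 samples (trial ", trial_id, ")",
         call. = FALSE)
  }
  if (length(x_deg) != n || length(y_deg) != n || length(pupil_valid) != n) {
    stop("gaze_trace: t_ms, x_deg, y_deg, pupil_valid must have equal length",
         call. = FALSE)
  }
  dt <- 1000 / sample_rate_hz
  if (any(abs(diff(t_ms) - dt) > tol_ms)) {
    stop("gaze_trace: non-uniform timestamps in trial ", trial_id,
         " (expected step ", dt, " ms)", call. = FALSE)
  }
  structure(
    list(subject_id = as.character(subject_id),
         trial_id = as.character(trial_id),
         sample_rate_hz = sample_rate_hz,
         t_ms = as.numeric(t_ms),
         x_deg = as.numeric(x_deg),
         y_deg = as.numeric(y_deg),
         pupil_valid = as.logical(pupil_valid)),
    class = "gaze_trace")
}

#' @export
print.gaze_trace <- function(x, ...) {
  cat(sprintf(
    "<gaze_trace> subject %s trial %s: %d samples @ %g Hz, %.0f-%.0f ms, %d invalid\n",
    x$subject_id, x$trial_id, length(x$t_ms), x$sample_rate_hz,
    x$t_ms[1], x$t_ms[length(x$t_ms)], sum(!x$pupil_valid)))
  invisible(x)
}

#' @export
as.data.frame.gaze_trace <- function(x, ...) {
  data.frame(subject = x$subject_id, trial = x$trial_id,
             time = x$t_ms, x = x$x_deg, y = x$y_deg,
             pupil_valid = as.integer(x$pupil_valid))
}
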