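#' @keywords internal
.conditions <- c("intact", "floating_heads", "headless_bodies")
.validities <- c("valid", "invalid", "not_applicable")
.responses <- c("present", "absent")
.exclusion_reasons <- c("none", "blink_in_video", "fixation_break")

.delim_for <- function(path) if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","

#' Read gaze samples from a delimited text file
#'
#' The file must contain header columns `trial`, `time`, `x`, `y`,
#' `pupil_valid` (and optionally `subject`). Pixel-unit input is converted
#' to centered degrees through the display geometry; timestamps are
#' validated as uniform at `sample_rate_hz`.
#'
#' @param path CSV (comma) or TSV (tab) file of per-sample records.
#' @param geometry A [screen_geometry()]; required when `units = "px"`.
#' @param units Coordinate units in the file, `"deg"` (centered degrees) or
#'   `"px"` (image convention).
#' @param sample_rate_hz Expected sampling rate.
#' @return A list of [gaze_trace()] objects, one per trial, in file order.
#' @export
read_gaze_samples <- function(path, geometry = screen_geometry(),
                              units = c("deg", "px"), sample_rate_hz = 1000) {
  units <- match.arg(units)
  df <- utils::read.table(path, header = TRUE, sep = .delim_for(path),
                          stringsAsFactors = FALSE)
  needed <- c("trial", "time", "x", "y", "pupil_valid")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("read_gaze_samples: missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"subject" %in% names(df)) df$subject <- "s01"
  if (units == "px") {
    xy <- convert_point(cbind(df$x, df$y), geometry, "px_to_deg")
    df$x <- xy[, 1]
    df$y <- xy[, 2]
  }
  ids <- unique(df$trial)
  lapply(ids, function(id) {
    d <- df[df$trial == id, , drop = FALSE]
    gaze_trace(subject_id = d$subject[1], trial_id = id,
               t_ms = d$time, x_deg = d$x, y_deg = d$y,
               pupil_valid = as.logical(d$pupil_valid),
               sample_rate_hz = sample_rate_hz)
  })
}

#' Write gaze traces to a delimited text file
#'
#' @param traces A list of [gaze_trace()] objects.
#' @param path Output path (`.csv` or `.tsv`).
#' @return Invisibly, the path.
#' @export
write_gaze_samples <- function(traces, path) {
  if (inherits(traces, "gaze_trace")) traces <- list(traces)
  df <- do.call(rbind, lapply(traces, as.data.frame))
  utils::write.table(df, path, sep = .delim_for(path), row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

.validate_trials <- function(trials, allowed_soa = c(200, 500)) {
  needed <- c("subject", "trial", "condition", "soa_ms", "target_present",
              "cue_validity", "cue_direction", "response")
  missing <- setdiff(needed, names(trials))
  if (length(missing)) {
    stop("trial table: missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad_cond <- setdiff(unique(trials$condition), .conditions)
  if (length(bad_cond)) {
    stop("trial table: unknown condition(s) ", paste(bad_cond, collapse = ", "),
         "; allowed: ", paste(.conditions, collapse = ", "), call. = FALSE)
  }
  bad_soa <- setdiff(unique(trials$soa_ms), allowed_soa)
  if (length(bad_soa)) {
    stop("trial table: unknown SOA value(s) ", paste(bad_soa, collapse = ", "),
         "; allowed: ", paste(allowed_soa, collapse = ", "), call. = FALSE)
  }
  bad_val <- setdiff(unique(trials$cue_validity), .validities)
  if (length(bad_val)) {
    stop("trial table: unknown cue_validity value(s) ",
         paste(bad_val, collapse = ", "), "; allowed: ",
         paste(.validities, collapse = ", "), call. = FALSE)
  }
  bad_dir <- setdiff(unique(trials$cue_direction), c("left", "right"))
  if (length(bad_dir)) {
    stop("trial table: unknown cue_direction value(s) ",
         paste(bad_dir, collapse = ", "), call. = FALSE)
  }
  trials$target_present <- as.logical(trials$target_present)
  # target-absent trials carry no defined validity
  trials$cue_validity[!trials$target_present] <- "not_applicable"
  if (any(trials$target_present & trials$cue_validity == "not_applicable")) {
    stop("trial table: target-present trials must have valid/invalid cue_validity",
         call. = FALSE)
  }
  if (!"excluded" %in% names(trials)) trials$excluded <- FALSE
  if (!"exclusion_reason" %in% names(trials)) trials$exclusion_reason <- "none"
  trials$excluded <- as.logical(trials$excluded)
  if (any(trials$excluded & trials$exclusion_reason == "none")) {
    stop("trial table: excluded trials must carry an exclusion_reason",
         call. = FALSE)
  }
  trials
}

#' Read a trial metadata table
#'
#' Expected columns: `subject`, `trial`, `condition`, `soa_ms`,
#' `target_present`, `cue_validity`, `cue_direction`, `response`, plus
#' optional timeline anchor columns (`head_motion_onset_ms`, ...,
#' `array_onset_ms`, `array_offset_ms`) and exclusion flags. Enumerated
#' columns are validated; target-absent trials are forced to
#' `cue_validity = "not_applicable"`.
#'
#' @param path CSV/TSV file.
#' @param allowed_soa Permitted SOA values in ms.
#' @return A validated trial data.frame.
#' @export
read_trial_table <- function(path, allowed_soa = c(200, 500)) {
  df <- utils::read.table(path, header = TRUE, sep = .delim_for(path),
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    warning("read_trial_table: empty file ", path)
    return(df)
  }
  .validate_trials(df, allowed_soa = allowed_soa)
}

#' Write a trial metadata table
#'
#' @param trials Trial data.frame.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_trial_table <- function(trials, path) {
  utils::write.table(trials, path, sep = .delim_for(path), row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

.event_columns <- c("subject", "trial", "kind", "onset_ms", "offset_ms",
                    "dx_deg", "dy_deg", "amplitude_deg", "direction_rad",
                    "peak_velocity_deg_s")

#' Write a detected-event table
#'
#' One row per ocular event, sorted deterministically by (trial, onset).
#' An empty event set produces a header-only file.
#'
#' @param events Event data.frame as returned by the detectors.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_event_table <- function(events, path) {
  if (is.null(events) || nrow(events) == 0L) {
    events <- as.data.frame(stats::setNames(
      replicate(length(.event_columns), numeric(0), simplify = FALSE),
      .event_columns))
  } else {
    missing <- setdiff(.event_columns, names(events))
    if (length(missing)) {
      stop("write_event_table: missing column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    events <- events[order(events$trial, events$onset_ms), .event_columns]
  }
  utils::write.table(events, path, sep = .delim_for(path), row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a detected-event table
#'
#' @param path CSV/TSV file written by [write_event_table()].
#' @return Event data.frame.
#' @export
read_event_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = .delim_for(path),
                    stringsAsFactors = FALSE)
}
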