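#' Signal-detection sensitivity (d-prime)
#'
#' `d' = qnorm(h*) - qnorm(f*)`, where the hit and false-alarm rates are
#' clamped to `[1/(2n), 1 - 1/(2n)]` of their respective trial counts so
#' that extreme rates (0 or 1) stay finite. The log-linear (add 0.5 to
#' every count) correction is available as an alternative.
#'
#' @param hit_rate,fa_rate Proportions in [0, 1].
#' @param n_present,n_absent Trial counts behind each rate.
#' @param correction `"clamp"` (default) or `"loglinear"`.
#' @return Sensitivity, unitless. Vectorized over its arguments.
#' @examples
#' dprime(0.58, 0.22, 60, 60)  # ~0.974
#' @export
dprime <- function(hit_rate, fa_rate, n_present, n_absent,
                   correction = c("clamp", "loglinear")) {
  correction <- match.arg(correction)
  if (any(hit_rate < 0 | hit_rate > 1 | fa_rate < 0 | fa_rate > 1, na.rm = TRUE)) {
    stop("dprime: rates must lie in [0, 1]", call. = FALSE)
  }
  if (any(c(n_present, n_absent) < 1)) {
    stop("dprime: trial counts must be >= 1", call. = FALSE)
  }
  if (correction == "clamp") {
    h <- pmin(pmax(hit_rate, 1 / (2 * n_present)), 1 - 1 / (2 * n_present))
    f <- pmin(pmax(fa_rate, 1 / (2 * n_absent)), 1 - 1 / (2 * n_absent))
  } else {
    h <- (hit_rate * n_present + 0.5) / (n_present + 1)
    f <- (fa_rate * n_absent + 0.5) / (n_absent + 1)
  }
  stats::qnorm(h) - stats::qnorm(f)
}

#' Tabulate signal-detection performance per subject, condition and SOA
#'
#' Counts hits per cue validity and false alarms per cell (validity is
#' undefined on target-absent trials, so the false-alarm rate is shared),
#' and derives per-validity d-prime with the cell's shared false-alarm
#' rate. Excluded trials are ignored. Cells missing a validity or absent
#' trials are emitted with NA rates and a warning.
#'
#' @param trials Trial data.frame (see [simulate_behavior()] /
#'   [read_trial_table()]).
#' @param correction Extreme-rate correction passed to [dprime()].
#' @return Data.frame with one row per subject x condition x SOA:
#'   counts, `hit_rate_valid`, `hit_rate_invalid`, `fa_rate`,
#'   `dprime_valid`, `dprime_invalid`.
#' @export
tabulate_sdt <- function(trials, correction = "clamp") {
  t <- trials[!trials$excluded, , drop = FALSE]
  key <- interaction(t$subject, t$condition, t$soa_ms, drop = TRUE)
  cells <- split(t, key)
  out <- do.call(rbind, lapply(cells, function(d) {
    pv <- d$target_present & d$cue_validity == "valid"
    pi <- d$target_present & d$cue_validity == "invalid"
    ab <- !d$target_present
    resp_p <- d$response == "present"
    n_pv <- sum(pv); n_pi <- sum(pi); n_ab <- sum(ab)
    data.frame(
      subject = d$subject[1], condition = d$condition[1], soa_ms = d$soa_ms[1],
      n_present_valid = n_pv, n_hits_valid = sum(pv & resp_p),
      n_present_invalid = n_pi, n_hits_invalid = sum(pi & resp_p),
      n_absent = n_ab, n_false_alarms = sum(ab & resp_p))
  }))
  rownames(out) <- NULL
  incomplete <- out$n_present_valid == 0 | out$n_present_invalid == 0 |
    out$n_absent == 0
  if (any(incomplete)) {
    warning("tabulate_sdt: ", sum(incomplete),
            " cell(s) missing a validity or absent trials; rates set to NA")
  }
  out$hit_rate_valid <- ifelse(out$n_present_valid > 0,
                               out$n_hits_valid / out$n_present_valid, NA)
  out$hit_rate_invalid <- ifelse(out$n_present_invalid > 0,
                                 out$n_hits_invalid / out$n_present_invalid, NA)
  out$fa_rate <- ifelse(out$n_absent > 0, out$n_false_alarms / out$n_absent, NA)
  ok <- !incomplete
  out$dprime_valid <- NA_real_
  out$dprime_invalid <- NA_real_
  out$dprime_valid[ok] <- dprime(out$hit_rate_valid[ok], out$fa_rate[ok],
                                 out$n_present_valid[ok], out$n_absent[ok],
                                 correction = correction)
  out$dprime_invalid[ok] <- dprime(out$hit_rate_invalid[ok], out$fa_rate[ok],
                                   out$n_present_invalid[ok], out$n_absent[ok],
                                   correction = correction)
  out
}

#' Per-subject cueing effects
#'
#' Valid-minus-invalid differences in hit rate and d-prime per subject,
#' condition and SOA, plus group means and standard errors across
#' subjects.
#'
#' @param summaries Output of [tabulate_sdt()].
#' @return A list with `per_subject` (one row per subject-cell) and
#'   `group` (mean, SE and n across subjects per condition x SOA; SE is NA
#'   with a single subject).
#' @export
cueing_effects <- function(summaries) {
  s <- summaries
  drop <- is.na(s$dprime_valid) | is.na(s$dprime_invalid)
  if (any(drop)) {
    warning("cueing_effects: omitting ", sum(drop),
            " subject-cell(s) with missing validity data")
    s <- s[!drop, , drop = FALSE]
  }
  per <- data.frame(subject = s$subject, condition = s$condition,
                    soa_ms = s$soa_ms,
                    delta_hit_rate = s$hit_rate_valid - s$hit_rate_invalid,
                    delta_dprime = s$dprime_valid - s$dprime_invalid)
  key <- interaction(per$condition, per$soa_ms, drop = TRUE)
  group <- do.call(rbind, lapply(split(per, key), function(d) {
    n <- nrow(d)
    data.frame(condition = d$condition[1], soa_ms = d$soa_ms[1], n_subjects = n,
               mean_delta_hit_rate = mean(d$delta_hit_rate),
               se_delta_hit_rate = if (n > 1) stats::sd(d$delta_hit_rate) / sqrt(n) else NA_real_,
               mean_delta_dprime = mean(d$delta_dprime),
               se_delta_dprime = if (n > 1) stats::sd(d$delta_dprime) / sqrt(n) else NA_real_)
  }))
  rownames(group) <- NULL
  if (any(group$n_subjects == 1)) {
    warning("cueing_effects: group SE undefined with a single subject")
  }
  list(per_subject = per, group = group)
}

#' Cohen's d for paired (within-subject) differences
#'
#' Mean of the per-subject differences divided by their sample SD.
#'
#' @param per_subject_deltas Numeric vector, one difference per subject.
#' @return Effect size (unitless); NA with a warning when the SD is zero.
#' @examples
#' cohens_d(c(0.2, 0.4, 0.6))  # 2
#' @export
cohens_d <- function(per_subject_deltas) {
  x <- per_subject_deltas[is.finite(per_subject_deltas)]
  if (length(x) < 2) stop("cohens_d: need >= 2 subjects", call. = FALSE)
  s <- stats::sd(x)
  if (s == 0) {
    warning("cohens_d: zero SD; effect size undefined")
    return(NA_real_)
  }
  mean(x) / s
}
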