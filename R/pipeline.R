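#' Bootstrap the cueing effect in every condition-by-SOA cell
#'
#' Per cell, each subject's valid-minus-invalid d-prime difference is the
#' unit statistic; the across-subject mean is bootstrapped at the
#' participant level and tested against zero. The six raw p-values form
#' one FDR family.
#'
#' @param trials Trial data.frame.
#' @param n_boot Bootstrap replicates per cell.
#' @param seed Optional integer seed.
#' @param measure `"delta_dprime"` or `"delta_hit_rate"`.
#' @return Data.frame with one row per condition x SOA: observed mean
#'   effect, bootstrap CI, Cohen's d, `p_raw` and `p_fdr`.
#' @export
boot_cueing_effects <- function(trials, n_boot = 10000, seed = NULL,
                                measure = c("delta_dprime", "delta_hit_rate")) {
  measure <- match.arg(measure)
  if (!is.null(seed)) set.seed(seed)
  eff <- cueing_effects(tabulate_sdt(trials))$per_subject
  key <- interaction(eff$condition, eff$soa_ms, drop = TRUE)
  rows <- lapply(split(eff, key), function(d) {
    vals <- stats::setNames(d[[measure]], d$subject)
    br <- bootstrap_mean(vals, n_boot = n_boot,
                         label = paste(measure, d$condition[1], d$soa_ms[1]))
    data.frame(condition = d$condition[1], soa_ms = d$soa_ms[1],
               n_subjects = nrow(d), observed = br$observed,
               ci_low = br$ci_low, ci_high = br$ci_high,
               cohens_d = cohens_d(vals), p_raw = br$p_raw)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- fdr_adjust(out$p_raw)
  out <- out[order(out$condition, out$soa_ms), ]
  rownames(out) <- NULL
  out
}

#' Run the full gaze-cueing analysis pipeline on simulated data
#'
#' End-to-end demonstration: simulate a full behavioral cohort, bootstrap
#' the cueing effect per condition x SOA with FDR correction, and run a
#' reduced oculomotor arm (simulated traces, event detection, trial
#' exclusions, amplitude and direction-bias summaries, rate curve).
#'
#' @param behavior_cfg A [behavior_sim_config()].
#' @param trace_cfg A [trace_sim_config()].
#' @param n_boot Bootstrap replicates per cell.
#' @param n_trace_subjects,n_traces_per_subject Size of the oculomotor arm.
#' @param seed Integer seed governing the whole run.
#' @return A list with `trials`, `sdt`, `effects` (group summary),
#'   `bootstrap` (per-cell table with p_fdr), `events`, `exclusions`,
#'   `amplitude`, `toward_cue`, `rate`.
#' @export
run_cueing_pipeline <- function(behavior_cfg = behavior_sim_config(),
                                trace_cfg = trace_sim_config(),
                                n_boot = 2000,
                                n_trace_subjects = 6,
                                n_traces_per_subject = 30,
                                seed = 1) {
  set.seed(seed)
  trials <- simulate_behavior(behavior_cfg)
  sdt <- tabulate_sdt(trials)
  effects <- cueing_effects(sdt)
  boot <- boot_cueing_effects(trials, n_boot = n_boot)

  # oculomotor arm on a subset of subjects/trials (timelines needed)
  subj <- utils::head(unique(trials$subject), n_trace_subjects)
  sub <- trials[trials$subject %in% subj, , drop = FALSE]
  sub <- do.call(rbind, lapply(split(sub, sub$subject), function(d) {
    d[sample.int(nrow(d), min(n_traces_per_subject, nrow(d))), , drop = FALSE]
  }))
  tl <- do.call(rbind, lapply(sub$soa_ms, make_timeline))
  sub <- cbind(sub[setdiff(names(sub), names(tl))], tl)
  sim <- simulate_traces_for_trials(sub, trace_cfg)
  events <- do.call(rbind, lapply(sim$traces, detect_trial))
  excl <- apply_trial_exclusions(sub, events, sim$traces)
  kept <- excl$trials[!excl$trials$excluded, , drop = FALSE]
  ev_kept <- events[events$trial %in% kept$trial, , drop = FALSE]
  aligned <- align_events(ev_kept, kept, anchor = "array_onset")
  list(trials = trials, sdt = sdt, effects = effects$group, bootstrap = boot,
       events = events, exclusions = excl$report,
       amplitude = amplitude_summary(ev_kept),
       toward_cue = toward_cue_window_stats(
         aligned[aligned$cue_validity == "valid", , drop = FALSE], kept,
         window_ms = c(400, 800)),
       rate = rate_curve(align_events(ev_kept, kept, "video_onset"), kept,
                         span_ms = c(0, 1000), bin_ms = 20, smooth_ms = 100))
}
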