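#' Hierarchical (participant-level) bootstrap
#'
#' Each replicate resamples subjects with replacement and carries ALL data
#' of every drawn subject (a subject drawn twice contributes twice),
#' respecting the nested trial-within-subject structure. The statistic is
#' evaluated on each resample; significance against `null_value` uses the
#' smoothed null-crossing rule
#' `p = 2 * min[(1 + #(theta* <= null)) / (n + 1),
#'              (1 + #(theta* >= null)) / (n + 1)]` (two-sided, capped at
#' 1), with one-sided variants available. The 95% interval is percentile.
#'
#' @param data A named list with one element per subject (a subject's
#'   trials, per-subject statistic, or any object the statistic consumes).
#' @param statistic Function taking a list of drawn subject elements (with
#'   repetition) and returning one number. NA/NaN replicates are redrawn,
#'   up to 1% of `n_boot`.
#' @param n_boot Number of replicates (default 10000).
#' @param null_value Null value for the p-value (default 0).
#' @param alternative `"two.sided"`, `"greater"` (statistic > null) or
#'   `"less"`.
#' @param seed Optional integer seed.
#' @param label Statistic label carried in the result.
#' @return An object of class `bootstrap_result`: a list with `observed`,
#'   `boot` (replicate values), `boot_mean`, `boot_sd`, `ci_low`,
#'   `ci_high`, `p_raw`, `n_boot`, `label`.
#' @export
hierarchical_bootstrap <- function(data, statistic, n_boot = 10000,
                                   null_value = 0,
                                   alternative = c("two.sided", "greater", "less"),
                                   seed = NULL, label = "statistic") {
  alternative <- match.arg(alternative)
  if (length(data) < 2) {
    stop("hierarchical_bootstrap: need >= 2 subjects", call. = FALSE)
  }
  if (n_boot < 100) warning("hierarchical_bootstrap: n_boot < 100 is unreliable")
  if (!is.null(seed)) set.seed(seed)
  ns <- length(data)
  observed <- statistic(data)
  boot <- numeric(n_boot)
  bad <- 0L
  max_bad <- ceiling(0.01 * n_boot)
  i <- 1L
  while (i <= n_boot) {
    idx <- sample.int(ns, ns, replace = TRUE)
    v <- statistic(data[idx])
    if (is.na(v)) {
      bad <- bad + 1L
      if (bad > max_bad) {
        stop("hierarchical_bootstrap: statistic '", label,
             "' undefined on more than 1% of resamples", call. = FALSE)
      }
      next
    }
    boot[i] <- v
    i <- i + 1L
  }
  p_lo <- (1 + sum(boot <= null_value)) / (n_boot + 1)
  p_hi <- (1 + sum(boot >= null_value)) / (n_boot + 1)
  p_raw <- switch(alternative,
                  two.sided = min(1, 2 * min(p_lo, p_hi)),
                  greater = p_lo,   # evidence that theta > null: mass <= null is small
                  less = p_hi)
  ci <- stats::quantile(boot, c(0.025, 0.975), names = FALSE, type = 7)
  structure(list(label = label, observed = observed, n_boot = n_boot,
                 boot = boot, boot_mean = mean(boot), boot_sd = stats::sd(boot),
                 ci_low = ci[1], ci_high = ci[2], p_raw = p_raw,
                 null_value = null_value, alternative = alternative),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> %s: observed %.4f, 95%% CI [%.4f, %.4f], p = %.4g (%s, %d resamples)\n",
              x$label, x$observed, x$ci_low, x$ci_high, x$p_raw,
              x$alternative, x$n_boot))
  invisible(x)
}

#' Bootstrap the across-subject mean of per-subject values
#'
#' Convenience wrapper around [hierarchical_bootstrap()] for the common
#' case where the statistic is the mean of one precomputed value per
#' subject (e.g. each subject's valid-minus-invalid d-prime difference).
#'
#' @param values Named numeric vector, one value per subject.
#' @param ... Passed to [hierarchical_bootstrap()].
#' @return A `bootstrap_result`.
#' @export
bootstrap_mean <- function(values, ...) {
  data <- as.list(values)
  hierarchical_bootstrap(data, function(chunks) mean(unlist(chunks)), ...)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values controlling the false discovery rate within
#' one declared family of tests.
#'
#' @param p_values Numeric vector of raw p-values in [0, 1].
#' @return Adjusted p-values in the original order.
#' @export
fdr_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("fdr_adjust: p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Median test for two samples (chi-square on the pooled-median split)
#'
#' Mood's median test: counts above vs not-above the pooled grand median
#' per group, chi-square with 1 df without continuity correction, and the
#' phi effect size `sqrt(chi2 / N)`.
#'
#' @param a,b Numeric vectors.
#' @return A list with `chi2`, `p`, `phi`, `median_pooled` and the 2x2
#'   `table`.
#' @export
median_test <- function(a, b) {
  if (!length(a) || !length(b)) {
    stop("median_test: both samples must be non-empty", call. = FALSE)
  }
  pooled <- c(a, b)
  m <- stats::median(pooled)
  tab <- rbind(a = c(above = sum(a > m), not_above = sum(a <= m)),
               b = c(above = sum(b > m), not_above = sum(b <= m)))
  if (any(colSums(tab) == 0)) {
    stop("median_test: degenerate table (all values on one side of the pooled median)",
         call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  chi2 <- unname(ct$statistic)
  list(chi2 = chi2, p = unname(ct$p.value),
       phi = sqrt(chi2 / sum(tab)), median_pooled = m, table = tab)
}
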