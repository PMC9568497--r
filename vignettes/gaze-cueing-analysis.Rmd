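---
title: "Methods: gaze-cueing analysis of detection performance and microsaccades"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gaze-cueing analysis of detection performance and microsaccades}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazecue)
```

## The scientific problem

In a gaze-cueing experiment, observers detect a target person in a dynamic
scene while the head and body orientation of other people in the scene acts
as a spatial attention cue. The cue is valid when the gazed-at location
later contains the target and invalid otherwise, with 50% cue validity, and
the target array appears 200 or 500 ms (the stimulus-onset asynchrony, SOA)
after the gaze cue completes. Three display conditions isolate the cue's
carriers: the whole person (*intact*), only the heads (*floating heads*),
or only the bodies (*headless bodies*). Two families of measurements
quantify the cue's effect:

* **Detection performance** — hit rate, false-alarm rate, and the
  signal-detection sensitivity $d' = \Phi^{-1}(h) - \Phi^{-1}(f)$, compared
  between valid and invalid cues ($\Delta d'$, the sensitivity cueing
  effect).
* **Microsaccades** — small fixational saccades (mostly below 0.5 deg)
  detected from 1000 Hz gaze recordings, whose rate over time and
  horizontal direction relative to the cued side index covert attention.

Because the human dataset is not distributable with the package, a
synthetic-data generator produces gaze traces with known injected events
and behavioral trials with a configurable cueing-effect structure; every
analysis stage is validated against this ground truth.

## Event detection

Detection follows the velocity-threshold approach standard for
microsaccades. Velocities come from a centred moving-average derivative:
with half-width $k = (w-1)/2$ for a window of $w$ samples (default 5),

$$v_n = \frac{\sum_{j=1}^{k} x_{n+j} - \sum_{j=1}^{k} x_{n-j}}
             {k(k+1)\,\Delta t},$$

which for $w=5$ is the familiar
$(x_{n+2}+x_{n+1}-x_{n-1}-x_{n-2})/(6\Delta t)$ filter. Samples near the
trace boundary shrink to a symmetric window of the available half-width;
the first and last samples use one-sided differences. Acceleration is the
centred difference of speed.

The microsaccade threshold is adaptive per trial: each velocity component
gets a robust scale $\sigma = \sqrt{\mathrm{med}(v^2) - \mathrm{med}(v)^2}$
and a threshold $\eta = \lambda\sigma$ with $\lambda = 6$. (For Gaussian
velocities this median-based scale is about $0.674$ times the true SD, so
$\lambda = 6$ acts as roughly four true SDs.) Candidate samples satisfy the
elliptical criterion $(v_x/\eta_x)^2 + (v_y/\eta_y)^2 > 1$; a scalar-speed
variant is available via `detector_params(criterion = "scalar")` since the
verbal description of the method ("a velocity above a threshold") is
scalar, but the elliptical form is the default.

The "intervals longer than 12 ms" rule is deliberately applied in **both**
of its readings, each independently configurable: events must span at
least `min_duration_ms = 12` ms (onset to offset), and events separated by
less than `merge_gap_ms = 12` ms are merged. Saccades are runs of speed
above 35 deg/s whose peak |acceleration| exceeds 9,500 deg/s²; a
threshold-crossing event that also meets both saccade criteria is labelled
a saccade rather than a microsaccade. The acceleration criterion is
evaluated at the event peak, not per sample: for any smooth ballistic
velocity profile the acceleration crosses zero exactly at peak speed, so a
sustained per-sample conjunction of both criteria is unsatisfiable.

Blinks are events containing missing-pupil samples (the tracker reports a
missing pupil during a saccade-like excursion). Samples within the
derivative half-window of an invalid-pupil span cannot seed microsaccade
candidates, which keeps lid-closure artifacts out of the microsaccade
class; `detect_trial()` re-adds non-overlapping saccade/blink detections so
blinks are still found and can trigger the exclusion rule. Trials with a
blink overlapping the video (onset through array offset) are excluded, as
are trials leaving the 1.5-deg fixation radius (strictly "more than":
exactly 1.5 deg is kept).

Degenerate traces (zero robust velocity scale, e.g. a constant trace)
yield an empty event table flagged `degenerate` with a warning rather than
an error, so batch processing continues.

## The synthetic-data generator

`simulate_trace()` builds one trial's gaze stream at 1000 Hz as:

* **drift** — a Gaussian random walk with scale
  `drift_sd_deg_per_sqrt_s` (deg per √s);
* **microsaccades** — a Poisson process (`ms_rate_hz`, default 1.5 /s, a
  literature-typical fixational rate) of ballistic events with
  raised-cosine velocity profiles, lognormal amplitudes
  (`amp_median_deg = 0.26`, i.e. 15.6 arcmin, `amp_sigma_log = 0.6`), and
  a linear main sequence: peak velocity = `main_seq_slope_per_s` ×
  amplitude (default 60 /s, ≈16 deg/s for a median event). Injected
  events are separated by at least 50 ms, an intersaccadic refractory
  period that also guarantees distinct injections never merge in the
  detector;
* **cue-direction bias** — each event's horizontal sign points toward the
  cued side with probability `toward_cue_prob` (only the sign is biased,
  matching the left/right direction coding of the analysis);
* **blink** — with probability `blink_prob_per_trial` (default 0.011), a
  100 ms span of invalid pupil with a fast 6-deg vertical excursion
  emulating tracker output during lid closure;
* **sensor noise** — additive white noise (`noise_sd_deg`).

Two parameters are coupled by geometry: a raised-cosine profile that
displaces amplitude $A$ in duration $d$ has peak velocity $2A/d$, so the
main-sequence constraint fixes $d = 2/\text{slope}$ (33.3 ms at the
default slope). `ms_duration_ms` therefore defaults to `2000/slope`;
overriding it keeps displacements exact but makes the realised peak
velocity $2A/d$ instead of the slope. The waveform choice is isolated in
one internal function; any C¹ profile with zero endpoint velocity would
serve.

The default drift (0.01 deg/√s) and noise (5×10⁻⁴ deg) emulate a clean
tower-mount recording and are deliberately low: the trial-wise threshold
then sits near 1 deg/s, and the threshold-crossing latency of an injected
event — $t = (d/2\pi)\arccos(1 - 2\eta/(60A))$ for amplitude $A$ — stays
within a few milliseconds across the amplitude distribution, so detector
scoring (onset tolerance ±5 ms) measures the detector rather than the
noise regime. With `amp_sigma_log = 0.6` about 86% of injected amplitudes
fall below 0.5 deg, in the range reported for human fixational data.

What the generator does **not** emulate: mean-reverting drift or
corrective microsaccades (positions random-walk away from center, so a few
percent of long trials legitimately trip the fixation-break rule),
pupil-size dynamics, binocular disparity, tracker-specific noise spectra,
and any dependence of microsaccade rate on the trial's events (the rate is
homogeneous, whereas human rates show inhibition and rebound after
stimulus onsets). Passing tests therefore certify the pipeline's
correctness on a well-specified model, not detector performance on real
recordings.

`simulate_behavior()` produces the cohort: per subject a base sensitivity
$d_s \sim N(\mu_{d'}, \sigma_{d'})$ truncated at 0; on target-present
trials the internal signal is $N(d_s \pm ce/2, 1)$ for valid/invalid cues
and responses are "present" above a criterion $c$. Defaults follow the
published design and Table-level summaries: 30 subjects, 120 trials per
condition split over the two SOAs with exact 50/50 presence and validity,
$\mu_{d'} = 0.95$, $\sigma_{d'} = 0.4$, $c = 0.75$ (false-alarm rate near
0.23), and a cueing-effect map with the published condition-by-SOA
structure — sustained for intact (0.31 and 0.41 at 200/500 ms), transient
for floating heads (0.29/0.05) and headless bodies (0.22/0.07). Under this
model $\mathbb{E}[\Delta d'] = ce$ exactly, which is what the recovery
tests exploit.

Trial timelines jitter the motion anchors (head 400–1800 ms, body
600–1700 ms, Gaussian SD 100 ms — comparable to the anchor variability of
the filmed scenes) and enforce positivity and ordering by redraw, erroring
after 100 rejections.

## Behavioral analysis

`tabulate_sdt()` counts hits per cue validity and false alarms per
subject × condition × SOA cell (validity is undefined on target-absent
trials, so both validities share the cell's false-alarm rate), and
converts rates to $d'$ after clamping to $[1/2n,\ 1-1/2n]$ — a standard,
disclosed correction for extreme rates; a log-linear (+0.5 counts)
alternative is selectable. $d'$ is computed per subject and then averaged,
never from pooled rates (the two differ; the aggregate-rate $d'$ of e.g.
hit 0.58 / false-alarm 0.22 is 0.97 and need not match a subject-averaged
table value). Cueing effects are per-subject valid-minus-invalid
differences; the paired effect size is Cohen's
$d = \bar{\Delta}/s_\Delta$.

## Inference

`hierarchical_bootstrap()` resamples **participants** with replacement and
carries every trial of each drawn subject (a subject drawn twice counts
twice), respecting the nested structure; 10,000 replicates by default
(analysis step 3 uses exactly that; the calibration test uses 1,000 per
dataset across 500 datasets to keep the suite fast). The p-value is the
smoothed two-sided null-crossing probability

$$p = 2\min\!\left[\frac{1 + \#\{\theta^* \le \theta_0\}}{B+1},\
\frac{1 + \#\{\theta^* \ge \theta_0\}}{B+1}\right]$$

capped at 1, with one-sided variants available (directional
toward-cue-proportion tests against 0.5 are a natural one-sided use).
Confidence intervals are percentile. The FDR family is a deliberate,
explicit choice of the caller: `boot_cueing_effects()` adjusts the six
condition × SOA p-values together with Benjamini–Hochberg. Note the BH
adjusted-p map is monotone but *not* idempotent — re-adjusting adjusted
values re-multiplies by $m/i$ — so adjusted values are reported once and
never re-fed.

At 30 subjects the percentile bootstrap is mildly anti-conservative (the
usual normal-versus-t discrepancy, rejection near 0.06 at nominal 0.05);
the calibration test verifies the rate stays within the binomial 95% band
around the nominal level.

Amplitude comparisons between conditions use the pooled-median
two-sample test: a 2×2 table of counts above/not-above the grand median,
$\chi^2$ with 1 df without continuity correction, and effect size
$\phi = \sqrt{\chi^2/N}$.

## Gaze-information metrics

Annotation analysis averages annotators' points per frame *before* taking
the Euclidean distance to the true gazed location ("mean annotated
location"; per-annotator distances are an option), reports pixels and
degrees (the default 1280×960 raster over 18.4°×13.8° is deliberately
isotropic, 69.57 px/deg both ways), and compares against a chance baseline
obtained by permuting the video↔truth pairing across videos (frames keep
their order; donor truth tracks are indexed cyclically when frame counts
differ). Enumeration is exhaustive up to 5 videos, Monte-Carlo beyond. The
pixel↔degree factor of the original video frames is not recoverable, so
pixel-scale results are interpretable only relative to the baseline.

The perspective conversion from a head's angular size to real-world
viewing distance uses the exact form
$D = \ell / (2\tan(\alpha/2))$ with $\ell = 0.24$ m adult head length; at
these angles it is indistinguishable from the linear approximation.

## Numerical and design choices

* Coordinates: degrees from screen center, +x right, +y up; pixels
  top-left origin, +y down; the linear (small-angle) mapping handles the
  flip and is exactly invertible.
* Event summary: displacement is last-minus-first sample of the run;
  amplitude its norm; direction `atan2(dy, dx)`; the onset sample carries
  the event for rate binning.
* "Toward the cue" uses only the horizontal sign; `dx = 0` counts as
  neither toward nor away (excluded from the proportion's denominator but
  conserved in `n_zero`). Trials without microsaccades in a window are
  excluded from the per-trial proportion average and counted.
* Sliding windows default to 400 ms width and 200 ms stride (midpoints at
  200, 400, ... ms), the stride being unstated in the source analyses.
* Direction maps mirror left-cue trials as $dx \to -dx$ so toward is
  always +x; this is the unique convention consistent with invariance
  under globally flipping cue directions and displacement signs.
* Rate curves use 1-ms bins with a 100-ms centred boxcar by default
  (20-ms bins in the analysis scripts for compact outputs); edge bins
  where the boxcar would be acausal are masked, and the across-subject
  95% interval is a t-interval.
* Exclusion precedence: blink-in-video is assigned before fixation-break
  when both apply.
* Seeds: every stochastic entry point takes an explicit seed; identical
  seeds give bit-identical outputs, including bootstrap results.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data at
these scales, chosen as the package's own verification budget: 50 traces
for detector-versus-reference equivalence, 200 trials for injection
recovery, 500 cohorts × 1,000 resamples for null calibration, 100 cohorts
for effect recovery, 1,000 trials for direction-bias recovery, and one
full pipeline run (30-subject behavior, 180-trace oculomotor arm) for the
end-to-end demonstration. The demonstration's significance *pattern* in
the small-effect cells is assessed over 15 replicate simulated
experiments, because a single 30-subject experiment carries only moderate
power there (effect/SE ≈ 2.6); the replication majority is the stable
signature of the configured transient-versus-sustained structure.

## Limitations

Detection quality on real recordings depends on noise and drift regimes
the generator idealizes; the adaptive threshold will sit several times
higher on real data, and recovery rates measured here do not transfer.
Monocular processing only; no binocular agreement criterion. No
response-time analysis is provided. The bootstrap assumes subjects are
exchangeable; it does not model session or video effects.
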