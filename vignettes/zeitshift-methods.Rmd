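---
title: "Quantifying circadian phase shifts: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying circadian phase shifts: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zeitshift)
```

# The problem

Aversive stimuli (footshock, forced swim) and light delivered during the
subjective night can displace the phase of the circadian pacemaker in the
suprachiasmatic nucleus (SCN). `zeitshift` implements the quantification
side of such experiments end to end: phase shifts of wheel-running activity
rhythms, event-locked fiber-photometry response metrics, phase shifts of the
SCN calcium rhythm recorded long-term under a duty cycle, and evoked-response
typing of two-photon ROI traces. Because in-vivo recordings of this kind are
rarely deposited, the package pairs every estimator with a synthetic-data
generator whose ground truth is known exactly, so each pipeline is validated
by parameter recovery rather than by eye.

Sign convention throughout (the standard phase-response-curve convention):
**advances are positive, delays negative**. A stimulus that moves activity
onset or the calcium acrophase to a *later* time yields a negative shift.

# Locomotor rhythms

## Onset detection

Wheel revolutions are binned at 5 min. For each 24-h day of the record, the
onset is the start of the first run of at least `min_run_bins = 6` bins (30
min) whose counts reach `threshold_frac = 0.2` of that day's maximum,
preceded by at least `quiet_h = 4` h below threshold. The quiet-period
requirement prevents activity spilling across the day boundary (inevitable
when the free-running period `tau != 24`) from being mistaken for an onset.
Days with no qualifying run are flagged and excluded — never interpolated.
Commercial actography software implements a proprietary onset detector; the
threshold-run rule here is a documented, fully testable equivalent. By
default counts are not smoothed before thresholding: the run-length rule
already rejects isolated noisy bins, and an unsmoothed crossing is unbiased
(a centred moving average is available via `smooth_bins` for sparse
records).

## Phase shift by onset regression

Detected onsets are unwrapped across midnight (successive onsets forced
within ±12 h) and regressed on day index by ordinary least squares,
separately for the pre-stimulus days and the post-stimulus days; by default
all post days enter the fit with no transient-day exclusion (a `day_range`
argument allows excluding transients). Both lines are evaluated at the event
day and

```
shift_h = -(post_intercept - pre_intercept)
```

The implied free-running period is `24 + slope`; fits whose period falls
outside 20–28 h are flagged. Under day-to-day onset jitter with SD 0.2 h and
7 + 7 days, the per-animal estimator SD is about 0.21 h, so cohorts of about
12 animals resolve effects of 0.2 h — which is why the generator's default
jitter was fixed at that value.

## Free-running period

Two estimators are provided: the onset-regression slope, and the
Sokolove–Bushell chi-square periodogram. For a candidate period of `P` bins
the record is folded into `P` phase columns over `K` complete cycles and

```
Qp = K * sum_h (colmean_h - grandmean)^2 / overall_variance
```

is referred to a chi-square distribution with `P - 1` degrees of freedom;
the best period is the candidate exceeding its `alpha = 0.05` significance
line by the largest margin, searched over 20–28 h at the bin resolution
(1/12 h for 5-min bins). Records whose peak never clears the line (e.g.
constant counts) are reported as arrhythmic rather than given a number.

## Group comparisons

Two-sample comparisons of per-animal shifts use the two-tailed Student's
t test (pooled variance), or the paired t test for within-animal designs;
when both groups are constant with equal means the degenerate case is
reported as `t = 0, p = 1`. Omnibus ANOVA machinery is out of scope.

# Event-locked fiber photometry

## Isosbestic correction

Motion and bleaching affect the calcium-dependent signal channel and the
calcium-independent reference channel together. The reference is fitted to
the signal by one least-squares line over the whole recording
(`sig ~ a*ref + b`), and

```
dF/F = (sig - fitted_ref) / fitted_ref
```

Because the generator applies bleaching and motion *multiplicatively and
identically* to both channels, this correction is exactly the right model
and the test suite can require cancellation to numerical precision. A
constant reference cannot be fitted; the correction then degenerates to
`a = 0, b = mean(sig)` with a warning and a flag.

## Trials, metrics, classification

Trials open 10 s before each stimulus, so the stimulus starts at relative
time 10 s; the baseline window is 0–10 s and the stimulus window 10–20 s for
footshock or 10–40 s for light (the 15-s pulse plus 15 s), with a 10-s tail
kept for plotting. Windows are configuration, not constants. Trials are
linearly interpolated onto a common grid at the native rate; per-trial
z-scoring by the baseline mean/SD is the default normalisation for response
statistics, with raw dF/F available throughout. AUCs are trapezoidal
integrals with interpolated window endpoints; the peak response is the
sample of largest absolute value in the stimulus window with its sign
preserved, ties broken at the earliest sample, and latency measured from
stimulus onset.

A response is `excitatory` when the peak exceeds `+2 * SD(baseline)`,
`inhibitory` below `-2 * SD(baseline)`, `no_change` otherwise; the rule is
applied to the across-trial mean trace per animal (per-trial labels are also
emitted). One numerical choice deserves emphasis: the baseline SD is
computed from the **raw** samples of the baseline window, while the peak is
taken from a **smoothed** copy of the trace (1-s centred moving average by
default). The maximum of `n` independent noise samples grows without bound
with `n`, so a literal "any raw sample beyond 2 SD" rule would classify
nearly every noise trace as a response at realistic sampling rates.
Measuring the excursion on the smoothed trace against the raw-noise SD
demands a *sustained* excursion and gives the rule the false-positive
behaviour its users expect (under the defaults, fewer than 10% of pure-noise
traces are called responses, and the suite checks this). Set `smooth_s = 0`
to apply the literal rule.

## Long-term duty-cycled recordings

To limit photobleaching over days, acquisition runs 4 min in every 12
(`duty_on_min`/`duty_period_min`). The isosbestic fit is **global** across
all sessions — a per-session fit would absorb the circadian signal itself,
since both bleaching and the rhythm span sessions. Each session is reduced
to its 2nd percentile of dF/F (linear-interpolation percentile definition,
fixed for reproducibility), a lower-envelope statistic that tracks the slow
intracellular calcium level and is insensitive to upward transients from
spiking. Sessions with fewer than 50 samples become gaps and are excluded,
never interpolated.

The resulting 12-min series is fit per cycle by a least-squares cosinor
`level ~ M + A*cos(2*pi*(t - phi)/period)`; the acrophase is the absolute
time of the fitted peak within the cycle, and cycles whose amplitude falls
below twice its standard error are flagged arrhythmic. The cosinor period is
fixed (the behavioural free-running period when available, else 24 h) rather
than co-fit: one cycle of data cannot constrain a period. The rhythm phase
shift projects the pre-stimulus acrophases onto the post-stimulus cycles and
reports `-(mean observed - mean projected)`. By default the projection
advances by exactly one period per cycle — the slope already implied by the
cosinor model. An OLS-estimated slope (`slope = "fit"`) is available with at
least 3 pre cycles, but with the 2 pre-cycle design used here a fitted slope
extrapolated over 3 post cycles would inflate the estimator variance about
four-fold, so the fixed-period projection is the default.

# Two-photon ROI responses

ROI traces (30 frames/s) are normalised as `dF/F0 = (F - F0)/F0` with `F0`
the mean over the 10 s preceding the first stimulation. After averaging (or
on the full trace), the 1-SD rule types each ROI within a post-stimulation
window (stimulation onset to 30 s by default — the observation window is a
configurable choice, since no fixed endpoint is canonical):

* `typeI`: smoothed maximum above `+1 SD`, no later sample below `-1 SD`;
* `typeII`: maximum above `+1 SD` followed, after the peak frame, by a
  sample below `-1 SD` (an excitation/inhibition sequence);
* `nonresponder`: everything within `(-1, +1) SD`.

The raw-SD/smoothed-excursion construction described above applies here too,
and matters even more at a 1-SD threshold. A dip without a preceding peak is
not a defined class and is reported as `nonresponder`, with the excursion
magnitudes (`post_excursion_sd`, `post_dip_sd`) retained so such ROIs can be
audited. Condition contrasts (e.g. blocking network inhibition with
TTX/4-AP) are quantified by the trapezoidal AUC over 30–90 s and by label
flips: removing the inhibitory lobe converts typeII ROIs to typeI.

# The synthetic-data generator

Each generator draws from a single explicit seed (`withr::with_seed`), so
identical configurations give bit-identical data and cohort seeds derive
deterministically from one base seed; there is no hidden global RNG state.

* **Actograms** — onsets drift at `tau_h` (default 23.7 h, a typical
  C57BL/6J free-running period in constant darkness; the source experiments
  report the period unaffected by the stimuli but print no value), carry
  Gaussian jitter (default SD 0.2 h, chosen so 12-animal cohorts resolve
  0.2-h effects) and are displaced by the injected shift after the event
  day; counts are Poisson (defaults 60/2 per 5-min bin in the active/rest
  phase, with the active phase covering half the cycle). Named presets pin
  the injected shift to each experimental condition's reported cohort
  effect: footshock −0.4 h at CT14 and −0.2 h at CT22, light −1.2 h at CT14
  (130 lux) and +0.5 h at CT22 (225 lux), paired light+footshock −1.6 h at
  CT14 and +0.2 h at CT22, forced swim −0.4 h, and 0 at CT6 and for
  controls.
* **Trial photometry** — 2-min baseline, five stimuli at a 60-s interval;
  both channels share a mono-exponential bleach and multiplicative
  low-frequency motion; the signal channel adds a transient kernel per
  event: a difference of exponentials (rise 0.5 s, decay 3 s) for
  excitation; inverted, delayed by 2 s and decaying twice as slowly for
  inhibition (mirroring the longer latencies of evoked decreases without
  asserting biological time constants); both superposed for biphasic.
  Sampling is 20 Hz — a desk-scale rate that leaves all window metrics
  unchanged.
* **Long-term photometry** — the session-level calcium level follows
  `mesor + amp*cos(2*pi*(t - acrophase)/tau)` (defaults 0.3 + 0.2, peak at
  hour 6), with the cosine phase displaced by the injected shift after the
  event (delivered at the pre/post cycle boundary); sessions add sparse
  positive transients, shared bleach/motion, and white noise (default dF/F
  SD 0.005, giving session-level noise well under a quarter of the rhythm
  amplitude). Sampling is 1 Hz per session: 240 samples amply determine a
  2nd percentile.
* **ROI matrices** — types are drawn from `roi_type_probs`; typeI ROIs get
  sustained positive kernels (peak 0.3 dF/F0), typeII a brief positive
  kernel plus a slow negative lobe, nonresponders white noise (SD 0.05,
  so kernel amplitudes are several noise SDs); the TTX/4-AP condition
  removes negative lobes and scales excitation by 1.5, the CNQX/AP5
  condition abolishes evoked responses.

## What the generator does and does not emulate

It reproduces the *structure* that the estimators rely on: drifting onsets
with day-to-day jitter, shared multiplicative photometry artifacts, a
cosine-shaped circadian calcium envelope under a duty cycle, and
kernel-shaped evoked transients. It does not emulate ultradian activity
bouts, wheel-availability artifacts, non-shared (channel-specific) motion,
state-dependent transient rates, or cell-to-cell kernel heterogeneity beyond
type labels. Passing recovery tests therefore demonstrates that the
estimators are unbiased and correctly signed under the assumed data model —
not that real recordings satisfy that model; on real data the isosbestic
assumption (artifacts shared and multiplicative) is the first thing to
check.

# Problem sizes and reproducibility

The test suite and the acceptance script run cohorts of 12 animals with
7 + 7 days for locomotor recovery, 7 animals with 2 + 3 days of duty-cycled
1-Hz photometry for rhythm recovery, 500 labelled traces per classifier
bound, and 1000 ROIs for the typing bound — sizes chosen to match the
experimental designs while keeping a full run in tens of seconds.
`scripts/acceptance.R --seed S --out F` regenerates every cohort from the
given seed and writes the recovered cohort-mean shift magnitudes as JSON.
The numbered scripts under `analysis/` run the same pipelines as narrative
analyses and write their tables under `results/`; the package functions they
call are the interface for programmatic use, so no shell CLI is provided.

# Known limitations

* Onset detection partitions the record into calendar days; onsets crossing
  the day boundary (extreme `tau` over long records) rely on unwrapping and
  would eventually need cycle-length partitioning (`cycle_h`).
* The chi-square periodogram inherits the bin resolution (1/12 h); periods
  are not interpolated between candidates.
* With exactly 2 pre-event cycles the rhythm-shift projection cannot detect
  a period error in the fixed slope; a wrong assumed period biases the shift
  by (true - assumed) per cycle of extrapolation.
* The SD-threshold classifiers assume the baseline window is
  response-free; anticipatory activity would inflate the baseline SD and
  make the rules conservative.
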