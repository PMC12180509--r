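# zeitshift

Quantification of stimulus-induced phase shifts of the circadian pacemaker,
for chronobiologists and systems neuroscientists analysing:

* **wheel-running actograms** — daily activity-onset detection, pre/post
  onset regressions, phase-shift and free-running-period estimation
  (onset-regression slope and Sokolove–Bushell chi-square periodogram);
* **event-locked fiber photometry** — isosbestic-corrected ΔF/F, trial
  segmentation, AUC / signed peak / latency metrics, and ±2 SD response
  classification (excitatory / inhibitory / no change);
* **duty-cycled long-term photometry** (4 min recorded per 12 min, for
  days) — global isosbestic fit, 2nd-percentile session levels, per-cycle
  cosinor acrophase, and acrophase-based pacemaker phase shifts;
* **two-photon ROI trace matrices** — ΔF/F0, stimulation-averaged responses,
  ±1 SD type I / type II / nonresponder typing, and 30–90 s AUC condition
  contrasts.

Every estimator ships with a synthetic-data generator that emulates the
corresponding experiment with known ground truth, so the whole chain is
validated by parameter recovery.

## The core quantities

With the phase-response-curve sign convention (advance positive, delay
negative):

* locomotor phase shift: onsets are regressed on day index separately
  before and after the stimulus and both lines evaluated at the event day,
  `Δφ = −(post intercept − pre intercept)`; the free-running period is
  `τ = 24 + slope`;
* photometry: `ΔF/F = (signal − fitted reference) / fitted reference`, the
  fitted reference being one least-squares line `a·ref + b` over the whole
  recording; responses are classified against `±2 × SD(baseline)` with
  baseline 0–10 s and stimulus window 10–20 s (shock) or 10–40 s (light);
* calcium rhythm: each session's 2nd percentile of ΔF/F forms a 12-min
  series, fit per cycle by a cosinor
  `level ≈ M + A·cos(2π(t − φ)/τ)`; the rhythm shift is
  `−(mean observed post acrophase − mean projected)`;
* ROI typing: type I if the post-stimulation excursion exceeds `+1 SD` with
  no later dip below `−1 SD`, type II if the dip follows the peak,
  nonresponder inside `±1 SD`.

## Worked example

Simulate a 12-animal cohort in which footshock at CT14 delays the clock by
0.4 h, then recover the shift from the actograms alone:

```r
library(zeitshift)

tab <- cohort_phase_shifts("ct14_footshock", n_animals = 12, seed = 1)
head(tab, 3)
#>              animal    shift_h magnitude_h direction pre_period_h post_period_h true_shift_h
#> 1 ct14_footshock_01 -0.4077381   0.4077381     delay     23.72917      23.70833         -0.4
#> 2 ct14_footshock_02 -0.3392857   0.3392857     delay     23.68452      23.73810         -0.4
#> 3 ct14_footshock_03 -0.4107143   0.4107143     delay     23.69643      23.69940         -0.4

mean(tab$shift_h)
#> [1] -0.4330357
```

The cohort mean, −0.43 h, recovers the injected −0.4-h delay within the
0.2-h day-to-day onset jitter of the generator; each animal's pre/post
free-running period stays near the simulated τ = 23.7 h. The same pipeline
applied to a single record:

```r
cfg <- preset_config("ct14_footshock", seed = 1)
sim <- simulate_actogram(cfg)
ps  <- estimate_phase_shift(sim$record, event_day = cfg$event_day)
ps$shift_h      # signed hours; negative = delay
ps$direction    # "delay"
plot_actogram(sim$record)   # double-plotted raster
```

The numbered scripts under `analysis/` run the full study-style analyses and
write tables under `results/`:

```sh
Rscript analysis/02_locomotor_phase_shifts.R
#> ct14_footshock   mean -0.50 h (injected -0.40)  t=-4.87 p=7.2e-05
#> ct14_light       mean -1.18 h (injected -1.20)  t=-12.29 p=2.5e-11
#> ct14_paired      mean -1.62 h (injected -1.60)  t=-16.66 p=5.9e-14
#> ...
Rscript analysis/04_longterm_rhythm.R
#> footshock: mean -0.411 h (injected -0.40); sham:  0.002 h
```

`01` writes example datasets in the on-disk CSV/JSON formats, `03` runs the
trial-photometry classification (inhibition peaks later than excitation:
3.45 s vs 1.18 s in the run above), and `05` types a simulated ROI
population and reproduces the type II → type I conversion when network
inhibition is blocked.

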