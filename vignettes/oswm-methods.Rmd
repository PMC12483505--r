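---
title: "Methods: selectivity, population bursts, replay decoding and ACC-CA1 coupling"
author: "oswm package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: selectivity, population bursts, replay decoding and ACC-CA1 coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The task and the data model

The package analyzes paired anterior cingulate (ACC) and hippocampal CA1
single-unit recordings from an observational spatial working memory task:
in each trial an observer rat watches a demonstrator choose the left or
right arm of a T-maze from a nearby observation box, is rewarded for poking
on the matching side of the box, and must later run the same trajectory
itself. A session is ~40 trials; a trial contributes a *delay period* (the
2 s before the observer's first rewarded poke, the window in which the
observer has seen the demonstrator's choice), a *water-consumption period*
right after the poke, and maze running laps on the four linearized
trajectories (left/right x outbound/inbound).

All analyses run on a plain-text session bundle (`spikes.csv`,
`position.csv`, `trials.csv`, `intervals.csv`, `manifest.yaml`) holding
sorted spike times per unit with a region label, a 30 Hz position series
with linearized trajectory coordinates, and per-trial event tables. Time is
in session-relative seconds and every interval is half-open `[start, end)`,
which makes binning and interval arithmetic free of boundary double
counting. The water-consumption period has no principled endogenous
definition, so it is an input: the trial table carries its bounds (the
generator emits them; for recorded data the user supplies them).

# Selectivity and difference indices

For each ACC cell the per-trial firing rate on the left or right side of
the maze is the spike count during active running (stopping periods —
speed < 5 cm/s sustained > 3 s — excluded) divided by running time,
outbound and inbound combined, over correct trials. A cell is *selective*
when a two-sided two-sample t-test on the per-trial rates gives p < 0.05.
The test defaults to Student's pooled-variance form — the plain reading of
"two-sided t-test" — with Welch available via `var_equal = FALSE`. The
selectivity index is

$$SI = \frac{FR_{right} - FR_{left}}{FR_{right} + FR_{left}} \in [-1, 1],$$

undefined (and the cell excluded, with a flag) when both rates are zero.
Box selectivity applies the same classifier to delay-period rates; by
default it, too, uses correct trials only, mirroring the maze definition
(`correct_only = FALSE` includes all trials — the choice is exposed because
the original procedure does not pin it down).

The population-level question is whether more cells are selective *on the
same side* in box and maze than chance allows. The chance distribution is
built by permuting each cell's delay-period rates across the pooled
left+right trials (a label permutation that preserves each cell's rate
multiset), re-classifying, and recounting the same-side fraction 1000
times; the observed fraction is z-scored against this distribution and
converted to a one-sided normal-tail p-value (`z_to_p`). The difference
index (DI) applies the same functional form to correct- vs error-trial
delay rates of same-side-selective cells on their preferred side, computed
only when the session has at least three error trials on that side;
population DI is tested against 0 with a two-sided one-sample t-test, and
the fraction of individually significant positive-DI cells is compared to a
1000-fold correct/error label permutation.

# Population burst events

Sharp-wave-ripple-associated events are detected from multiunit activity
alone: all CA1 spikes are binned at 10 ms, smoothed with a Gaussian kernel
of sigma = 2 bins (truncated at ±4 sigma and renormalized at the edges, so
constants are preserved), and min–max standardized to [0, 1]. A population
burst event (PBE) is a maximal run of bins at or above 0.15 containing a
bin at or above 0.35; events separated by less than 30 ms are merged.
Threshold comparisons are inclusive (`>=`) to avoid float-equality
flakiness. The standardization window is the whole session — the simplest
faithful reading of "standardized from 0 to 1" — and a per-epoch variant
can be had by slicing the trace before standardizing. Because the scale is
set by the session's largest smoothed bin, detection is invariant to
uniform spike-count offsets only up to re-standardization; this is a
property of min–max scaling, not of the implementation.

# Templates, ensembles and Bayesian replay decoding

Each CA1 cell's spatial rate curve on a trajectory is its spike count per
2 cm bin divided by occupancy time per bin (active running only), with
counts and occupancy smoothed by the same 2-bin Gaussian before the ratio;
never-occupied bins are invalid and excluded from curve statistics. A cell
joins a trajectory's template when its curve peak is at least 3 SD above
the curve mean (statistics over valid bins) and strictly above the mean, so
constant curves are excluded. The 3 SD criterion is deliberately weak — on
these smoothed curves it sits close to the boundary for wide fields, and
occasionally admits a cell whose "field" is baseline noise; this matches
the permissiveness of the original criterion and is why ensembles may
contain a few low-rate members. A side's *ensemble* is the union of its
inbound and outbound template members; ensemble rates aggregate all member
spikes.

PBEs with at least four active template members are candidates. Decoding
assumes independent Poisson spiking: in each 20 ms window (10 ms step; a
trailing partial window is kept when at least half a window long, and its
actual length is used as tau),

$$P(x \mid n) \propto \prod_i (\tau f_i(x))^{n_i} e^{-\tau f_i(x)}$$

under a uniform spatial prior, computed in the log domain and normalized
per window. Template rates are clamped below at `rate_floor` (0.001 Hz) so
empty spatial bins keep a finite log-likelihood. The decoded position is
the per-window posterior argmax (ties resolve to the lowest position);
zero-spike windows are excluded from the decoded series by default because
their posterior reflects only the $e^{-\tau f}$ factor and biases the
sequence correlation. The replay statistic is the Pearson correlation *r*
of decoded positions against window indices, compared with 1000
correlations obtained by permuting the window indices; `p = (1 + #{|r_s|
\ge |r|}) / (n + 1)`, so p is never 0. The default is two-sided on |r|
because forward and reverse replays are both of interest; the one-sided
greater-than-actual convention is available (`sided = "one.sided"`). An
event significant for several templates increments each template's
per-trial count — no exclusivity rule is imposed.

**A calibration caveat worth knowing.** With overlapping 20 ms/10 ms
windows, adjacent windows share spikes, so even order-free burst events
have autocorrelated decoded positions; measured against the time-bin
shuffle this inflates the nominal 5% replay call rate to roughly 10–12% on
such events. This is a property of the shuffle test under overlapping
windows, not an implementation artifact. The package's calibration test
therefore destroys replay structure the way the field's time-bin shuffle
does — by permuting the columns of the event's spike-count matrix — under
which the test is exactly exchangeable and calibrated. Replay-rate
comparisons between conditions are unaffected (the inflation is common to
both); absolute replay counts should be read with this in mind.

# ACC–CA1 coupling

Four families of statistics quantify the interaction between each
maze-selective ACC cell and its same-/opposite-side CA1 ensemble:

* **Delay cross-correlation** — ACC and ensemble spike counts in 200 ms
  bins within each delay period, correlated per trial at lags up to ±5
  bins (±1 s; longer lags leave too few overlapping bins in a 2 s delay)
  and averaged over trials; the lag-0 value is the cell's statistic. The
  per-trial-average mode is the default; a pooled mode that gathers bin
  pairs across all delay periods before a single correlation per lag is
  config-selectable, since the two readings of the procedure differ.
* **Water-period correlation** — the ACC rate over the whole water interval
  (no finer structure is imposed on ACC activity there) against the
  ensemble's in-SWR rate (member spikes inside the trial's PBEs divided by
  total PBE time; trials without PBEs are missing and drop out pairwise),
  correlated trial by trial.
* **Delay-to-SWR correlation** — the ACC delay rate against the same
  in-SWR ensemble rate, linking observation-period activation to
  subsequent SWR content.
* **Replay-count correlation** — the ACC delay rate against the per-trial
  number of significant replays of the same/opposite inbound or outbound
  template.

Population summaries are one-sample t-tests of the mean statistic against
0 and paired t-tests of same vs opposite, with the sidedness recorded per
analysis as metadata: two-sided for the delay cross-correlation and the
delay-to-SWR correlation, one-sided for the water-period and replay-count
analyses, following the directional hypotheses those analyses carry.
Benjamini–Hochberg-adjusted p-values are written as a supplementary column
of `population_tests.csv` and never feed the headline per-cell counts,
which reproduce the uncorrected alpha = 0.05 convention.

# The synthetic generator and what it does (not) emulate

`generate_session()` builds a full session with known ground truth:
~40 left/right trials (11% errors), a delay window of 2 s plus exponential
jitter so its mode sits at 2 s, 64 s of maze running per trial at constant
speed on a 200 cm linearized trajectory, CA1 place cells (baseline 0.5 Hz,
Gaussian fields of sigma 10 cm peaking 8 Hz above baseline — maze means
inside the 0.4–10 Hz active-cell band), and ACC cells whose delay, water
and maze rates are stepped by a side-preference ratio (default 2), with
error trials attenuating the preferred-side delay rate (default 0.75).

During each water period, a Poisson number (mean 3) of bursts is embedded.
A burst is a time-compressed virtual traversal of one trajectory template:
each member fires one ordered anchor spike (jitter SD 5 ms) plus on average
2.5 field-locked extras as the virtual position crosses its field, while
non-member CA1 cells receive a 15-fold diffuse rate surge so the MUA
detector sees a concurrent population burst. The template is the trial's
same side with probability `replay_bias` (default 0.7), inbound/outbound
and forward/reverse each with probability 0.5. Sequence spikes are
stereotyped; the trial-wise excitability gain rides on the diffuse surge.
That gain is the coupling plant: one latent excitability series per side
drives the side's CA1 in-burst rates through a mean-one lognormal gain
(log-scale SD 0.35, about ±35% trial-to-trial modulation — large enough to
carry a detectable correlation, small enough that burst amplitudes stay
within the min–max detector's dynamic range), and each ACC cell draws its
own gain series correlated with its preferred side's latent series at
`coupling_strength` (default 0.4), applied to the cell's delay and water
rates on every trial. The per-cell construction matters: a single gain
shared by all cells of a side would make every cell in a session carry the
same realization, and population tests across cells would then see a
session-level random effect and reject far above their nominal level even
with no planted effect. With per-cell gains, cells are conditionally
independent given the ensembles and the population tests calibrate. For
the same reason the error-trial DI calibration runs disable nothing — the
per-cell gains are independent across cells, so the DI null is a true
null.

What the generator does *not* emulate: theta phase precession,
interneurons, LFP waveforms, 2-D exploration, overdispersed (non-Poisson)
spiking, drift in field positions, or within-delay fast co-fluctuations of
ACC and CA1 rates. The last point matters for interpretation: the planted
coupling is trial-scale, so the delay cross-correlation analysis has no
planted effect in synthetic data (its correctness is verified by
construction — an ensemble duplicating the ACC train must give lag-0 r = 1
— rather than by recovery). Passing recovery tests on this generator shows
the estimators extract what was planted under Poisson noise; it does not
certify behavior under real data's richer failure modes.

# Numerical choices and degenerate inputs

* Half-open intervals everywhere; spikes exactly on bin edges go to the
  later bin.
* Gaussian kernels are truncated at ±4 sigma and renormalized at edges.
* The decoder works in log space with a log-sum-exp normalization; argmax
  ties take the lowest position.
* Permutation p-values use the `+1/(n+1)` correction and are two-sided on
  the magnitude where both signs are meaningful.
* Cells with zero rates on both sides (SI/DI undefined at 0/0), trials
  with zero variance in a correlation, delay windows lacking a poke, and
  sessions without error trials are excluded with flags/log entries rather
  than propagating NaN.
* `write_session` formats floats to six decimals (microsecond resolution)
  in a fixed column order, so bundles are byte-stable and diffable.

# Problem sizes used by the test suite

The statistical tests run on sizes chosen to give each check adequate
power while keeping the suite quick: calibration of the selectivity
classifier uses 1000 synthetic cells (10 sessions x 100 ACC cells, 8 s
laps); error-trial DI recovery uses 100 seeded sessions per condition with
`p_error = 0.25` so most sessions clear the 3-error minimum; coupling
recovery uses 100 sessions of 30 ACC cells at latent gain correlation 0.4
(50 null sessions), run on the generator's neutral grid — selectivity
ratio 1 with ground-truth cell labels, high-rate ACC cells and dense SWR
sampling — so the planted correlation is the only left/right asymmetry
and its estimate is measurement-limited (with a planted rate asymmetry,
same-preference cells would share the side pattern's chance correlation
with the single ensemble realization, a session-level random effect no
cell-level test can calibrate away); replay-bias recovery uses 10 full-pipeline sessions at
`replay_bias = 0.8` with 500 decoding shuffles; the shuffle-calibration
check uses 1000 structure-destroyed candidate events at 1000 shuffles
each. Sessions in fast loops shorten maze laps (8–12 s) — lap length only
sets the precision of maze rate estimates, not the statistics under test —
while replay-dependent checks keep 32 CA1 cells (8-member templates) and
long laps for well-estimated templates.

# Known limitations

* The min–max standardization makes absolute PBE detection sensitive to
  the session's single largest burst; heavy-tailed burst amplitudes push
  weak events below the relative threshold.
* The time-bin shuffle's anticonservativeness under overlapping windows
  (above) applies to absolute replay rates.
* The 3 SD template criterion is permissive on smoothed curves; template
  membership should not be read as a strong place-field claim.
* Trial-by-trial correlations use pairwise-complete observations; sessions
  with few PBE-containing trials yield noisy in-SWR rate correlations and
  are flagged by the per-cell `n`.
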