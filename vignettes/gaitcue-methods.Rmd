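---
title: "Methods: gait-event detection, step-time variability and on-demand cueing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gait-event detection, step-time variability and on-demand cueing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitcue)
```

## The problem

Freezing of gait (FoG) is a sudden, brief inability to advance the feet that
affects many people with Parkinson's disease. Episodes are often preceded by a
*pre-FoG window* in which step-to-step timing becomes markedly more variable.
A projected visual cue (a laser line on the floor ahead of the walker) can
help re-initiate or stabilize gait, but a continuously present cue loses
effect through habituation. The idea behind *on-demand* cueing is to watch
step-time variability in real time and switch the cue on only when a surge —
the pre-FoG signature — is detected.

`gaitcue` implements the complete computational chain of such a device as an
offline/streaming engine: plantar-pressure (FSR) event detection, step-time
variability tracking, the ratio-threshold strategy generator that triggers the
cue, and a closed-loop simulator in which cue visibility feeds back on the
generated gait, so every part of the logic can be validated on synthetic data
with known ground truth.

## Signal model

An insole carries three force-sensitive resistors per foot: two under the heel
(lateral and medial, so that a contact under either site is seen regardless of
foot inversion/eversion) and one under the toe. Channels are digitized to
integer counts on a 0–1023 scale. Logs are uniformly sampled; the default rate
is 100 Hz (adequate for ±10 ms event timing), carried in the file header and
configurable. Time is in seconds with `t = 0` at the first sample. A log with
non-uniform spacing (beyond 1e-9 s) is rejected rather than resampled: gap
filling would silently distort the variability statistics that everything
downstream depends on.

Two pathway markers, `segment_start` and `segment_end`, delimit a timed
10 m segment; the physical delineator hardware is abstracted to these
instantaneous events.

## Event detection

The two heel channels of a foot are merged by element-wise maximum. A *contact
episode* is a maximal run of samples at or above the peak-validity threshold
(50 counts by default). The heel strike is stamped at the episode's maximum
sample — earliest sample on ties, for determinism — matching a device that
records the time stamp of the valid peak; an `onset` anchor (first
supra-threshold sample) is available in the detector configuration. A new
episode is admitted only after the signal has returned to the valley level (0
counts by default) since the previous one, so a shallow trough between two
peaks does not split one stance into two strikes. `valley_epsilon` relaxes the
valley level for noisy signals whose baseline never sits exactly at zero.

The toe-off of a stride is the first sample at or after the heel strike where
the toe channel, having loaded above the valley level, returns to it. The
search is bounded by the next ipsilateral heel strike; a heel strike whose
toe-off is not observed within that bound is flagged incomplete rather than
fabricated. Events are labelled `L+`/`R+` (heel strikes) and `L-`/`R-`
(toe-offs) and merged into a single time-ordered sequence, left before right
on exact ties.

## Gait metrics

*Step time* is the interval between consecutive heel strikes of opposite
legs; consecutive ipsilateral strikes (a missed contralateral event) yield no
step and are flagged. Variability is summarized as the coefficient of
variation in percent,

$$\%CV = \frac{SD}{mean} \times 100,$$

with the sample (n−1) standard deviation by default (`sd_denominator = "n"`
gives the population form). The rolling %CV array uses pairwise windows
(window 2) by default — one value per consecutive pair of step times, the
literal reading of a per-step variability array — with larger windows
configurable. Step times are *not* filtered by plausibility bounds: freezing
manifests exactly as implausibly long intervals, and the variability statistic
must see them.

Walking speed is the marked segment length (10 m by default) divided by the
time between the two markers. Percent time frozen is the measure of the
*union* of the FoG annotation intervals clipped to the walk interval (the
marked segment when markers exist, else the full log), so overlapping labels
are never double-counted; the episode count is the number of connected
components of that union.

## The strategy generator

After each step the controller appends one entry to its %CV array and forms
the ratio of the newest entry to a reference. The decision rule is fixed by
the device design: a ratio at or above the upper threshold 2.5 (inclusive)
fires the cue; a ratio strictly inside the lower band (0.5, 1) — a
hesitation-like drop — also fires it when the lower band is enabled, which is
the default; anything else is a non-trigger. Zero-variability conventions
keep regular gait quiet: both terms zero gives ratio 1; a zero reference with
a positive numerator gives `Inf` (which triggers).

### Why the reference is a running baseline

The minimal reading of the ratio — newest %CV entry over the previous one —
turns out to be unusable, for a structural reason: with short %CV windows the
consecutive-entry ratio is *scale-free*. For pairwise windows it behaves like
a ratio of correlated half-normal variables; the probability that it exceeds
2.5 on perfectly steady gait is about 0.22 *per step* at any baseline
variability level, so essentially every walk would false-trigger, while the
same heavy tails also cap genuine detection power. No threshold choice fixes
this: the statistic does not know the walker's own baseline.

The controller therefore references the newest entry against the *running
median of all earlier entries*. The median is robust to the very surges the
detector is looking for (they should not inflate the reference), and the
ratio then rises persistently — not just transiently — through a variability
surge, which also makes the release rule meaningful. The literal
consecutive-entry quotient remains available via
`strategy_config(ratio_reference = "previous")`.

Two further controller parameters were sized by a design simulation of the
detector's operating characteristics (the acceptance script re-measures them
on every run): the controller's %CV window is 7 steps and the warm-up is 8
entries (first decision once 8 entries exist, i.e. after the 15th heel
strike). Shorter windows make the numerator too heavy-tailed to keep
false-trigger walks below a few percent; longer ones dilute a surge across
too many old samples to react within about three steps. At these settings a
tenfold step-time-SD surge is flagged within three steps in ≈98% of walks
while fewer than ≈2% of steady 100-step walks ever false-trigger through the
upper threshold. Note what this window does *not* change: the gait-metrics
rolling %CV stays pairwise; only the controller's internal array is smoothed.

### Cue release

The device literature does not say how long the cue stayed on. The default
release closes the cue after 2 consecutive non-triggering decisions; because
the reference is the pre-surge baseline, the ratio stays elevated for as long
as the variability is elevated, so the cue naturally spans a sustained surge
and drops ~2 steps after gait restabilizes. A fixed-duration release
(`fixed_duration_s`, refreshed by re-triggers) is the alternative. The cue
interval opens at the heel-strike time of the triggering step; intervals are
clipped to the walk span and adjacent ones merge.

The cue line itself is projected 0.4 × body height ahead of the walker and is
1.5 m long.

## The simulator

Step times are drawn from a log-normal distribution — positive, right-skewed,
and fully determined by the configured mean (0.55 s) and CV (3% at baseline).
Defaults describe a freeze-prone parkinsonian walker on a long straight
corridor: 120 steps (~70 s — an extended bout long enough for habituation
dynamics to matter), a pre-FoG burst multiplying the CV by 5 for 25 steps
from step 60, and 0.5 m steps with the marked 10 m segment at 27.5–37.5 m,
bracketing the middle of the bout where the default burst sits.

**Freezes.** A freeze inserts a step-free gap (0.5 s plus an exponential
remainder, mean 2.5 s) before the next heel strike. The per-step hazard is a
hinge in the recent pairwise %CV of the realized step times:

$$p = \min\left(p_{max},\; b + g \cdot \max(0,\; \%CV_{recent} - c_{ref})\right)$$

with defaults `b = 0.001`, `g = 0.006` per %CV point, `c_ref = 6%`,
`p_max = 0.06`. The hinge encodes that freezes are precipitated by *elevated*
variability — the pre-FoG window — while steady gait carries only a small
background risk; a purely linear coupling would spread the risk evenly over
the walk and wash out the difference between episodic and continuous cueing.
The cap keeps the post-freeze feedback loop (a freeze itself spikes the
recent %CV, raising the hazard of an immediate successor) from running away;
freeze clustering at a moderated rate is intended, as clustered episodes are
characteristic of real FoG.

**Cue response.** While a cue is visible the step-time SD is multiplied by
`rho` (default 0.6), and the same factor gates the %CV input of the freeze
hazard — the cue attenuates the freeze-provoking signal, which is the premise
of cueing therapy. Under continuous exposure the effect habituates:
`1 − rho` decays exponentially at `habituation_rate` (default 0.02/s) with
exposure time. On-demand exposure is intermittent and keeps full salience —
habituation avoidance is precisely the rationale for on-demand cueing. Both
magnitudes are modeling choices, *not* estimates from any measured
dose-response; only their signs and the existence of habituation are
empirically grounded. Consequently the closed-loop results are qualitative
(orderings across modes), never quantitative predictions.

**Waveforms.** Stance loading is synthesized as piecewise-linear ramps: the
heel rises over 80 ms to peak exactly at the true heel-strike time and
unloads within half the stride; the toe loads shortly after heel contact,
plateaus, and returns to zero exactly at the true toe-off. Peaks default to
400 (heel) and 300 (toe) counts. The shapes are deliberately simple — the
detector thresholds care only about peak/valley structure and timing — and
ground truth is emitted alongside, so detection can be scored to within one
sample period. Additive Gaussian ADC noise (clipped to 0–1023) is available;
with noise the valley never sits exactly at zero, which is what
`valley_epsilon` is for.

**What the simulator does not emulate.** Real FSR nonlinearity and drift,
double-limb-support overlap of loading curves, turning or non-straight paths,
inter-stride amplitude variation, and any kinematics beyond timing. Passing
the round-trip tests therefore demonstrates the correctness of the decision
logic and metrics on signals with the assumed peak/valley structure — not
detector robustness on arbitrary clinical recordings.

## The closed loop and the simulated cohort

In a closed-loop session, steps are generated one at a time; the streaming
controller is fed each realized step time (exactly what a device measures,
freeze gaps included) and its state determines cue visibility for the next
step. The random draws are consumed identically in all modes, so with
`rho = 1` and zero habituation the three modes produce bit-identical walks
from the same seed — the null-effect case — and any divergence is exactly
the cue effect.

The simulated cohort pairs seeds across modes within a participant (a
matched-walk design, sharpening mode contrasts the way repeated-measures
designs do) and draws a per-participant severity covariate that scales the
freeze hazard and burst magnitude while also generating UPDRS-III, H&Y and
disease-onset values, so FoG counts and clinical scores are positively
associated by construction and the correlation pipeline can be validated
end-to-end.

## Numerical conventions

* Peak ties within an episode: earliest sample wins. Simultaneous left/right
  events: left first. Both deterministic.
* `percent_cv` demands n ≥ 2 and a positive mean; it never returns NaN.
* `pearson_r` delegates to the standard product-moment routine and snaps
  results within 1e-12 of ±1 to exactly ±1: perfectly affine inputs can land
  a few ulps inside the poles through the square roots in the denominator.
* Interval unions treat touching intervals as one component.
* Timestamps are validated strictly increasing and uniform to 1e-9 s; CSV
  round trips preserve numeric fields bit-exactly (17 significant digits).
* Walk-config seeds are plain 32-bit integers; every stochastic quantity in a
  walk, a session or a cohort derives from them.

## Problem sizes

The test suite validates detection against ground truth on 100 seeded
120-step walks, replays the controller against an independent brute-force
implementation on 500 seeded walks, measures trigger operating
characteristics on 500 + 500 seeded 100-step walks, and compares the three
cueing modes over 200 seeds with the full synthesis–detection–metrics
pipeline per session. The acceptance script repeats the same measurements at
slightly smaller sizes (60/300/300/120 seeds) from a user-supplied master
seed. These sizes give Monte-Carlo standard errors comfortably below the
margins being asserted while keeping a full run in the low minutes.

## Known limitations

* The controller's operating characteristics are tuned for surges of several
  fold; a gradual drift in variability raises the running median along with
  the numerator and may never trigger. A device would periodically re-anchor
  the baseline; re-anchoring policies are out of scope here.
* With the lower band enabled (the default, mirroring the device's
  hesitation heuristic), ratios drift into (0.5, 1) often enough that
  on-demand cue exposure is high on variable gait; disable the band
  (`lower_band_enabled = FALSE`) to study the upper-threshold trigger in
  isolation.
* Percent changes between modes depend on every free simulator parameter;
  they reproduce observed orderings qualitatively and are not calibrated to
  any measured cohort.
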