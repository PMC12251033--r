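# gaitcue

Gait-event detection, step-time variability tracking and on-demand visual
cueing simulation for freezing-of-gait (FoG) research.

People with Parkinson's disease often experience FoG — sudden episodes in
which the feet will not advance — typically preceded by a *pre-FoG window* of
sharply increased step-time variability. A projected laser line on the floor
can stabilize gait, but a continuously visible cue habituates. `gaitcue`
implements, in software, the full decision chain of a wearable that delivers
the cue *on demand*: plantar-pressure (FSR) gait-event detection, step-time
variability (%CV) tracking, the ratio-threshold strategy generator that fires
the cue, a closed-loop gait simulator with ground truth, and a cohort
pipeline. It is aimed at researchers who want to study and validate cueing
decision logic and gait metrics without hardware, on reproducible synthetic
walks.

## The core method

From each foot's FSR channels (0–1023 ADC counts; two heel sites merged by
element-wise max), a **heel strike** is the peak sample of a contact episode —
a maximal run of samples ≥ 50 counts, admitted only after the signal has
returned to the 0-count valley since the previous episode. The **toe-off** is
the first return of the toe channel to the valley after loading. **Step
time** is the interval between consecutive contralateral heel strikes, and
its variability is

```
%CV = SD / mean × 100          (sample SD, n − 1)
```

kept as a rolling array. The **strategy generator** compares the ratio of
the newest %CV entry to the walker's running-median baseline against an upper
threshold **2.5** (cue on: variability surge, the pre-FoG signature) and a
lower band **(0.5, 1)** (cue on: hesitation-like drop), releasing the cue
after two consecutive non-triggering decisions. The cue line (1.5 m long) is
projected at 0.4 × body height ahead of the walker. **Walking speed** is
timed over a marked 10 m segment, and FoG exposure is measured as the
interval-union of annotation episodes.

The closed-loop simulator draws log-normal step times (with pre-FoG bursts,
hinge-hazard freezes coupled to recent %CV, and start hesitation), lets cue
visibility scale the step-time SD by `rho = 0.6` (habituating at 0.02/s under
continuous exposure only), and synthesizes FSR waveforms whose true event
times are known to the sample.

## Worked example

One simulated freeze-prone walker (seed 4), walked under each cueing mode:

```r
library(gaitcue)

for (m in c("none", "continuous", "on_demand")) {
  ses <- closed_loop_session(walk_config(seed = 4), m)
  r   <- analyze_session(ses$log, ses$truth$fog, mode = m)
  cat(sprintf("%-10s cv %.2f  speed %.3f  fog %d  frozen %.2f%%  cue-on %.1f%%\n",
              m, r$mean_pairwise_cv, r$walking_speed_mps, r$n_fog_episodes,
              r$pct_time_frozen, r$cue_on_fraction))
}
#> none       cv 7.67  speed 0.551  fog 2  frozen 37.13%  cue-on 0.0%
#> continuous cv 5.65  speed 0.816  fog 2  frozen 9.44%  cue-on 100.0%
#> on_demand  cv 3.39  speed 0.905  fog 0  frozen 0.00%  cue-on 59.7%
```

Each line is one full pipeline run: FSR synthesis → event detection → step
times → metrics (plus the cue controller for `on_demand`). For this walker,
uncued gait freezes twice inside the timed segment (walking speed 0.55 m/s,
37% of the segment spent frozen); the continuous cue damps variability but
has habituated by the time the pre-FoG burst arrives; the on-demand cue fires
into the burst at full strength — mean pairwise %CV drops to 3.4, no freezes
occur, and speed recovers to 0.91 m/s with the cue visible only 60% of the
walk.

The pieces are available individually:

```r
log    <- closed_loop_session(walk_config(seed = 7), "on_demand")$log
events <- detect_gait_events(log)        # 121 heel strikes, 121 toe-offs
steps  <- step_times(events)             # 120 steps, mean 0.551 s
mean(rolling_cv(steps))                  # 3.02 (% pairwise CV)
walking_speed(log)                       # 0.898 m/s over the marked 10 m
cue_line_placement(1.75)                 # $distance_m 0.7, $line_length_m 1.5
```

A thin CLI wraps the same functions
(`Rscript inst/cli/gaitcue.R {simulate|detect|metrics|cue|cohort} ...`).

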