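# Synthetic gait generator with ground truth: log-normal step times with
# pre-FoG variability bursts, hinge-hazard freeze episodes coupled to recent
# pairwise %CV, start hesitation, a cue-response model (SD reduction while a
# cue is visible, habituation under continuous exposure), and piecewise-linear
# FSR waveform synthesis.

#' Walk simulation configuration
#'
#' Defaults describe a freeze-prone parkinsonian walker on a long straight
#' corridor: 120 steps of mean 0.55 s at 3% baseline step-time CV, a pre-FoG
#' variability burst (CV multiplied by 5 for 25 steps from step 60), and a
#' freeze hazard that rises once recent pairwise %CV exceeds a pre-FoG level.
#' A marked 10 m segment (27.5 m to 37.5 m at 0.5 m per step) brackets the
#' middle of the bout for walking-speed computation.
#'
#' @param seed Integer RNG seed; every draw of the walk derives from it.
#' @param n_steps Number of step intervals. Default 120.
#' @param mean_step_time Mean step time in seconds. Default 0.55.
#' @param baseline_cv Baseline step-time CV in percent. Default 3.
#' @param burst `NULL` or list `onset_step`, `length_steps`,
#'   `cv_multiplier >= 1`: the CV is multiplied inside
#'   `[onset_step, onset_step + length_steps - 1]`.
#' @param freeze `NULL` or list `hazard_base` (per-step probability),
#'   `hazard_cv_gain` (per %CV point above `hazard_cv_ref`), `hazard_cv_ref`
#'   (%CV hinge), `hazard_max` (cap) and `duration_s` (mean episode length;
#'   episodes are 0.5 s plus an exponential remainder).
#' @param hesitation `NULL` or list `mean_delay_s`: an exponential extra delay
#'   before the first heel strike.
#' @param cue_response List `rho` (step-time SD multiplier in `(0, 1]` while a
#'   cue is visible, default 0.6) and `habituation_rate` (per-second decay of
#'   `1 - rho` toward 0 under continuous exposure, default 0.02).
#' @param amplitude List `heel_peak`, `toe_peak` in ADC counts (defaults
#'   400/300), both above the 50-count validity threshold.
#' @param noise_sd Additive ADC noise SD (clipped to `[0, 1023]`). Default 0.
#' @param sample_rate Synthesis sampling rate in Hz. Default 100.
#' @param step_length_m Distance advanced per step in meters. Default 0.5.
#' @param segment_start_m,segment_end_m Positions of the pathway delineators
#'   in meters walked, or `NULL` for no markers. Defaults 27.5 and 37.5
#'   (a 10 m segment).
#' @param start_offset_s Time of the first heel strike (before any hesitation
#'   delay). Default 0.3.
#' @return An object of class `walk_config`.
#' @export
walk_config <- function(seed = 1L, n_steps = 120, mean_step_time = 0.55,
                        baseline_cv = 3,
                        burst = list(onset_step = 60, length_steps = 25,
                                     cv_multiplier = 5),
                        freeze = list(hazard_base = 0.001,
                                      hazard_cv_gain = 0.006,
                                      hazard_cv_ref = 6, hazard_max = 0.06,
                                      duration_s = 2.5),
                        hesitation = NULL,
                        cue_response = list(rho = 0.6, habituation_rate = 0.02),
                        amplitude = list(heel_peak = 400, toe_peak = 300),
                        noise_sd = 0, sample_rate = 100, step_length_m = 0.5,
                        segment_start_m = 27.5, segment_end_m = 37.5,
                        start_offset_s = 0.3) {
  gc_assert(n_steps >= 1 && n_steps == round(n_steps),
            "n_steps must be a positive integer", "config")
  gc_assert(mean_step_time > 0 && baseline_cv >= 0,
            "mean_step_time must be positive and baseline_cv non-negative",
            "config")
  if (!is.null(burst)) {
    gc_assert(all(c("onset_step", "length_steps", "cv_multiplier") %in%
                    names(burst)) && burst$cv_multiplier >= 1 &&
                burst$onset_step >= 1 && burst$length_steps >= 1,
              "burst needs onset_step, length_steps, cv_multiplier >= 1",
              "config")
  }
  if (!is.null(freeze)) {
    freeze <- utils::modifyList(list(hazard_base = 0.001,
                                     hazard_cv_gain = 0.006,
                                     hazard_cv_ref = 6, hazard_max = 0.06,
                                     duration_s = 2.5), freeze)
    gc_assert(freeze$hazard_base >= 0 && freeze$hazard_base <= 1 &&
                freeze$hazard_cv_gain >= 0 && freeze$hazard_max <= 1 &&
                freeze$duration_s > 0.5,
              "freeze hazard parameters out of range", "config")
  }
  if (!is.null(hesitation))
    gc_assert(is.numeric(hesitation$mean_delay_s) &&
                hesitation$mean_delay_s > 0,
              "hesitation needs a positive mean_delay_s", "config")
  cue_response <- utils::modifyList(list(rho = 0.6, habituation_rate = 0.02),
                                    cue_response)
  gc_assert(cue_response$rho > 0 && cue_response$rho <= 1 &&
              cue_response$habituation_rate >= 0,
            "need 0 < rho <= 1 and habituation_rate >= 0", "config")
  amplitude <- utils::modifyList(list(heel_peak = 400, toe_peak = 300),
                                 amplitude)
  gc_assert(amplitude$heel_peak > 50 && amplitude$heel_peak <= 1023 &&
              amplitude$toe_peak > 0 && amplitude$toe_peak <= 1023,
            "amplitudes must lie in (50, 1023] (heel) and (0, 1023] (toe)",
            "config")
  gc_assert(noise_sd >= 0 && sample_rate > 0 && step_length_m > 0 &&
              start_offset_s >= 0.1,
            "invalid noise, sampling or geometry parameter", "config")
  if (!is.null(segment_start_m)) {
    gc_assert(!is.null(segment_end_m) && segment_end_m > segment_start_m,
              "segment_end_m must exceed segment_start_m", "config")
    gc_assert(segment_end_m <= n_steps * step_length_m,
              "marked segment extends beyond the walk", "config")
  }
  structure(list(seed = as.integer(seed), n_steps = as.integer(n_steps),
                 mean_step_time = mean_step_time, baseline_cv = baseline_cv,
                 burst = burst, freeze = freeze, hesitation = hesitation,
                 cue_response = cue_response, amplitude = amplitude,
                 noise_sd = noise_sd, sample_rate = sample_rate,
                 step_length_m = step_length_m,
                 segment_start_m = segment_start_m,
                 segment_end_m = segment_end_m,
                 start_offset_s = start_offset_s),
            class = "walk_config")
}

# lognormal parameters for a given mean and CV (cv as a fraction); cv = 0
# degenerates to the constant mean
gc_lnorm_draw <- function(mean, cv, z) {
  if (cv <= 0) return(mean)
  sig2 <- log(1 + cv^2)
  exp(log(mean) - sig2 / 2 + sqrt(sig2) * z)
}

# Core sequential generator shared by the open-loop and closed-loop entry
# points. The controller is fed realized step times (including freeze gaps),
# exactly what the device would measure.
gc_sim_engine <- function(cfg, mode, strategy_cfg) {
  set.seed(cfg$seed)
  hesitation_s <- if (!is.null(cfg$hesitation))
    stats::rexp(1, 1 / cfg$hesitation$mean_delay_s) else 0
  t0 <- cfg$start_offset_s + hesitation_s
  n <- cfg$n_steps
  rho <- cfg$cue_response$rho
  hab <- cfg$cue_response$habituation_rate
  ctrl <- cue_controller(strategy_cfg, mode, walk_start_s = 0)
  hs_times <- numeric(n + 1)
  hs_times[1] <- t0
  realized <- numeric(n)
  drawn <- numeric(n)
  freeze_before <- numeric(n)
  fog_start <- numeric(0); fog_end <- numeric(0)
  rho_applied <- rep(1, n)
  t <- t0
  for (i in seq_len(n)) {
    visible <- cue_controller_visible(ctrl, t)
    rho_eff <- 1
    if (visible) {
      rho_eff <- if (mode == "continuous")
        1 - (1 - rho) * exp(-hab * t) else rho
    }
    rho_applied[i] <- rho_eff
    cv_t <- cfg$baseline_cv / 100
    if (!is.null(cfg$burst) && i >= cfg$burst$onset_step &&
        i < cfg$burst$onset_step + cfg$burst$length_steps)
      cv_t <- cv_t * cfg$burst$cv_multiplier
    z <- stats::rnorm(1)
    d <- gc_lnorm_draw(cfg$mean_step_time, cv_t * rho_eff, z)
    u <- stats::runif(1)
    fz <- 0
    if (!is.null(cfg$freeze) && i >= 3) {
      a <- realized[i - 2]; b <- realized[i - 1]
      cvp <- 100 * abs(a - b) / (sqrt(2) * (a + b) / 2)
      gate <- if (visible) rho_eff else 1
      p <- min(cfg$freeze$hazard_max,
               cfg$freeze$hazard_base + cfg$freeze$hazard_cv_gain *
                 max(0, cvp * gate - cfg$freeze$hazard_cv_ref))
      if (u < p) {
        fz <- 0.5 + stats::rexp(1, 1 / (cfg$freeze$duration_s - 0.5))
        fog_start <- c(fog_start, t)
        fog_end <- c(fog_end, t + fz)
      }
    }
    drawn[i] <- d
    freeze_before[i] <- fz
    realized[i] <- fz + d
    t <- t + realized[i]
    hs_times[i + 1] <- t
    ctrl <- cue_controller_update(ctrl, realized[i], t)
  }
  sides <- rep(c("left", "right"), length.out = n + 1)
  # toe-offs: stance is a fraction of the gap to the next ipsilateral strike
  gap_ipsi <- c(hs_times[-(1:2)], NA, NA) - hs_times
  gap_ipsi[is.na(gap_ipsi)] <- 2 * cfg$mean_step_time
  stance <- pmin(1.2, pmax(0.3, 0.62 * gap_ipsi))
  stance <- pmin(stance, pmax(0.2, gap_ipsi - 0.15))
  toe_times <- hs_times + stance
  t_end <- max(toe_times) + 0.5
  timeline <- cue_controller_finalize(ctrl, t_end)
  markers <- NULL
  if (!is.null(cfg$segment_start_m)) {
    k_s <- ceiling(cfg$segment_start_m / cfg$step_length_m)
    k_e <- ceiling(cfg$segment_end_m / cfg$step_length_m)
    markers <- data.frame(time_s = c(hs_times[k_s + 1], hs_times[k_e + 1]),
                          kind = gc_marker_kinds, stringsAsFactors = FALSE)
  }
  structure(list(seed = cfg$seed, mode = mode, config = cfg,
                 strategy_config = strategy_cfg,
                 step_times = realized, drawn_durations = drawn,
                 freeze_before = freeze_before,
                 heel_strikes = data.frame(time_s = hs_times, side = sides,
                                           stringsAsFactors = FALSE),
                 toe_offs = data.frame(time_s = toe_times, side = sides,
                                       stringsAsFactors = FALSE),
                 fog = fog_annotation(fog_start, fog_end, "simulator"),
                 hesitation_s = hesitation_s,
                 rho_applied = rho_applied,
                 cue_timeline = timeline, markers = markers, t_end = t_end),
            class = "walk_truth")
}

#' @export
print.walk_truth <- function(x, ...) {
  cat(sprintf(paste0("<walk_truth> seed=%d mode=%s: %d steps, %d freeze(s), ",
                     "%.1f s walk\n"),
              x$seed, x$mode, length(x$step_times),
              nrow(x$fog$intervals), x$t_end))
  invisible(x)
}

#' Simulate step times (open loop)
#'
#' Draws the walk without any cue influence: log-normal step times at the
#' configured mean and CV, burst inflation, hinge-hazard freezes coupled to
#' the recent pairwise %CV of the realized step times, and optional start
#' hesitation. Fully reproducible from `cfg$seed`.
#'
#' @param cfg A [walk_config()].
#' @return A `walk_truth` object: realized step times, per-side true
#'   heel-strike/toe-off times, freeze intervals, hesitation delay, marker
#'   times and the (empty) cue timeline.
#' @export
simulate_step_times <- function(cfg = walk_config()) {
  gc_assert(inherits(cfg, "walk_config"), "not a walk_config", "config")
  gc_sim_engine(cfg, "none", strategy_config())
}

# add a linear ramp v_a -> v_b over [t_a, t_b] into signal (uniform grid)
gc_add_ramp <- function(sig, sr, n, t_a, t_b, v_a, v_b) {
  i_a <- max(1L, as.integer(ceiling(t_a * sr - 1e-9)) + 1L)
  i_b <- min(n, as.integer(floor(t_b * sr + 1e-9)) + 1L)
  if (i_a > i_b) return(sig)
  tt <- (i_a:i_b - 1) / sr
  v <- v_a + (v_b - v_a) * (tt - t_a) / (t_b - t_a)
  idx <- i_a:i_b
  sig[idx] <- pmax(sig[idx], v)
  sig
}

#' Synthesize FSR waveforms from a ground-truth walk
#'
#' Piecewise-linear stance loading: each heel channel ramps up just before the
#' true heel-strike time, peaks exactly at it, and unloads to 0; the toe
#' channel loads after heel contact and first returns to 0 exactly at the true
#' toe-off time. Optional additive Gaussian noise is clipped to `[0, 1023]`
#' and all samples are rounded to integer ADC counts. Pathway markers are
#' placed at the configured crossing times.
#'
#' @param truth A `walk_truth` from [simulate_step_times()] or
#'   [closed_loop_session()].
#' @param cfg The [walk_config()] used (defaults to the one inside `truth`).
#' @return A [sensor_log()].
#' @export
synthesize_fsr <- function(truth, cfg = truth$config) {
  gc_assert(inherits(truth, "walk_truth"), "not a walk_truth", "config")
  sr <- cfg$sample_rate
  n <- as.integer(floor(truth$t_end * sr)) + 1L
  sig <- stats::setNames(rep(list(numeric(n)), 6), fsr_channels())
  heel_peak <- cfg$amplitude$heel_peak
  toe_peak <- cfg$amplitude$toe_peak
  hs <- truth$heel_strikes
  to <- truth$toe_offs
  nh <- nrow(hs)
  for (k in seq_len(nh)) {
    T <- hs$time_s[k]
    gap <- if (k + 2 <= nh) hs$time_s[k + 2] - T else 2 * cfg$mean_step_time
    fall <- max(0.1, min(0.3, 0.5 * gap - 0.1))
    p <- if (hs$side[k] == "left") "L" else "R"
    lat <- paste0(p, "_heel_lat"); med <- paste0(p, "_heel_med")
    sig[[lat]] <- gc_add_ramp(sig[[lat]], sr, n, T - 0.08, T, 0, heel_peak)
    sig[[lat]] <- gc_add_ramp(sig[[lat]], sr, n, T, T + fall, heel_peak, 0)
    sig[[med]] <- gc_add_ramp(sig[[med]], sr, n, T - 0.07, T,
                              0, 0.85 * heel_peak)
    sig[[med]] <- gc_add_ramp(sig[[med]], sr, n, T, T + 0.9 * fall,
                              0.85 * heel_peak, 0)
    # toe loads after heel contact and unloads exactly at the true toe-off
    t_off <- to$time_s[k]
    stance <- t_off - T
    toe_start <- T + max(0.04, 0.15 * stance)
    rise <- min(0.08, 0.3 * stance)
    tfall <- min(0.12, 0.4 * stance)
    toe <- paste0(p, "_toe")
    sig[[toe]] <- gc_add_ramp(sig[[toe]], sr, n, toe_start, toe_start + rise,
                              0, toe_peak)
    sig[[toe]] <- gc_add_ramp(sig[[toe]], sr, n, toe_start + rise,
                              t_off - tfall, toe_peak, toe_peak)
    sig[[toe]] <- gc_add_ramp(sig[[toe]], sr, n, t_off - tfall, t_off,
                              toe_peak, 0)
  }
  ch <- as.data.frame(lapply(sig, function(v) {
    if (cfg$noise_sd > 0) v <- v + stats::rnorm(n, 0, cfg$noise_sd)
    as.integer(round(pmin(1023, pmax(0, v))))
  }))
  markers <- NULL
  if (!is.null(truth$markers)) {
    markers <- truth$markers
    markers$time_s <- round(markers$time_s * sr) / sr  # snap to the grid
  }
  sensor_log(ch, sample_rate = sr, markers = markers)
}

#' Run a closed-loop cueing session
#'
#' Steps are generated sequentially; the cue controller (for `on_demand`) or
#' the mode itself (`continuous`) decides cue visibility from the steps
#' generated so far, and while a cue is visible the step-time SD is multiplied
#' by the effective rho. Under continuous exposure `1 - rho` decays at the
#' habituation rate; on-demand exposure keeps full cue salience. The freeze
#' hazard uses the cue-modulated recent pairwise %CV.
#'
#' @param cfg A [walk_config()].
#' @param mode `"none"`, `"continuous"` or `"on_demand"`.
#' @param strategy_cfg A [strategy_config()].
#' @param synthesize Also synthesize the FSR log? Default `TRUE`.
#' @return List with `truth` (`walk_truth`), `log` ([sensor_log()] or `NULL`)
#'   and `timeline` (the applied `cue_timeline`).
#' @export
closed_loop_session <- function(cfg = walk_config(),
                                mode = c("none", "continuous", "on_demand"),
                                strategy_cfg = strategy_config(),
                                synthesize = TRUE) {
  mode <- match.arg(mode)
  gc_assert(inherits(cfg, "walk_config"), "not a walk_config", "config")
  gc_assert(inherits(strategy_cfg, "strategy_config"), "not a strategy_config",
            "config")
  truth <- gc_sim_engine(cfg, mode, strategy_cfg)
  log <- if (synthesize) synthesize_fsr(truth, cfg) else NULL
  list(truth = truth, log = log, timeline = truth$cue_timeline)
}
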