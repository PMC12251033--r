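# Strategy generator: step-time variability ratio, upper/lower thresholds and
# the streaming cue controller for the three cueing modes, plus the cue-line
# placement geometry.
#
# The ratio statistic compares the newest %CV array entry against a reference.
# The default reference is the running median of all earlier entries: a
# consecutive-entry quotient of short-window %CV estimates is scale-free and
# heavy-tailed (its false-trigger probability per step is ~0.2 at any baseline
# variability), which makes a usable trigger impossible; referencing the
# walker's own running baseline keeps the ratio near 1 during steady gait and
# makes it rise persistently through a variability surge. The literal
# consecutive-entry quotient remains available as ratio_reference = "previous".

#' Strategy generator configuration
#'
#' Thresholds and controller behaviour for on-demand cueing. The upper
#' threshold (default 2.5) fires the cue on a surge in step-time variability
#' (the pre-FoG signature); the lower band (default `0.5 < ratio < 1`,
#' exclusive at both ends) marks hesitation-like drops and, when enabled, also
#' fires the cue.
#'
#' @param thresh_u Upper ratio threshold, inclusive (`ratio >= thresh_u`
#'   triggers). Default 2.5.
#' @param lower_band Numeric length-2 `(low, high)` with
#'   `0 < low < high <= 1 < thresh_u`. Default `c(0.5, 1)`.
#' @param lower_band_enabled Should a ratio strictly inside the lower band
#'   trigger the cue? Default `TRUE`.
#' @param min_cv_values Number of %CV array entries that must exist before the
#'   first decision (warm-up). Default 8.
#' @param cv_window Window length (in step times) of each controller %CV array
#'   entry. Default 7. The gait-metrics rolling %CV default of 2 is
#'   independent of this.
#' @param ratio_reference `"baseline_median"` (newest entry over the running
#'   median of all earlier entries, default) or `"previous"` (consecutive
#'   entry quotient).
#' @param steps_in_band Close an open cue after this many consecutive
#'   non-triggering decisions. Default 2.
#' @param fixed_duration_s If set, close an open cue this many seconds after
#'   its most recent trigger instead of counting decisions. Default `NULL`.
#' @param sd_denominator Passed to [percent_cv()] for the controller's %CV
#'   entries.
#' @return An object of class `strategy_config`.
#' @export
strategy_config <- function(thresh_u = 2.5, lower_band = c(0.5, 1),
                            lower_band_enabled = TRUE, min_cv_values = 8,
                            cv_window = 7,
                            ratio_reference = c("baseline_median", "previous"),
                            steps_in_band = 2, fixed_duration_s = NULL,
                            sd_denominator = c("n-1", "n")) {
  ratio_reference <- match.arg(ratio_reference)
  sd_denominator <- match.arg(sd_denominator)
  lower_band <- as.numeric(lower_band)
  gc_assert(length(lower_band) == 2 && 0 < lower_band[1] &&
              lower_band[1] < lower_band[2] && lower_band[2] <= 1 &&
              1 < thresh_u,
            "need 0 < lower_band[1] < lower_band[2] <= 1 < thresh_u", "config")
  gc_assert(min_cv_values >= 2 && min_cv_values == round(min_cv_values),
            "min_cv_values must be an integer >= 2", "config")
  gc_assert(cv_window >= 2 && cv_window == round(cv_window),
            "cv_window must be an integer >= 2", "config")
  gc_assert(steps_in_band >= 1 && steps_in_band == round(steps_in_band),
            "steps_in_band must be a positive integer", "config")
  if (!is.null(fixed_duration_s))
    gc_assert(fixed_duration_s > 0, "fixed_duration_s must be positive",
              "config")
  structure(list(thresh_u = thresh_u, lower_band = lower_band,
                 lower_band_enabled = isTRUE(lower_band_enabled),
                 min_cv_values = as.integer(min_cv_values),
                 cv_window = as.integer(cv_window),
                 ratio_reference = ratio_reference,
                 steps_in_band = as.integer(steps_in_band),
                 fixed_duration_s = fixed_duration_s,
                 sd_denominator = sd_denominator),
            class = "strategy_config")
}

#' Step-time variability ratio
#'
#' Quotient of the %CV array entry at `k` over a reference: the previous entry
#' (`reference = "previous"`) or the median of all entries before `k`
#' (`reference = "baseline_median"`). Conventions: both terms zero gives 1
#' (perfectly regular gait stays quiet); a zero reference with a positive
#' numerator gives `Inf`.
#'
#' @param cv Numeric %CV array (e.g. a [rolling_cv()] result).
#' @param k Index of the numerator entry, `2 <= k <= length(cv)` (1-based).
#' @param reference Reference convention, see above. Default `"previous"`.
#' @return Non-negative ratio, possibly `Inf`.
#' @examples
#' cv_ratio(c(4, 10), 2)  # 2.5
#' @export
cv_ratio <- function(cv, k, reference = c("previous", "baseline_median")) {
  reference <- match.arg(reference)
  cv <- as.numeric(cv)
  gc_assert(length(k) == 1 && k == round(k) && k >= 2 && k <= length(cv),
            "k must index an entry with at least one earlier entry", "index")
  num <- cv[k]
  ref <- if (reference == "previous") cv[k - 1] else
    stats::median(cv[seq_len(k - 1)])
  if (num == 0 && ref == 0) return(1)
  if (ref == 0) return(Inf)
  num / ref
}

#' Threshold decision on a variability ratio
#'
#' `trigger_upper` when `ratio >= thresh_u`; otherwise `trigger_lower` when
#' the lower band is enabled and `low < ratio < high` (strict); otherwise
#' `none`.
#'
#' @param ratio Non-negative ratio (possibly `Inf`).
#' @param cfg A [strategy_config()].
#' @param at_step_index Optional step index recorded on the decision.
#' @return An object of class `cue_decision`: list with `outcome`, `ratio`,
#'   `at_step_index`.
#' @export
decide_cue <- function(ratio, cfg = strategy_config(), at_step_index = NA_integer_) {
  gc_assert(is.numeric(ratio) && length(ratio) == 1 && !is.na(ratio) &&
              ratio >= 0, "ratio must be a non-negative number", "config")
  outcome <- if (ratio >= cfg$thresh_u) "trigger_upper"
  else if (cfg$lower_band_enabled && ratio > cfg$lower_band[1] &&
           ratio < cfg$lower_band[2]) "trigger_lower"
  else "none"
  structure(list(outcome = outcome, ratio = ratio,
                 at_step_index = as.integer(at_step_index)),
            class = "cue_decision")
}

#' Create a streaming cue-controller state
#'
#' The controller consumes step times one at a time ([cue_controller_update()])
#' and is closed with [cue_controller_finalize()]; [run_cue_controller()] is
#' the batch wrapper. Streaming and batch processing produce identical
#' timelines.
#'
#' @param cfg A [strategy_config()].
#' @param mode Cueing mode: `"none"`, `"continuous"` or `"on_demand"`.
#' @param walk_start_s Start of the walk span in seconds.
#' @return An opaque state object of class `cue_controller`.
#' @export
cue_controller <- function(cfg = strategy_config(),
                           mode = c("none", "continuous", "on_demand"),
                           walk_start_s = 0) {
  mode <- match.arg(mode)
  structure(list(cfg = cfg, mode = mode, walk_start = walk_start_s,
                 durations = numeric(0), cv = numeric(0),
                 dec_index = integer(0), dec_time = numeric(0),
                 dec_ratio = numeric(0), dec_outcome = character(0),
                 open = FALSE, open_start = NA_real_, open_reason = NA_character_,
                 last_trigger = NA_real_, nontrig = 0L,
                 iv_start = numeric(0), iv_end = numeric(0),
                 iv_reason = character(0)),
            class = "cue_controller")
}

gc_ctrl_close <- function(state, at) {
  state$iv_start <- c(state$iv_start, state$open_start)
  state$iv_end <- c(state$iv_end, max(at, state$open_start))
  state$iv_reason <- c(state$iv_reason, state$open_reason)
  state$open <- FALSE
  state$open_start <- NA_real_
  state$open_reason <- NA_character_
  state$nontrig <- 0L
  state
}

#' Feed one step time to the streaming cue controller
#'
#' In `on_demand` mode: appends the duration, updates the %CV array (one new
#' entry per step once `cv_window` durations exist), and once `min_cv_values`
#' entries exist takes a threshold decision at this step's heel-strike time. A
#' trigger opens (or sustains) the cue at that heel-strike time; the cue closes
#' per the release rule of the configuration.
#'
#' @param state A `cue_controller`.
#' @param duration_s The new step time in seconds.
#' @param heel_strike_time_s Time of the heel strike completing this step.
#' @return The updated state.
#' @export
cue_controller_update <- function(state, duration_s, heel_strike_time_s) {
  gc_assert(inherits(state, "cue_controller"), "not a cue_controller", "config")
  state$durations <- c(state$durations, duration_s)
  if (state$mode != "on_demand") return(state)
  cfg <- state$cfg
  n <- length(state$durations)
  if (n < cfg$cv_window) return(state)
  newest <- percent_cv(state$durations[(n - cfg$cv_window + 1):n],
                       cfg$sd_denominator)
  state$cv <- c(state$cv, newest)
  j <- length(state$cv)
  if (j < cfg$min_cv_values) return(state)

  # time-based release is checked against the decision clock before deciding
  if (state$open && !is.null(cfg$fixed_duration_s) &&
      heel_strike_time_s >= state$last_trigger + cfg$fixed_duration_s) {
    state <- gc_ctrl_close(state, state$last_trigger + cfg$fixed_duration_s)
  }

  ref <- if (cfg$ratio_reference == "previous") "previous" else "baseline_median"
  ratio <- cv_ratio(state$cv, j, ref)
  dec <- decide_cue(ratio, cfg, at_step_index = n)
  state$dec_index <- c(state$dec_index, n)
  state$dec_time <- c(state$dec_time, heel_strike_time_s)
  state$dec_ratio <- c(state$dec_ratio, ratio)
  state$dec_outcome <- c(state$dec_outcome, dec$outcome)

  if (dec$outcome != "none") {
    if (!state$open) {
      state$open <- TRUE
      state$open_start <- heel_strike_time_s
      state$open_reason <- dec$outcome
    }
    state$last_trigger <- heel_strike_time_s
    state$nontrig <- 0L
  } else if (state$open && is.null(cfg$fixed_duration_s)) {
    state$nontrig <- state$nontrig + 1L
    if (state$nontrig >= cfg$steps_in_band) {
      state <- gc_ctrl_close(state, heel_strike_time_s)
    }
  }
  state
}

#' Is the cue currently visible?
#'
#' @param state A `cue_controller`.
#' @param time_s Query time (only used to expire a fixed-duration cue).
#' @return Logical.
#' @export
cue_controller_visible <- function(state, time_s) {
  if (state$mode == "continuous") return(TRUE)
  if (state$mode == "none") return(FALSE)
  if (!state$open) return(FALSE)
  if (!is.null(state$cfg$fixed_duration_s))
    return(time_s < state$last_trigger + state$cfg$fixed_duration_s)
  TRUE
}

#' Close the streaming controller and build the cue timeline
#'
#' @param state A `cue_controller`.
#' @param walk_end_s End of the walk span in seconds.
#' @return A `cue_timeline`. Attribute `decisions` carries the decision log
#'   (data frame: `step_index`, `time_s`, `ratio`, `outcome`).
#' @export
cue_controller_finalize <- function(state, walk_end_s) {
  gc_assert(inherits(state, "cue_controller"), "not a cue_controller", "config")
  if (state$mode == "none") {
    tl <- cue_timeline("none")
  } else if (state$mode == "continuous") {
    tl <- cue_timeline("continuous", state$walk_start, walk_end_s, "continuous")
  } else {
    if (state$open) {
      at <- if (!is.null(state$cfg$fixed_duration_s))
        min(walk_end_s, state$last_trigger + state$cfg$fixed_duration_s)
      else walk_end_s
      state <- gc_ctrl_close(state, at)
    }
    s <- pmax(state$iv_start, state$walk_start)
    e <- pmin(state$iv_end, walk_end_s)
    keep <- e > s
    s <- s[keep]; e <- e[keep]; r <- state$iv_reason[keep]
    # merge adjacent/overlapping intervals, keeping the first reason
    if (length(s) > 1) {
      ms <- s[1]; me <- e[1]; mr <- r[1]; k <- 1L
      for (i in seq_along(s)[-1]) {
        if (s[i] <= me[k]) {
          me[k] <- max(me[k], e[i])
        } else {
          k <- k + 1L
          ms[k] <- s[i]; me[k] <- e[i]; mr[k] <- r[i]
        }
      }
      s <- ms; e <- me; r <- mr
    }
    tl <- cue_timeline("on_demand", s, e, r)
  }
  attr(tl, "decisions") <- data.frame(step_index = state$dec_index,
                                      time_s = state$dec_time,
                                      ratio = state$dec_ratio,
                                      outcome = state$dec_outcome,
                                      stringsAsFactors = FALSE)
  tl
}

#' Run the cue controller over a full step-time series
#'
#' Batch equivalent of the streaming interface: `none` gives an empty
#' timeline, `continuous` one interval spanning the walk, and `on_demand` the
#' streaming threshold evaluation over the %CV array.
#'
#' @param steps A `step_time_series` (or numeric durations, in which case
#'   heel-strike times are taken as the cumulative sum from `walk_span[1]`).
#' @param mode `"none"`, `"continuous"` or `"on_demand"`.
#' @param cfg A [strategy_config()].
#' @param walk_span Length-2 numeric `(start, end)` of the walk in seconds.
#' @return A `cue_timeline` with attribute `decisions`.
#' @export
run_cue_controller <- function(steps, mode = c("none", "continuous", "on_demand"),
                               cfg = strategy_config(), walk_span) {
  mode <- match.arg(mode)
  gc_assert(length(walk_span) == 2 && walk_span[2] > walk_span[1],
            "walk_span must be (start, end) with end > start", "interval")
  if (inherits(steps, "step_time_series")) {
    d <- steps$steps$duration_s
    hs <- steps$steps$to_time_s
  } else {
    d <- as.numeric(steps)
    hs <- walk_span[1] + cumsum(d)
  }
  state <- cue_controller(cfg, mode, walk_span[1])
  for (i in seq_along(d)) state <- cue_controller_update(state, d[i], hs[i])
  cue_controller_finalize(state, walk_span[2])
}

#' Placement geometry of the projected cue line
#'
#' The laser line (length 1.5 m) is projected on the floor at a distance of
#' 40% of the walker's height in front of them.
#'
#' @param height_m Walker height in meters, positive.
#' @return List with `distance_m` (`0.4 * height_m`) and `line_length_m`
#'   (1.5).
#' @examples
#' cue_line_placement(1.75)  # distance 0.70 m
#' @export
cue_line_placement <- function(height_m) {
  gc_assert(is.numeric(height_m) && length(height_m) == 1 &&
              is.finite(height_m) && height_m > 0,
            "height_m must be positive", "config")
  list(distance_m = 0.4 * height_m, line_length_m = 1.5)
}
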