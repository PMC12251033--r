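test_that("cv_ratio follows the quotient and zero conventions", {
  expect_equal(cv_ratio(c(4, 10), 2), 2.5)
  expect_identical(cv_ratio(c(0, 3), 2), Inf)
  expect_identical(cv_ratio(c(0, 0), 2), 1)
  expect_equal(cv_ratio(c(2, 4, 6), 3, reference = "baseline_median"), 2)
  expect_error(cv_ratio(c(4, 10), 1), class = "gaitcue_error_index")
  expect_error(cv_ratio(c(4, 10), 3), class = "gaitcue_error_index")
})

test_that("cue decisions respect threshold boundary conventions", {
  cfg <- strategy_config()
  expect_identical(decide_cue(2.6, cfg)$outcome, "trigger_upper")
  expect_identical(decide_cue(2.5, cfg)$outcome, "trigger_upper")  # inclusive
  expect_identical(decide_cue(Inf, cfg)$outcome, "trigger_upper")
  expect_identical(decide_cue(0.7, cfg)$outcome, "trigger_lower")
  expect_identical(decide_cue(0.5, cfg)$outcome, "none")  # band exclusive
  expect_identical(decide_cue(1.0, cfg)$outcome, "none")
  expect_identical(decide_cue(1.5, cfg)$outcome, "none")
  off <- strategy_config(lower_band_enabled = FALSE)
  expect_identical(decide_cue(0.7, off)$outcome, "none")
})

test_that("strategy config validates its band ordering", {
  expect_error(strategy_config(thresh_u = 0.9), class = "gaitcue_error_config")
  expect_error(strategy_config(lower_band = c(0.8, 0.5)),
               class = "gaitcue_error_config")
})

test_that("controller modes none and continuous are trivial timelines", {
  d <- rep(0.55, 30)
  tl_none <- run_cue_controller(d, "none", walk_span = c(0, 30))
  expect_equal(nrow(tl_none$intervals), 0)
  tl_cont <- run_cue_controller(d, "continuous", walk_span = c(0, 30))
  expect_equal(tl_cont$intervals$start_s, 0)
  expect_equal(tl_cont$intervals$end_s, 30)
  expect_identical(tl_cont$intervals$reason, "continuous")
})

test_that("perfectly regular gait never cues on demand", {
  d <- rep(0.55, 60)
  tl <- run_cue_controller(d, "on_demand", walk_span = c(0, 40))
  expect_equal(nrow(tl$intervals), 0)
  dec <- attr(tl, "decisions")
  expect_true(all(dec$ratio == 1))  # both-zero convention
  expect_true(all(dec$outcome == "none"))
})

test_that("streaming and batch controller runs are identical", {
  for (seed in 1:6) {
    tr <- simulate_step_times(walk_config(seed = 300 + seed, n_steps = 80,
                                          segment_start_m = NULL,
                                          segment_end_m = NULL))
    d <- tr$step_times
    hs <- tr$heel_strikes$time_s[-1]
    span <- c(0, tr$t_end)
    batch <- run_cue_controller(
      structure(list(steps = data.frame(duration_s = d, to_time_s = hs),
                     flags = character(0)), class = "step_time_series"),
      "on_demand", walk_span = span)
    state <- cue_controller(strategy_config(), "on_demand", span[1])
    for (i in seq_along(d)) state <- cue_controller_update(state, d[i], hs[i])
    stream <- cue_controller_finalize(state, span[2])
    expect_equal(stream$intervals, batch$intervals, tolerance = 0)
    expect_identical(attr(stream, "decisions"), attr(batch, "decisions"))
  }
})

test_that("controller runs are deterministic and bounded by the walk span", {
  tr <- simulate_step_times(walk_config(seed = 77))
  d <- tr$step_times
  span <- c(0, tr$t_end)
  tl1 <- run_cue_controller(d, "on_demand", walk_span = span)
  tl2 <- run_cue_controller(d, "on_demand", walk_span = span)
  expect_identical(tl1$intervals, tl2$intervals)
  if (nrow(tl1$intervals)) {
    expect_true(all(tl1$intervals$start_s >= span[1]))
    expect_true(all(tl1$intervals$end_s <= span[2]))
  }
  on_time <- sum(tl1$intervals$end_s - tl1$intervals$start_s)
  cont <- run_cue_controller(d, "continuous", walk_span = span)
  expect_lte(on_time, sum(cont$intervals$end_s - cont$intervals$start_s))
})

test_that("the on-demand timeline equals a brute-force strategy replay", {
  cfg <- strategy_config()
  for (seed in 1:25) {
    tr <- simulate_step_times(walk_config(seed = 500 + seed))
    d <- tr$step_times
    hs <- tr$heel_strikes$time_s[-1]
    span <- c(0, tr$t_end)
    got <- run_cue_controller(
      structure(list(steps = data.frame(duration_s = d, to_time_s = hs),
                     flags = character(0)), class = "step_time_series"),
      "on_demand", cfg, walk_span = span)
    want <- oracle_replay_controller(d, hs, cfg, span)
    expect_equal(got$intervals, want, tolerance = 0)
  }
})

test_that("the replay equivalence also holds for the literal previous-entry ratio", {
  cfg <- strategy_config(ratio_reference = "previous", cv_window = 2,
                         min_cv_values = 2)
  for (seed in 1:10) {
    tr <- simulate_step_times(walk_config(seed = 900 + seed, n_steps = 60,
                                          segment_start_m = NULL,
                                          segment_end_m = NULL))
    d <- tr$step_times
    hs <- tr$heel_strikes$time_s[-1]
    span <- c(0, tr$t_end)
    got <- run_cue_controller(d, "on_demand", cfg, walk_span = span)
    # durations fed as numerics anchor heel strikes at the cumulative sum
    want <- oracle_replay_controller(d, span[1] + cumsum(d), cfg, span)
    expect_equal(got$intervals, want, tolerance = 0)
  }
})

test_that("a variability step-change opens the cue near its onset", {
  cfg <- strategy_config(lower_band_enabled = FALSE)
  hits <- 0
  for (seed in 1:40) {
    tr <- simulate_step_times(
      walk_config(seed = 1200 + seed, n_steps = 100, baseline_cv = 3,
                  burst = list(onset_step = 50, length_steps = 51,
                               cv_multiplier = 10),
                  freeze = NULL, segment_start_m = NULL,
                  segment_end_m = NULL))
    tl <- run_cue_controller(tr$step_times, "on_demand", cfg,
                             walk_span = c(0, tr$t_end))
    dec <- attr(tl, "decisions")
    up <- dec$step_index[dec$outcome == "trigger_upper"]
    if (length(up) && min(up[up >= 50]) <= 53) hits <- hits + 1
  }
  expect_gte(hits, 34)  # ~ the designed >= 95% at modest n
})

test_that("a fixed-duration release closes the cue after the set time", {
  cfg <- strategy_config(fixed_duration_s = 3, lower_band_enabled = FALSE)
  # regular gait with a single long outlier step mid-walk
  d <- c(rep(0.55, 40), 1.6, rep(0.55, 40))
  tl <- run_cue_controller(d, "on_demand", cfg, walk_span = c(0, sum(d) + 1))
  expect_equal(nrow(tl$intervals), 1)
  dec <- attr(tl, "decisions")
  last_trig <- max(dec$time_s[dec$outcome == "trigger_upper"])
  expect_equal(tl$intervals$end_s, last_trig + 3)
})

test_that("cue line placement follows the 40%-of-height rule", {
  expect_equal(cue_line_placement(1.75), list(distance_m = 0.70,
                                              line_length_m = 1.5))
  expect_equal(cue_line_placement(1.60)$distance_m, 0.64)
  expect_error(cue_line_placement(0), class = "gaitcue_error_config")
  expect_error(cue_line_placement(-1.6), class = "gaitcue_error_config")
})
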