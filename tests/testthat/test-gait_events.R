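test_that("heel channels merge element-wise and idempotently", {
  expect_equal(merge_heel_channels(c(0, 60, 0), c(0, 0, 0)), c(0, 60, 0))
  expect_equal(merge_heel_channels(c(10, 20), c(30, 5)), c(30, 20))
  x <- c(3, 100, 7)
  expect_equal(merge_heel_channels(x, x), x)
  expect_error(merge_heel_channels(1:3, 1:4), class = "gaitcue_error_length")
})

test_that("a single supra-threshold episode yields one event at its peak", {
  t <- seq(0, 0.7, by = 0.05)
  x <- c(0, 0, 0, 20, 60, 90, 100, 95, 70, 30, 0, 0, 0, 0, 0)
  ev <- detect_heel_strikes(x, t, "left")
  expect_equal(nrow(ev), 1)
  expect_equal(ev$time_s, 0.30)  # sample of the maximum (100)
  expect_identical(ev$label, "L+")
})

test_that("a sub-threshold episode produces no event", {
  t <- seq(0, 0.5, by = 0.05)
  x <- c(0, 10, 25, 40, 35, 20, 5, 0, 0, 0, 0)
  expect_equal(nrow(detect_heel_strikes(x, t, "left")), 0)
})

test_that("valley validity gates episode admission", {
  t <- seq(0, 1.0, by = 0.1)
  full_valley <- c(0, 90, 0, 0, 0, 70, 0, 0, 0, 0, 0)
  shallow <- c(0, 90, 10, 10, 10, 70, 0, 0, 0, 0, 0)
  ev1 <- detect_heel_strikes(full_valley, t, "left")
  ev2 <- detect_heel_strikes(shallow, t, "left")
  expect_equal(nrow(ev1), 2)
  expect_equal(nrow(ev2), 1)  # trough only reached 10: second peak invalid
  expect_equal(ev2$time_s, 0.1)
  # matches the per-sample state-machine oracle
  expect_equal(ev1$time_s, oracle_heel_strikes(full_valley, t))
  expect_equal(ev2$time_s, oracle_heel_strikes(shallow, t))
  # a valley after the rejected peak re-arms detection
  rearm <- c(0, 90, 10, 70, 0, 0, 80, 0, 0, 0, 0)
  expect_equal(detect_heel_strikes(rearm, t, "left")$time_s,
               oracle_heel_strikes(rearm, t))
})

test_that("detection agrees with the state-machine oracle on random traces", {
  set.seed(7)
  for (rep in 1:60) {
    n <- 80
    x <- numeric(n)
    pos <- 1
    while (pos < n - 6) {
      pos <- pos + sample(2:8, 1)
      len <- sample(2:5, 1)
      if (pos + len > n) break
      peak <- sample(c(20, 45, 60, 200, 900), 1)
      x[pos:(pos + len)] <- pmin(1023, peak + sample(-5:5, len + 1, TRUE))
      # sometimes leave a shallow (non-valley) floor after the episode
      if (stats::runif(1) < 0.3 && pos + len + 2 <= n)
        x[(pos + len + 1):(pos + len + 2)] <- sample(1:20, 2, TRUE)
      pos <- pos + len
    }
    x <- pmax(0, x)
    t <- (seq_len(n) - 1) / 100
    expect_equal(detect_heel_strikes(x, t, "left")$time_s,
                 oracle_heel_strikes(x, t))
  }
})

test_that("detection is translation-equivariant in time", {
  tr <- simulate_step_times(walk_config(seed = 12, n_steps = 40,
                                        segment_start_m = NULL,
                                        segment_end_m = NULL))
  log <- synthesize_fsr(tr)
  ev0 <- detect_gait_events(log)
  shifted <- log
  shifted$time_s <- log$time_s + 5.25
  ev1 <- detect_gait_events(shifted)
  expect_equal(ev1$time_s, ev0$time_s + 5.25)
  expect_identical(ev1$label, ev0$label)
})

test_that("amplitude scaling above threshold never changes event counts", {
  tr <- simulate_step_times(walk_config(seed = 13, n_steps = 40,
                                        segment_start_m = NULL,
                                        segment_end_m = NULL))
  log <- synthesize_fsr(tr)
  ev0 <- detect_gait_events(log)
  for (c_scale in c(1.5, 2, 2.5)) {
    scaled <- log
    scaled$channels[] <- lapply(log$channels, function(v)
      as.integer(ifelse(v >= 50, pmin(1023, round(v * c_scale)), v)))
    ev <- detect_gait_events(scaled)
    expect_equal(table(ev$label), table(ev0$label))
  }
})

test_that("bounded zero-mean noise below a quarter threshold keeps counts", {
  cfg <- walk_config(seed = 14, n_steps = 60, segment_start_m = NULL,
                     segment_end_m = NULL)
  tr <- simulate_step_times(cfg)
  log <- synthesize_fsr(tr, cfg)
  ev0 <- detect_gait_events(log)
  set.seed(99)
  noisy <- log
  noisy$channels[] <- lapply(log$channels, function(v)
    as.integer(pmin(1023, pmax(0, round(v + stats::runif(length(v), -12, 12))))))
  ev <- detect_gait_events(noisy, detector_config(valley_epsilon = 0))
  expect_equal(sum(ev$kind == "heel_strike"), sum(ev0$kind == "heel_strike"))
})

test_that("toe-off is the first return to the valley after loading", {
  t <- seq(0, 1.4, by = 0.05)
  heel <- numeric(length(t)); heel[3:6] <- c(80, 100, 60, 0)
  toe <- numeric(length(t))
  toe[9:24] <- 250  # loaded over [0.40 s, 1.15 s], after the heel strike
  # first sample back at the valley is t = 1.20 s
  hs <- detect_heel_strikes(heel, t, "left")
  to <- detect_toe_offs(toe, t, hs)
  expect_equal(nrow(to), 1)
  expect_equal(to$time_s, 1.20)
  expect_identical(to$label, "L-")
  expect_length(attr(to, "incomplete"), 0)
})

test_that("a toe channel that never unloads yields an incomplete flag", {
  t <- seq(0, 1.0, by = 0.05)
  heel <- numeric(length(t)); heel[3:5] <- c(80, 100, 60)
  toe <- numeric(length(t)); toe[t >= 0.3] <- 200
  hs <- detect_heel_strikes(heel, t, "left")
  to <- detect_toe_offs(toe, t, hs)
  expect_equal(nrow(to), 0)
  expect_equal(attr(to, "incomplete"), 1L)
})

test_that("event merge is stable with left-before-right tie-break", {
  l <- data.frame(time_s = 0.0, side = "left", kind = "heel_strike",
                  label = "L+")
  r <- data.frame(time_s = c(0.0, 0.55), side = "right", kind = "heel_strike",
                  label = "R+")
  seq1 <- build_event_sequence(l, r)
  expect_identical(seq1$label, c("L+", "R+", "R+"))
  seq2 <- build_event_sequence(l[0, ], r[2, ])
  expect_identical(seq2$label, "R+")
})

test_that("the onset anchor stamps events at first threshold crossing", {
  t <- seq(0, 0.7, by = 0.05)
  x <- c(0, 0, 0, 20, 60, 90, 100, 95, 70, 30, 0, 0, 0, 0, 0)
  ev <- detect_heel_strikes(x, t, "left",
                            detector_config(event_anchor = "onset"))
  expect_equal(ev$time_s, 0.20)  # first sample >= 50
})
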