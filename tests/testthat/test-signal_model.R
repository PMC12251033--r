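test_that("sensor log CSV round-trips exactly for random valid logs", {
  set.seed(41)
  for (rep in 1:15) {
    n <- sample(3:60, 1)
    sr <- sample(c(50, 100, 128, 250), 1)
    ch <- as.data.frame(stats::setNames(
      lapply(1:6, function(i) as.integer(sample(0:1023, n, replace = TRUE))),
      fsr_channels()))
    log <- sensor_log(ch, sample_rate = sr)
    if (n >= 4 && rep %% 2 == 0) {
      idx <- sort(sample(n, 2))
      log$markers <- data.frame(time_s = log$time_s[idx],
                                kind = c("segment_start", "segment_end"))
    }
    path <- withr::local_tempfile(fileext = ".csv")
    write_sensor_log(log, path)
    back <- read_sensor_log(path)
    expect_equal(back$sample_rate, log$sample_rate, tolerance = 0)
    expect_equal(back$time_s, log$time_s, tolerance = 0)
    expect_identical(back$channels, log$channels)
    expect_equal(back$markers$time_s, log$markers$time_s, tolerance = 0)
    expect_identical(back$markers$kind, log$markers$kind)
  }
})

test_that("a minimal three-sample file parses to the expected log", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# sample_rate_hz=100",
               "time_s,L_heel_lat,L_heel_med,L_toe,R_heel_lat,R_heel_med,R_toe,marker",
               "0,0,0,0,0,0,0,", "0.01,60,0,0,0,0,0,", "0.02,0,0,0,0,0,0,"),
             path)
  log <- read_sensor_log(path)
  expect_equal(log$channels$L_heel_lat, c(0L, 60L, 0L))
  expect_equal(log$time_s, c(0, 0.01, 0.02))
  expect_equal(nrow(log$markers), 0)
})

test_that("invalid sensor files raise distinct named errors", {
  mk <- function(lines) {
    p <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
    writeLines(lines, p)
    p
  }
  hdr <- "time_s,L_heel_lat,L_heel_med,L_toe,R_heel_lat,R_heel_med,R_toe,marker"
  expect_error(read_sensor_log(mk(c("# sample_rate_hz=100",
                                    "time,foo", "0,1"))),
               class = "gaitcue_error_malformed_header")
  expect_error(read_sensor_log(mk(c(hdr, "0,0,0,0,0,0,0,"))),
               class = "gaitcue_error_malformed_header")  # no rate line
  expect_error(read_sensor_log(mk(c("# sample_rate_hz=100", hdr,
                                    "0,1024,0,0,0,0,0,"))),
               class = "gaitcue_error_adc_range")
  expect_error(read_sensor_log(mk(c("# sample_rate_hz=100", hdr,
                                    "0.02,0,0,0,0,0,0,", "0.01,0,0,0,0,0,0,"))),
               class = "gaitcue_error_nonmonotonic_time")
  expect_error(read_sensor_log(mk(c("# sample_rate_hz=100", hdr,
                                    "0,0,0,0,0,0,0,", "0.5,0,0,0,0,0,0,"))),
               class = "gaitcue_error_nonuniform_time")
  expect_error(read_sensor_log(mk(c("# sample_rate_hz=100", hdr,
                                    "0,0,0,0,0,0,0,wobble"))),
               class = "gaitcue_error_unknown_marker")
  expect_error(read_sensor_log(mk(c("# sample_rate_hz=100", hdr,
                                    "0,0,0,0,0,0,0,segment_end",
                                    "0.01,0,0,0,0,0,0,segment_start"))),
               class = "gaitcue_error_marker")
})

test_that("marker rows are written in time order and re-read", {
  ch <- zero_channels(10)
  log <- sensor_log(ch, 100, markers = data.frame(
    time_s = c(0.02, 0.07), kind = c("segment_start", "segment_end")))
  path <- withr::local_tempfile(fileext = ".csv")
  write_sensor_log(log, path)
  rows <- grep("segment_", readLines(path), value = TRUE)
  expect_length(rows, 2)
  expect_match(rows[1], "segment_start")
  expect_match(rows[2], "segment_end")
})

test_that("empty-channel log writes a header-only file", {
  log <- sensor_log(zero_channels(0))
  path <- withr::local_tempfile(fileext = ".csv")
  write_sensor_log(log, path)
  expect_length(readLines(path), 2)  # rate comment + column header
  expect_equal(length(read_sensor_log(path)$time_s), 0)
})

test_that("annotation files round-trip and reject degenerate intervals", {
  ann <- fog_annotation(c(1.5, 6), c(3.25, 8.5), "clinician")
  path <- withr::local_tempfile(fileext = ".csv")
  write_annotations(ann, path)
  back <- read_annotations(path)
  expect_equal(back$intervals, ann$intervals, tolerance = 0)
  expect_identical(back$source, "clinician")

  expect_error(fog_annotation(2, 2), class = "gaitcue_error_interval")
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("start_s,end_s,source", "2,2,clinician"), bad)
  expect_error(read_annotations(bad), class = "gaitcue_error_interval")
})

test_that("event and cue-timeline files round-trip", {
  ev <- build_event_sequence(
    data.frame(time_s = c(0.3, 0.97), side = "left",
               kind = c("heel_strike", "toe_off"), label = c("L+", "L-")),
    data.frame(time_s = 0.84, side = "right", kind = "heel_strike",
               label = "R+"))
  p1 <- withr::local_tempfile(fileext = ".csv")
  write_events(ev, p1)
  expect_equal(as.data.frame(read_events(p1)), as.data.frame(ev),
               tolerance = 0)

  tl <- cue_timeline("on_demand", c(2, 10), c(5.5, 12),
                     c("trigger_upper", "trigger_lower"))
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_cue_timeline(tl, p2)
  back <- read_cue_timeline(p2)
  expect_identical(back$mode, "on_demand")
  expect_equal(back$intervals, tl$intervals, tolerance = 0)
})

test_that("cue timeline invariants are enforced", {
  expect_error(cue_timeline("none", 1, 2, "continuous"),
               class = "gaitcue_error_config")
  expect_error(cue_timeline("continuous", c(1, 5), c(2, 6),
                            c("continuous", "continuous")),
               class = "gaitcue_error_config")
  expect_error(cue_timeline("on_demand", c(1, 2), c(3, 4),
                            c("trigger_upper", "trigger_upper")),
               class = "gaitcue_error_interval")  # overlap
})

test_that("config files populate defaults and reject unknown sections", {
  p <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("detector:", "  valid_peak_min: 60", "strategy:",
               "  thresh_u: 3", "walk:", "  n_steps: 80",
               "  segment_start_m: null", "  segment_end_m: null"), p)
  cfg <- read_config(p)
  expect_equal(cfg$detector$valid_peak_min, 60)
  expect_equal(cfg$detector$valley_level, 0)
  expect_equal(cfg$strategy$thresh_u, 3)
  expect_equal(cfg$strategy$lower_band, c(0.5, 1))
  expect_equal(cfg$walk$n_steps, 80L)

  pj <- withr::local_tempfile(fileext = ".json")
  writeLines('{"detector": {"valley_epsilon": 5}}', pj)
  expect_equal(read_config(pj)$detector$valley_epsilon, 5)

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("oops: 1", bad)
  expect_error(read_config(bad), class = "gaitcue_error_config")
})
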