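# Data model and file I/O for insole sensor logs, gait events, cue timelines
# and freezing-of-gait annotations.

#' FSR channel names of a sensor log
#'
#' Per-foot force-sensitive-resistor channels in file-column order: two heel
#' sites (lateral and medial, guarding against foot inversion/eversion) and one
#' toe site per foot.
#'
#' @return Character vector of the six channel names.
#' @export
fsr_channels <- function() {
  c("L_heel_lat", "L_heel_med", "L_toe", "R_heel_lat", "R_heel_med", "R_toe")
}

gc_marker_kinds <- c("segment_start", "segment_end")

#' Construct a sensor log
#'
#' A sensor log holds uniformly sampled integer ADC counts (0--1023) for the
#' six FSR channels plus optional pathway-marker events delimiting the timed
#' 10 m segment. Time is in seconds with `t = t0` at the first sample.
#'
#' @param channels Data frame (or coercible list) with the six columns named as
#'   in [fsr_channels()], integer ADC counts in `[0, 1023]`.
#' @param sample_rate Sampling rate in Hz (positive). Default 100.
#' @param markers Optional data frame with columns `time_s` and `kind`
#'   (`"segment_start"` / `"segment_end"`), at most one of each.
#' @param t0 Time of the first sample in seconds. Default 0.
#' @return An object of class `sensor_log` with fields `sample_rate`,
#'   `time_s`, `channels` and `markers`.
#' @examples
#' log <- sensor_log(data.frame(L_heel_lat = c(0L, 60L, 0L), L_heel_med = 0L,
#'                              L_toe = 0L, R_heel_lat = 0L, R_heel_med = 0L,
#'                              R_toe = 0L))
#' @export
sensor_log <- function(channels, sample_rate = 100, markers = NULL, t0 = 0) {
  channels <- as.data.frame(channels)
  n <- nrow(channels)
  time_s <- t0 + seq_len(n) / sample_rate - 1 / sample_rate
  if (is.null(markers)) {
    markers <- data.frame(time_s = numeric(0), kind = character(0),
                          stringsAsFactors = FALSE)
  }
  log <- structure(list(sample_rate = sample_rate, time_s = time_s,
                        channels = channels, markers = markers),
                   class = "sensor_log")
  validate_sensor_log(log)
}

#' Validate a sensor log against its invariants
#'
#' Checks channel layout, ADC range, strict monotone uniform time base
#' (tolerance 1e-9 s) and marker consistency. Raises a classed error on any
#' violation; never coerces silently.
#'
#' @param log A `sensor_log`.
#' @return The validated log, invisibly usable in pipelines.
#' @export
validate_sensor_log <- function(log) {
  gc_assert(is.numeric(log$sample_rate) && length(log$sample_rate) == 1 &&
              is.finite(log$sample_rate) && log$sample_rate > 0,
            "sample_rate must be a positive number", "malformed_header")
  ch <- log$channels
  gc_assert(is.data.frame(ch) && identical(names(ch), fsr_channels()),
            sprintf("channels must be exactly: %s",
                    paste(fsr_channels(), collapse = ", ")),
            "malformed_header")
  for (nm in fsr_channels()) {
    v <- ch[[nm]]
    gc_assert(all(is.finite(v)), sprintf("channel %s has non-finite values", nm),
              "adc_range")
    if (any(v < 0 | v > 1023))
      gc_abort(sprintf("channel %s has ADC values outside [0, 1023]", nm),
               "adc_range")
    gc_assert(all(v == round(v)),
              sprintf("channel %s has non-integer ADC values", nm), "adc_range")
  }
  t <- log$time_s
  gc_assert(length(t) == nrow(ch), "timestamps and channels differ in length",
            "malformed_header")
  if (length(t) > 1) {
    dt <- diff(t)
    if (any(dt <= 0)) gc_abort("timestamps are not strictly increasing",
                               "nonmonotonic_time")
    if (any(abs(dt - 1 / log$sample_rate) > 1e-9))
      gc_abort("timestamps are not uniform at 1/sample_rate (tolerance 1e-9 s)",
               "nonuniform_time")
  }
  mk <- log$markers
  gc_assert(is.data.frame(mk) && all(c("time_s", "kind") %in% names(mk)),
            "markers must have columns time_s and kind", "malformed_header")
  if (nrow(mk)) {
    bad <- setdiff(unique(mk$kind), gc_marker_kinds)
    if (length(bad)) gc_abort(sprintf("unknown marker kind: %s",
                                      paste(bad, collapse = ", ")),
                              "unknown_marker")
    if (any(table(mk$kind) > 1))
      gc_abort("at most one segment_start and one segment_end marker allowed",
               "marker")
    if (all(gc_marker_kinds %in% mk$kind)) {
      ts <- mk$time_s[mk$kind == "segment_start"]
      te <- mk$time_s[mk$kind == "segment_end"]
      gc_assert(ts < te, "segment_start must precede segment_end", "marker")
    }
  }
  log
}

#' @export
print.sensor_log <- function(x, ...) {
  cat(sprintf("<sensor_log> %d samples @ %g Hz (%.2f s), %d marker(s)\n",
              length(x$time_s), x$sample_rate,
              if (length(x$time_s)) diff(range(x$time_s)) else 0,
              nrow(x$markers)))
  invisible(x)
}

gc_sensor_header <- "time_s,L_heel_lat,L_heel_med,L_toe,R_heel_lat,R_heel_med,R_toe,marker"

#' Read a sensor log CSV
#'
#' The dialect is: comment lines `# sample_rate_hz=<float>`, a fixed column
#' header, one row per sample, and a `marker` column that is empty or one of
#' `segment_start` / `segment_end`.
#'
#' @param path Path to the CSV file.
#' @return A validated [sensor_log()].
#' @export
read_sensor_log <- function(path) {
  gc_assert(file.exists(path), sprintf("file not found: %s", path), "io")
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  sr_line <- grep("^#\\s*sample_rate_hz=", hdr, value = TRUE)
  gc_assert(length(sr_line) == 1,
            "header must contain exactly one '# sample_rate_hz=<float>' line",
            "malformed_header")
  sample_rate <- suppressWarnings(
    as.numeric(sub("^#\\s*sample_rate_hz=", "", sr_line)))
  gc_assert(is.finite(sample_rate) && sample_rate > 0,
            "sample_rate_hz must be a positive number", "malformed_header")
  body <- lines[!grepl("^#", lines)]
  gc_assert(length(body) >= 1 && identical(body[[1]], gc_sensor_header),
            sprintf("column header must be '%s'", gc_sensor_header),
            "malformed_header")
  df <- utils::read.csv(text = body, stringsAsFactors = FALSE,
                        colClasses = c("numeric", rep("integer", 6),
                                       "character"))
  markers <- df[nzchar(df$marker), c("time_s", "marker")]
  names(markers) <- c("time_s", "kind")
  rownames(markers) <- NULL
  channels <- df[fsr_channels()]
  log <- structure(list(sample_rate = sample_rate, time_s = df$time_s,
                        channels = channels, markers = markers),
                   class = "sensor_log")
  validate_sensor_log(log)
}

#' Write a sensor log CSV
#'
#' Inverse of [read_sensor_log()]: numeric fields round-trip exactly.
#'
#' @param log A valid [sensor_log()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sensor_log <- function(log, path) {
  validate_sensor_log(log)
  marker_col <- character(length(log$time_s))
  if (nrow(log$markers)) {
    idx <- vapply(log$markers$time_s,
                  function(tm) which.min(abs(log$time_s - tm)), 0L)
    marker_col[idx] <- log$markers$kind
  }
  rows <- if (length(log$time_s)) {
    paste(formatC(log$time_s, digits = 17, format = "g"),
          log$channels$L_heel_lat, log$channels$L_heel_med, log$channels$L_toe,
          log$channels$R_heel_lat, log$channels$R_heel_med, log$channels$R_toe,
          marker_col, sep = ",")
  } else character(0)
  out <- c(sprintf("# sample_rate_hz=%s",
                   formatC(log$sample_rate, digits = 17, format = "g")),
           gc_sensor_header, rows)
  tryCatch(writeLines(out, path),
           error = function(e) gc_abort(conditionMessage(e), "io"))
  invisible(path)
}

#' Construct a freezing-of-gait annotation set
#'
#' Intervals in seconds during which the walker is frozen, labelled either by
#' a clinician (from video) or by the simulator's ground truth. Intervals may
#' overlap on input; all derived measures use their union.
#'
#' @param start_s,end_s Numeric vectors of interval bounds, `end_s > start_s`.
#' @param source `"clinician"` or `"simulator"`.
#' @return An object of class `fog_annotation`.
#' @export
fog_annotation <- function(start_s = numeric(0), end_s = numeric(0),
                           source = "simulator") {
  gc_assert(length(start_s) == length(end_s),
            "start_s and end_s differ in length", "length")
  source <- match.arg(source, c("clinician", "simulator"))
  gc_assert(all(is.finite(start_s)) && all(is.finite(end_s)),
            "interval bounds must be finite", "interval")
  if (any(end_s <= start_s))
    gc_abort("every annotation interval must have end > start", "interval")
  structure(list(intervals = data.frame(start_s = start_s, end_s = end_s),
                 source = source),
            class = "fog_annotation")
}

#' @export
print.fog_annotation <- function(x, ...) {
  cat(sprintf("<fog_annotation> %d interval(s), source=%s\n",
              nrow(x$intervals), x$source))
  invisible(x)
}

#' Read / write FoG annotation CSV files
#'
#' CSV columns: `start_s,end_s,source`.
#'
#' @param path File path.
#' @return `read_annotations` returns a [fog_annotation()];
#'   `write_annotations` returns `path` invisibly.
#' @export
read_annotations <- function(path) {
  gc_assert(file.exists(path), sprintf("file not found: %s", path), "io")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  gc_assert(all(c("start_s", "end_s", "source") %in% names(df)),
            "annotation CSV must have columns start_s,end_s,source",
            "malformed_header")
  src <- unique(df$source)
  gc_assert(length(src) <= 1, "mixed annotation sources in one file",
            "malformed_header")
  fog_annotation(df$start_s, df$end_s,
                 if (length(src)) src else "simulator")
}

#' @param ann A [fog_annotation()].
#' @rdname read_annotations
#' @export
write_annotations <- function(ann, path) {
  gc_assert(inherits(ann, "fog_annotation"), "not a fog_annotation", "config")
  df <- ann$intervals
  df$source <- rep(ann$source, nrow(df))
  df$start_s <- formatC(df$start_s, digits = 17, format = "g")
  df$end_s <- formatC(df$end_s, digits = 17, format = "g")
  tryCatch(utils::write.csv(df, path, row.names = FALSE, quote = FALSE),
           error = function(e) gc_abort(conditionMessage(e), "io"))
  invisible(path)
}

#' Read / write labelled gait-event CSV files
#'
#' CSV columns: `time_s,side,kind,label` as produced by
#' [build_event_sequence()].
#'
#' @param path File path.
#' @return `read_events` returns an `event_sequence` data frame;
#'   `write_events` returns `path` invisibly.
#' @export
read_events <- function(path) {
  gc_assert(file.exists(path), sprintf("file not found: %s", path), "io")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  gc_assert(identical(names(df), c("time_s", "side", "kind", "label")),
            "event CSV must have columns time_s,side,kind,label",
            "malformed_header")
  as_event_sequence(df)
}

#' @param events An `event_sequence`.
#' @rdname read_events
#' @export
write_events <- function(events, path) {
  df <- as.data.frame(events)
  df$time_s <- formatC(df$time_s, digits = 17, format = "g")
  tryCatch(utils::write.csv(df, path, row.names = FALSE, quote = FALSE),
           error = function(e) gc_abort(conditionMessage(e), "io"))
  invisible(path)
}

#' Read / write cue timeline CSV files
#'
#' CSV columns: `start_s,end_s,mode,reason`.
#'
#' @param path File path.
#' @return `read_cue_timeline` returns a `cue_timeline`;
#'   `write_cue_timeline` returns `path` invisibly.
#' @export
read_cue_timeline <- function(path) {
  gc_assert(file.exists(path), sprintf("file not found: %s", path), "io")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("numeric", "numeric", "character",
                                       "character"))
  gc_assert(identical(names(df), c("start_s", "end_s", "mode", "reason")),
            "cue timeline CSV must have columns start_s,end_s,mode,reason",
            "malformed_header")
  mode <- unique(df$mode)
  gc_assert(length(mode) <= 1, "mixed modes in one cue timeline file",
            "malformed_header")
  cue_timeline(if (length(mode)) mode else "none",
               df$start_s, df$end_s, df$reason)
}

#' @param timeline A `cue_timeline`.
#' @rdname read_cue_timeline
#' @export
write_cue_timeline <- function(timeline, path) {
  gc_assert(inherits(timeline, "cue_timeline"), "not a cue_timeline", "config")
  df <- data.frame(start_s = formatC(timeline$intervals$start_s, digits = 17,
                                     format = "g"),
                   end_s = formatC(timeline$intervals$end_s, digits = 17,
                                   format = "g"),
                   mode = rep(timeline$mode, nrow(timeline$intervals)),
                   reason = timeline$intervals$reason)
  tryCatch(utils::write.csv(df, path, row.names = FALSE, quote = FALSE),
           error = function(e) gc_abort(conditionMessage(e), "io"))
  invisible(path)
}

#' Construct a cue timeline
#'
#' On/off intervals of the projected visual cue with the reason each interval
#' was opened. Mode `none` has an empty timeline; mode `continuous` exactly one
#' interval spanning the walk; mode `on_demand` the controller's trigger
#' intervals, non-overlapping and time-ordered.
#'
#' @param mode `"none"`, `"continuous"` or `"on_demand"`.
#' @param start_s,end_s Interval bounds in seconds.
#' @param reason Per-interval reason: `"continuous"`, `"trigger_upper"` or
#'   `"trigger_lower"`.
#' @return An object of class `cue_timeline`.
#' @export
cue_timeline <- function(mode, start_s = numeric(0), end_s = numeric(0),
                         reason = character(0)) {
  mode <- match.arg(mode, c("none", "continuous", "on_demand"))
  gc_assert(length(start_s) == length(end_s) &&
              length(start_s) == length(reason),
            "start_s, end_s and reason differ in length", "length")
  gc_assert(all(end_s >= start_s), "cue intervals must have end >= start",
            "interval")
  if (mode == "none")
    gc_assert(length(start_s) == 0, "mode none implies an empty timeline",
              "config")
  if (mode == "continuous")
    gc_assert(length(start_s) == 1 && identical(reason, "continuous"),
              "mode continuous implies one interval with reason continuous",
              "config")
  gc_assert(all(reason %in% c("continuous", "trigger_upper", "trigger_lower")),
            "unknown cue reason", "config")
  if (length(start_s) > 1) {
    gc_assert(!is.unsorted(start_s, strictly = FALSE) &&
                all(start_s[-1] >= end_s[-length(end_s)]),
              "cue intervals must be time-ordered and non-overlapping",
              "interval")
  }
  structure(list(mode = mode,
                 intervals = data.frame(start_s = start_s, end_s = end_s,
                                        reason = reason,
                                        stringsAsFactors = FALSE)),
            class = "cue_timeline")
}

#' @export
print.cue_timeline <- function(x, ...) {
  cat(sprintf("<cue_timeline> mode=%s, %d interval(s), cue-on %.2f s\n",
              x$mode, nrow(x$intervals),
              sum(x$intervals$end_s - x$intervals$start_s)))
  invisible(x)
}

#' Read a configuration file (JSON or YAML)
#'
#' Keys override the package defaults for the detector, strategy and walk
#' configurations; unknown top-level sections are rejected.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file with optional
#'   top-level sections `detector`, `strategy`, `walk`.
#' @return Named list with elements `detector`, `strategy`, `walk`, each a
#'   fully populated config object.
#' @export
read_config <- function(path) {
  gc_assert(file.exists(path), sprintf("file not found: %s", path), "io")
  ext <- tolower(sub(".*\\.([A-Za-z]+)$", "\\1", path))
  raw <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else gc_abort("config must be .json, .yaml or .yml", "config")
  bad <- setdiff(names(raw), c("detector", "strategy", "walk"))
  gc_assert(length(bad) == 0,
            sprintf("unknown config section(s): %s", paste(bad, collapse = ", ")),
            "config")
  list(detector = do.call(detector_config, as.list(raw$detector)),
       strategy = do.call(strategy_config, as.list(raw$strategy)),
       walk = do.call(walk_config, as.list(raw$walk)))
}
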