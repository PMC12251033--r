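# Step time, %CV of step time, walking speed over the marked 10 m segment,
# and freezing-of-gait exposure measures.

#' Step times from a labelled event sequence
#'
#' Step time is the duration between consecutive heel strikes of contralateral
#' legs. Consecutive ipsilateral heel strikes (a missed contralateral event)
#' produce no step and are flagged; toe-off events are ignored.
#'
#' @param seq An `event_sequence` from [build_event_sequence()] or
#'   [detect_gait_events()].
#' @return An object of class `step_time_series`: list with `steps` (data
#'   frame `duration_s`, `from_time_s`, `to_time_s`, `from_label`, `to_label`)
#'   and `flags` (character vector of anomalies).
#' @export
step_times <- function(seq) {
  df <- as.data.frame(seq)
  hs <- df[df$kind == "heel_strike", , drop = FALSE]
  n <- nrow(hs)
  flags <- character(0)
  if (n < 2) {
    steps <- data.frame(duration_s = numeric(0), from_time_s = numeric(0),
                        to_time_s = numeric(0), from_label = character(0),
                        to_label = character(0), stringsAsFactors = FALSE)
    return(structure(list(steps = steps, flags = flags),
                     class = "step_time_series"))
  }
  contra <- hs$side[-1] != hs$side[-n]
  if (any(!contra))
    flags <- sprintf("skipped_ipsilateral_pair at t=%.6g s",
                     hs$time_s[-1][!contra])
  steps <- data.frame(duration_s = diff(hs$time_s)[contra],
                      from_time_s = hs$time_s[-n][contra],
                      to_time_s = hs$time_s[-1][contra],
                      from_label = hs$label[-n][contra],
                      to_label = hs$label[-1][contra],
                      stringsAsFactors = FALSE)
  gc_assert(all(steps$duration_s > 0),
            "non-positive step duration; event sequence not time-ordered",
            "nonmonotonic_time")
  structure(list(steps = steps, flags = flags), class = "step_time_series")
}

#' @export
print.step_time_series <- function(x, ...) {
  cat(sprintf("<step_time_series> %d step(s), mean %.3f s, %d flag(s)\n",
              nrow(x$steps),
              if (nrow(x$steps)) mean(x$steps$duration_s) else NA_real_,
              length(x$flags)))
  invisible(x)
}

gc_durations <- function(x) {
  if (inherits(x, "step_time_series")) x$steps$duration_s else as.numeric(x)
}

#' Coefficient of variation in percent
#'
#' `%CV = (standard deviation / mean) * 100`, by default with the sample
#' (n-1) standard deviation.
#'
#' @param values Numeric vector of positive values, `n >= 2`, `mean > 0`.
#' @param sd_denominator `"n-1"` (sample SD, default) or `"n"` (population
#'   SD).
#' @return The %CV, a non-negative scalar.
#' @examples
#' percent_cv(c(0.5, 0.6, 0.7))  # 16.667
#' @export
percent_cv <- function(values, sd_denominator = c("n-1", "n")) {
  sd_denominator <- match.arg(sd_denominator)
  values <- as.numeric(values)
  n <- length(values)
  gc_assert(n >= 2, "percent_cv needs at least two values", "degenerate")
  m <- mean(values)
  gc_assert(is.finite(m) && m > 0, "percent_cv needs a positive mean",
            "degenerate")
  s <- stats::sd(values)
  if (sd_denominator == "n") s <- s * sqrt((n - 1) / n)
  100 * s / m
}

#' Rolling %CV over consecutive step times
#'
#' The %CV array of the strategy generator: one %CV value per sliding window
#' of `window` consecutive step durations, in order. The device's literal
#' array uses pairwise windows (`window = 2`).
#'
#' @param steps A `step_time_series` or numeric vector of step durations.
#' @param window Window length, integer `>= 2`. Default 2.
#' @param sd_denominator Passed to [percent_cv()].
#' @return An object of class `cv_array`: numeric vector of length
#'   `max(0, n_steps - window + 1)` with attribute `window`.
#' @export
rolling_cv <- function(steps, window = 2, sd_denominator = c("n-1", "n")) {
  sd_denominator <- match.arg(sd_denominator)
  gc_assert(length(window) == 1 && window >= 2 && window == round(window),
            "window must be an integer >= 2", "config")
  d <- gc_durations(steps)
  n <- length(d)
  k <- max(0, n - window + 1)
  vals <- vapply(seq_len(k), function(i)
    percent_cv(d[i:(i + window - 1)], sd_denominator), 0)
  structure(vals, window = as.integer(window), class = "cv_array")
}

#' @export
print.cv_array <- function(x, ...) {
  cat(sprintf("<cv_array> window=%d, %d value(s)\n", attr(x, "window"),
              length(x)))
  if (length(x)) print(utils::head(as.numeric(x), 8))
  invisible(x)
}

#' Walking speed over the marked segment
#'
#' Distance of the marked pathway segment divided by the traversal time
#' between the `segment_start` and `segment_end` markers.
#'
#' @param x A [sensor_log()] or a marker data frame with columns `time_s` and
#'   `kind`.
#' @param segment_distance_m Length of the marked segment in meters.
#'   Default 10.
#' @return Speed in m/s.
#' @export
walking_speed <- function(x, segment_distance_m = 10) {
  mk <- if (inherits(x, "sensor_log")) x$markers else as.data.frame(x)
  ts <- mk$time_s[mk$kind == "segment_start"]
  te <- mk$time_s[mk$kind == "segment_end"]
  gc_assert(length(ts) == 1 && length(te) == 1,
            "both segment_start and segment_end markers are required",
            "missing_marker")
  gc_assert(te > ts, "segment_end must come after segment_start", "interval")
  segment_distance_m / (te - ts)
}

# Union of real-valued intervals: returns a matrix with columns start, end of
# the disjoint, sorted connected components. Touching intervals merge.
gc_interval_union <- function(start, end) {
  stopifnot(length(start) == length(end))
  if (!length(start)) return(cbind(start = numeric(0), end = numeric(0)))
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  us <- start[1]; ue <- end[1]
  k <- 1L
  for (i in seq_along(start)[-1]) {
    if (start[i] <= ue[k]) {
      ue[k] <- max(ue[k], end[i])
    } else {
      k <- k + 1L
      us[k] <- start[i]; ue[k] <- end[i]
    }
  }
  cbind(start = us, end = ue)
}

#' Percent of a walk spent frozen
#'
#' 100 times the measure of the union of the annotation intervals clipped to
#' `[walk_start, walk_end]`, divided by the walk duration. Overlapping
#' annotations are not double counted.
#'
#' @param ann A [fog_annotation()].
#' @param walk_start_s,walk_end_s Walk interval bounds in seconds,
#'   `walk_end_s > walk_start_s`.
#' @return Percentage in `[0, 100]`.
#' @export
percent_time_frozen <- function(ann, walk_start_s, walk_end_s) {
  gc_assert(inherits(ann, "fog_annotation"), "not a fog_annotation", "config")
  gc_assert(walk_end_s > walk_start_s, "degenerate walk interval", "interval")
  u <- gc_interval_union(ann$intervals$start_s, ann$intervals$end_s)
  s <- pmax(u[, 1], walk_start_s)
  e <- pmin(u[, 2], walk_end_s)
  100 * sum(pmax(0, e - s)) / (walk_end_s - walk_start_s)
}

#' Number of freezing episodes
#'
#' The number of maximal connected components of the union of the annotation
#' intervals: abutting or overlapping labels count as one episode.
#'
#' @param ann A [fog_annotation()].
#' @return Non-negative integer count.
#' @export
count_fog_episodes <- function(ann) {
  gc_assert(inherits(ann, "fog_annotation"), "not a fog_annotation", "config")
  nrow(gc_interval_union(ann$intervals$start_s, ann$intervals$end_s))
}
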