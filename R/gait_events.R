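# Heel-strike / toe-off detection from FSR channels.
#
# A heel contact episode is a maximal run of samples >= valid_peak_min
# (default 50 ADC counts); the event is stamped at the episode's maximum
# sample. A new episode is admitted only once the signal has returned to the
# valley level (default 0 counts) since the previous one: a trough that does
# not reach the valley does not separate contacts.

#' Detector configuration
#'
#' Validity thresholds for peak/valley gait-event extraction. A peak is valid
#' at `>= valid_peak_min` ADC counts and a valley at
#' `<= valley_level + valley_epsilon`; `valley_epsilon` exists for noisy
#' signals where the baseline never sits exactly at the valley level.
#'
#' @param valid_peak_min Minimum ADC magnitude of a valid peak. Default 50.
#' @param valley_level Valley level in ADC counts. Default 0.
#' @param valley_epsilon Tolerance above `valley_level` still counted as a
#'   valley. Default 0.
#' @param event_anchor Where the heel-strike timestamp is anchored: at the
#'   episode's `"peak"` sample (default) or at its `"onset"` (first
#'   supra-threshold sample).
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(valid_peak_min = 50, valley_level = 0,
                            valley_epsilon = 0,
                            event_anchor = c("peak", "onset")) {
  event_anchor <- match.arg(event_anchor)
  gc_assert(valley_level + valley_epsilon >= 0 &&
              valley_level + valley_epsilon < valid_peak_min &&
              valid_peak_min <= 1023,
            "need 0 <= valley_level + valley_epsilon < valid_peak_min <= 1023",
            "config")
  structure(list(valid_peak_min = valid_peak_min, valley_level = valley_level,
                 valley_epsilon = valley_epsilon, event_anchor = event_anchor),
            class = "detector_config")
}

#' Merge the two heel FSR channels of one foot
#'
#' Element-wise maximum of the lateral and medial heel channels, so that a
#' valid contact on either site counts as heel contact regardless of foot
#' inversion/eversion.
#'
#' @param lateral,medial Equal-length numeric ADC series.
#' @return Numeric series `pmax(lateral, medial)`.
#' @export
merge_heel_channels <- function(lateral, medial) {
  gc_assert(length(lateral) == length(medial),
            "lateral and medial heel series differ in length", "length")
  pmax(lateral, medial)
}

# Maximal supra-threshold runs with valley-validity gating. Returns a data
# frame of admitted episodes (start, end, peak sample indices). The record is
# assumed to start in a valley (armed) state.
gc_contact_episodes <- function(x, cfg) {
  n <- length(x)
  if (n == 0) return(data.frame(start = integer(0), end = integer(0),
                                peak = integer(0)))
  above <- x >= cfg$valid_peak_min
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  valley_thr <- cfg$valley_level + cfg$valley_epsilon
  keep <- logical(length(runs))
  armed <- TRUE
  prev_end <- 0L
  for (i in seq_along(runs)) {
    s <- starts[runs[i]]
    if (!armed && prev_end + 1L <= s - 1L &&
        min(x[(prev_end + 1L):(s - 1L)]) <= valley_thr) armed <- TRUE
    keep[i] <- armed
    if (armed) {
      armed <- FALSE
      prev_end <- ends[runs[i]]
    } else {
      # non-admitted run extends the refractory region
      prev_end <- ends[runs[i]]
    }
  }
  runs <- runs[keep]
  peak <- vapply(runs, function(k) {
    s <- starts[k]; e <- ends[k]
    s + which.max(x[s:e]) - 1L  # earliest index on ties
  }, 0L)
  data.frame(start = starts[runs], end = ends[runs], peak = peak)
}

#' Detect heel-strike events from a merged heel channel
#'
#' One heel strike per valid contact episode, stamped at the episode's maximum
#' sample (earliest sample on ties) or at episode onset when the detector is
#' configured with `event_anchor = "onset"`.
#'
#' @param heel Numeric ADC series of one foot's merged heel channel.
#' @param time_s Timestamps of the samples (same length as `heel`).
#' @param side `"left"` or `"right"`.
#' @param cfg A [detector_config()].
#' @return Data frame of events (`time_s`, `side`, `kind`, `label`), possibly
#'   empty.
#' @export
detect_heel_strikes <- function(heel, time_s, side = c("left", "right"),
                                cfg = detector_config()) {
  side <- match.arg(side)
  gc_assert(length(heel) == length(time_s),
            "heel series and timestamps differ in length", "length")
  ep <- gc_contact_episodes(heel, cfg)
  idx <- if (cfg$event_anchor == "peak") ep$peak else ep$start
  gc_event_df(time_s[idx], side, "heel_strike")
}

#' Detect toe-off events following heel strikes
#'
#' For each heel strike, the toe-off is the first sample at or after it where,
#' following a supra-valley loading of the toe channel, the toe channel returns
#' to the valley level. The search is bounded by the next ipsilateral heel
#' strike (or end of log); a heel strike whose toe-off is not observed within
#' that bound yields no toe-off and is flagged incomplete.
#'
#' @param toe Numeric ADC series of the same foot's toe channel.
#' @param time_s Timestamps of the samples.
#' @param heel_strikes Event data frame from [detect_heel_strikes()] for the
#'   same foot.
#' @param cfg A [detector_config()].
#' @return Data frame of toe-off events with attribute `incomplete`: indices
#'   (into `heel_strikes`) of heel strikes without an observed toe-off.
#' @export
detect_toe_offs <- function(toe, time_s, heel_strikes,
                            cfg = detector_config()) {
  gc_assert(length(toe) == length(time_s),
            "toe series and timestamps differ in length", "length")
  valley_thr <- cfg$valley_level + cfg$valley_epsilon
  nh <- nrow(heel_strikes)
  side <- if (nh) heel_strikes$side[[1]] else "left"
  off_t <- rep(NA_real_, nh)
  for (i in seq_len(nh)) {
    lo <- findInterval(heel_strikes$time_s[i] - 1e-12, time_s) + 1L
    hi <- if (i < nh) {
      findInterval(heel_strikes$time_s[i + 1] - 1e-12, time_s)
    } else length(time_s)
    if (lo > hi) next
    seg <- toe[lo:hi]
    load <- which(seg > valley_thr)
    if (!length(load)) next
    rel <- which(seg[load[1]:length(seg)] <= valley_thr)
    if (!length(rel)) next
    off_t[i] <- time_s[lo + load[1] + rel[1] - 2L]
  }
  ok <- !is.na(off_t)
  ev <- gc_event_df(off_t[ok], side, "toe_off")
  attr(ev, "incomplete") <- which(!ok)
  ev
}

gc_event_label <- function(kind, side) {
  sgn <- ifelse(kind == "heel_strike", "+", "-")
  paste0(ifelse(side == "left", "L", "R"), sgn)
}

gc_event_df <- function(time_s, side, kind) {
  data.frame(time_s = as.numeric(time_s),
             side = rep_len(side, length(time_s)),
             kind = rep_len(kind, length(time_s)),
             label = if (length(time_s)) gc_event_label(
               rep_len(kind, length(time_s)), rep_len(side, length(time_s)))
             else character(0),
             stringsAsFactors = FALSE)
}

as_event_sequence <- function(df) {
  gc_assert(all(df$kind %in% c("heel_strike", "toe_off")) &&
              all(df$side %in% c("left", "right")),
            "invalid event kind or side", "config")
  gc_assert(identical(df$label, gc_event_label(df$kind, df$side)),
            "event labels inconsistent with kind and side", "config")
  structure(df, class = c("event_sequence", "data.frame"))
}

#' Merge per-foot events into one labelled event sequence
#'
#' Stable time-ordered merge of the left- and right-foot event lists with
#' labels `L+`/`L-`/`R+`/`R-` (heel strike / toe-off per side). On exact time
#' ties, left precedes right.
#'
#' @param left_events,right_events Event data frames (time-ordered) as
#'   produced by the detectors.
#' @return An `event_sequence` (a data frame with columns `time_s`, `side`,
#'   `kind`, `label`).
#' @export
build_event_sequence <- function(left_events, right_events) {
  all <- rbind(as.data.frame(left_events), as.data.frame(right_events))
  ord <- order(all$time_s, match(all$side, c("left", "right")))
  out <- all[ord, , drop = FALSE]
  rownames(out) <- NULL
  as_event_sequence(out)
}

#' @export
print.event_sequence <- function(x, ...) {
  cat(sprintf("<event_sequence> %d event(s): %d heel strikes, %d toe-offs\n",
              nrow(x), sum(x$kind == "heel_strike"), sum(x$kind == "toe_off")))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6))
  invisible(x)
}

#' Detect all gait events in a sensor log
#'
#' Convenience wrapper: merges each foot's heel channels, detects heel strikes
#' and toe-offs per foot, and merges everything into one labelled sequence.
#'
#' @param log A [sensor_log()].
#' @param cfg A [detector_config()].
#' @return An `event_sequence`; attribute `incomplete` carries the per-side
#'   incomplete heel-strike indices.
#' @export
detect_gait_events <- function(log, cfg = detector_config()) {
  validate_sensor_log(log)
  t <- log$time_s
  ch <- log$channels
  res <- lapply(c(left = "L", right = "R"), function(p) {
    heel <- merge_heel_channels(ch[[paste0(p, "_heel_lat")]],
                                ch[[paste0(p, "_heel_med")]])
    side <- if (p == "L") "left" else "right"
    hs <- detect_heel_strikes(heel, t, side, cfg)
    to <- detect_toe_offs(ch[[paste0(p, "_toe")]], t, hs, cfg)
    list(events = rbind(hs, to)[order(c(hs$time_s, to$time_s)), , drop = FALSE],
         incomplete = attr(to, "incomplete"))
  })
  seq <- build_event_sequence(res$left$events, res$right$events)
  attr(seq, "incomplete") <- list(left = res$left$incomplete,
                                  right = res$right$incomplete)
  seq
}
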