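# Independent brute-force oracles, deliberately implemented with plain loops
# and from-scratch formulas so they share no code path with the package.

# %CV by direct evaluation of the definition (sample SD, n-1 denominator)
oracle_cv <- function(x) {
  n <- length(x)
  m <- 0
  for (v in x) m <- m + v
  m <- m / n
  ss <- 0
  for (v in x) ss <- ss + (v - m)^2
  100 * sqrt(ss / (n - 1)) / m
}

# Pearson r by direct summation
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  num <- 0; dx <- 0; dy <- 0
  for (i in seq_len(n)) {
    num <- num + (x[i] - mx) * (y[i] - my)
    dx <- dx + (x[i] - mx)^2
    dy <- dy + (y[i] - my)^2
  }
  num / (sqrt(dx) * sqrt(dy))
}

# measure of the union of intervals clipped to [a, b], by 1 ms discretization
oracle_union_measure <- function(start, end, a, b) {
  if (!length(start)) return(0)
  grid <- seq(a, b, by = 0.001)
  mids <- grid[-1] - 0.0005
  covered <- rep(FALSE, length(mids))
  for (i in seq_along(start))
    covered <- covered | (mids > start[i] & mids < end[i])
  sum(covered) * 0.001
}

# per-sample state-machine replay of heel contact-episode detection
oracle_heel_strikes <- function(x, t, peak_min = 50, valley_thr = 0) {
  events <- numeric(0)
  armed <- TRUE
  in_episode <- FALSE
  best <- -Inf; best_t <- NA
  for (i in seq_along(x)) {
    if (in_episode) {
      if (x[i] >= peak_min) {
        if (x[i] > best) { best <- x[i]; best_t <- t[i] }
      } else {
        if (armed) events <- c(events, best_t)
        in_episode <- FALSE
        armed <- FALSE
        if (x[i] <= valley_thr) armed <- TRUE
      }
    } else {
      if (x[i] <= valley_thr) armed <- TRUE
      if (x[i] >= peak_min) {
        in_episode <- TRUE
        best <- x[i]; best_t <- t[i]
      }
    }
  }
  if (in_episode && armed) events <- c(events, best_t)
  events
}

# brute-force replay of the strategy-generator flow: %CV array build ->
# ratio vs reference -> threshold decisions -> release rule
oracle_replay_controller <- function(d, hs, cfg, walk_span) {
  w <- cfg$cv_window
  cv <- numeric(0)
  open <- FALSE; open_start <- NA; open_reason <- NA
  nontrig <- 0
  iv <- list()
  for (i in seq_along(d)) {
    if (i < w) next
    win <- d[(i - w + 1):i]
    cv <- c(cv, if (all(win == win[1])) 0 else oracle_cv(win))
    j <- length(cv)
    if (j < cfg$min_cv_values) next
    ref <- if (cfg$ratio_reference == "previous") cv[j - 1] else {
      prior <- sort(cv[1:(j - 1)])
      np <- length(prior)
      if (np %% 2 == 1) prior[(np + 1) / 2]
      else (prior[np / 2] + prior[np / 2 + 1]) / 2
    }
    ratio <- if (cv[j] == 0 && ref == 0) 1 else if (ref == 0) Inf else
      cv[j] / ref
    outcome <- if (ratio >= cfg$thresh_u) "trigger_upper"
    else if (cfg$lower_band_enabled && ratio > cfg$lower_band[1] &&
             ratio < cfg$lower_band[2]) "trigger_lower"
    else "none"
    if (outcome != "none") {
      if (!open) { open <- TRUE; open_start <- hs[i]; open_reason <- outcome }
      nontrig <- 0
    } else if (open) {
      nontrig <- nontrig + 1
      if (nontrig >= cfg$steps_in_band) {
        iv[[length(iv) + 1]] <- list(s = open_start, e = hs[i], r = open_reason)
        open <- FALSE; nontrig <- 0
      }
    }
  }
  if (open) iv[[length(iv) + 1]] <- list(s = open_start, e = walk_span[2],
                                         r = open_reason)
  if (!length(iv)) return(data.frame(start_s = numeric(0), end_s = numeric(0),
                                     reason = character(0),
                                     stringsAsFactors = FALSE))
  s <- pmax(vapply(iv, `[[`, 0, "s"), walk_span[1])
  e <- pmin(vapply(iv, `[[`, 0, "e"), walk_span[2])
  r <- vapply(iv, `[[`, "", "r")
  keep <- e > s
  s <- s[keep]; e <- e[keep]; r <- r[keep]
  out <- data.frame(start_s = s[1], end_s = e[1], reason = r[1],
                    stringsAsFactors = FALSE)
  for (i in seq_along(s)[-1]) {
    k <- nrow(out)
    if (s[i] <= out$end_s[k]) {
      out$end_s[k] <- max(out$end_s[k], e[i])
    } else {
      out <- rbind(out, data.frame(start_s = s[i], end_s = e[i],
                                   reason = r[i], stringsAsFactors = FALSE))
    }
  }
  out
}

# small all-zero channel frame of n samples
zero_channels <- function(n) {
  as.data.frame(stats::setNames(rep(list(integer(n)), 6), fsr_channels()))
}

# sensor log with a given left-lateral-heel trace (other channels zero)
heel_log <- function(x, sample_rate = 100, toe = NULL) {
  ch <- zero_channels(length(x))
  ch$L_heel_lat <- as.integer(x)
  if (!is.null(toe)) ch$L_toe <- as.integer(toe)
  sensor_log(ch, sample_rate = sample_rate)
}
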