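# Session- and cohort-level analysis: per-mode metric summaries, FoG episode
# statistics, correlation of FoG counts with clinical scores, and report
# generation.

#' Analyze one walking session
#'
#' Runs detection, step-time extraction, the gait metrics and (for on-demand
#' mode) the cue controller over one sensor log, and assembles the session
#' outcome record.
#'
#' @param log A [sensor_log()].
#' @param annotations Optional [fog_annotation()]; `NA` metrics when absent.
#' @param mode Cueing mode of the session.
#' @param detector_cfg A [detector_config()].
#' @param strategy_cfg A [strategy_config()].
#' @param participant_id,group,task Session metadata (`group` is `"healthy"`
#'   or `"pd"`, `task` is `"single"` or `"dual"`).
#' @param segment_distance_m Length of the marked segment. Default 10.
#' @return An object of class `session_result`: one-row data frame with
#'   `participant_id`, `group`, `task`, `mode`, `mean_pairwise_cv`,
#'   `walking_speed_mps`, `n_fog_episodes`, `pct_time_frozen`,
#'   `cue_on_fraction`, `n_steps`.
#' @export
analyze_session <- function(log, annotations = NULL,
                            mode = c("none", "continuous", "on_demand"),
                            detector_cfg = detector_config(),
                            strategy_cfg = strategy_config(),
                            participant_id = "p1", group = c("pd", "healthy"),
                            task = c("single", "dual"),
                            segment_distance_m = 10) {
  mode <- match.arg(mode)
  group <- match.arg(group)
  task <- match.arg(task)
  validate_sensor_log(log)
  events <- detect_gait_events(log, detector_cfg)
  steps <- step_times(events)
  cv2 <- rolling_cv(steps, window = 2)
  span <- range(log$time_s)
  has_markers <- nrow(log$markers) == 2 &&
    all(gc_marker_kinds %in% log$markers$kind)
  speed <- if (has_markers) walking_speed(log, segment_distance_m) else NA_real_
  walk_iv <- if (has_markers) {
    c(log$markers$time_s[log$markers$kind == "segment_start"],
      log$markers$time_s[log$markers$kind == "segment_end"])
  } else span
  pct_frozen <- if (!is.null(annotations))
    percent_time_frozen(annotations, walk_iv[1], walk_iv[2]) else NA_real_
  n_fog <- if (!is.null(annotations)) count_fog_episodes(annotations)
  else NA_integer_
  timeline <- run_cue_controller(steps, mode, strategy_cfg, walk_span = span)
  u <- gc_interval_union(timeline$intervals$start_s, timeline$intervals$end_s)
  cue_on <- sum(pmax(0, pmin(u[, 2], span[2]) - pmax(u[, 1], span[1])))
  out <- data.frame(participant_id = participant_id, group = group,
                    task = task, mode = mode,
                    mean_pairwise_cv = if (length(cv2)) mean(cv2) else NA_real_,
                    walking_speed_mps = speed,
                    n_fog_episodes = n_fog,
                    pct_time_frozen = pct_frozen,
                    cue_on_fraction = 100 * cue_on / diff(span),
                    n_steps = nrow(steps$steps),
                    stringsAsFactors = FALSE)
  class(out) <- c("session_result", "data.frame")
  attr(out, "timeline") <- timeline
  out
}

gc_metric_cols <- c("mean_pairwise_cv", "walking_speed_mps", "n_fog_episodes",
                    "pct_time_frozen", "cue_on_fraction")

gc_bind_results <- function(results) {
  if (inherits(results, "data.frame")) return(as.data.frame(results))
  do.call(rbind, lapply(results, as.data.frame))
}

#' Summarize session results per stratum and mode
#'
#' Per `(group, task, mode)`: mean and SD of each outcome metric; plus the
#' pairwise percent change between mode stratum means, computed as
#' `100 * (a - b) / a` with the earlier-listed mode (none, then continuous,
#' then on_demand) as baseline `a`.
#'
#' @param results List of [analyze_session()] results, or an equivalent data
#'   frame.
#' @return List of class `mode_comparison` with `summary` (one row per
#'   stratum-mode with `<metric>_mean` / `<metric>_sd` columns and `n`) and
#'   `changes` (one row per stratum, mode pair and metric).
#' @export
compare_modes <- function(results) {
  df <- gc_bind_results(results)
  gc_assert(nrow(df) > 0, "no session results to aggregate", "degenerate")
  strata <- unique(df[c("group", "task", "mode")])
  strata <- strata[order(strata$group, strata$task,
                         match(strata$mode,
                               c("none", "continuous", "on_demand"))), ]
  summ <- do.call(rbind, lapply(seq_len(nrow(strata)), function(i) {
    sel <- df$group == strata$group[i] & df$task == strata$task[i] &
      df$mode == strata$mode[i]
    sub <- df[sel, , drop = FALSE]
    row <- strata[i, , drop = FALSE]
    row$n <- nrow(sub)
    for (m in gc_metric_cols) {
      row[[paste0(m, "_mean")]] <- mean(sub[[m]])
      row[[paste0(m, "_sd")]] <- if (nrow(sub) > 1) stats::sd(sub[[m]])
      else 0
    }
    row
  }))
  rownames(summ) <- NULL
  mode_order <- c("none", "continuous", "on_demand")
  ch <- list()
  for (g in unique(summ$group)) for (tk in unique(summ$task[summ$group == g])) {
    s <- summ[summ$group == g & summ$task == tk, , drop = FALSE]
    present <- intersect(mode_order, s$mode)
    if (length(present) < 2) next
    for (i in seq_len(length(present) - 1)) for (j in (i + 1):length(present)) {
      a <- s[s$mode == present[i], ]; b <- s[s$mode == present[j], ]
      for (m in gc_metric_cols) {
        am <- a[[paste0(m, "_mean")]]
        bm <- b[[paste0(m, "_mean")]]
        ch[[length(ch) + 1]] <- data.frame(
          group = g, task = tk, baseline_mode = present[i],
          comparison_mode = present[j], metric = m,
          percent_change = if (is.finite(am) && am != 0)
            100 * (am - bm) / am else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(summary = summ,
                 changes = if (length(ch)) do.call(rbind, ch) else
                   data.frame()),
            class = "mode_comparison")
}

#' @export
print.mode_comparison <- function(x, ...) {
  cat("<mode_comparison>\n")
  print.data.frame(x$summary, digits = 4)
  invisible(x)
}

#' Pearson correlation coefficient
#'
#' Standard product-moment correlation between two equal-length samples.
#'
#' @param x,y Numeric vectors of equal length `>= 3` with non-zero variance.
#' @return r in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  gc_assert(length(x) == length(y), "x and y differ in length", "length")
  gc_assert(length(x) >= 3, "need at least three pairs", "degenerate")
  gc_assert(stats::var(x) > 0 && stats::var(y) > 0,
            "degenerate variance in correlation input", "degenerate")
  r <- stats::cor(x, y)
  # perfectly affine inputs can land a few ulps inside the poles through the
  # sqrt in the denominator; snap those to exactly +/-1
  if (abs(r) > 1 - 1e-12) r <- sign(r)
  r
}

#' Correlate FoG episode counts with clinical scores
#'
#' Per `(mode, task)` stratum, the Pearson correlation between the number of
#' FoG episodes and each of disease-onset duration and UPDRS-III.
#'
#' @param results Session results (list or data frame) with
#'   `participant_id` and `n_fog_episodes`.
#' @param clinical Data frame with columns `participant_id`, `updrs_iii`,
#'   `hy`, `onset_years`, non-negative.
#' @return Data frame with one row per `(mode, task)`: `r_onset`, `r_updrs`,
#'   `n`.
#' @export
correlate_fog_with_clinical <- function(results, clinical) {
  df <- gc_bind_results(results)
  gc_assert(all(c("participant_id", "updrs_iii", "hy", "onset_years") %in%
                  names(clinical)),
            "clinical needs participant_id, updrs_iii, hy, onset_years",
            "config")
  gc_assert(all(clinical$updrs_iii >= 0) && all(clinical$hy >= 0) &&
              all(clinical$onset_years >= 0),
            "clinical scores must be non-negative", "config")
  unmatched <- setdiff(df$participant_id, clinical$participant_id)
  gc_assert(length(unmatched) == 0,
            sprintf("participants without clinical record: %s",
                    paste(unmatched, collapse = ", ")), "config")
  m <- merge(df, clinical, by = "participant_id")
  strata <- unique(m[c("mode", "task")])
  out <- do.call(rbind, lapply(seq_len(nrow(strata)), function(i) {
    sub <- m[m$mode == strata$mode[i] & m$task == strata$task[i], ]
    data.frame(mode = strata$mode[i], task = strata$task[i],
               r_onset = pearson_r(sub$n_fog_episodes, sub$onset_years),
               r_updrs = pearson_r(sub$n_fog_episodes, sub$updrs_iii),
               n = nrow(sub), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Simulate a closed-loop cohort
#'
#' Simulates `n_participants` freeze-prone walkers, each walking once per
#' cueing mode with the same seed (a matched-walk design). A per-participant
#' severity covariate scales the freeze hazard (base, gain and cap) and the
#' pre-FoG burst magnitude, and also generates the clinical record
#' (UPDRS-III, H&Y, disease-onset years), so FoG counts and clinical scores
#' are positively associated by construction. Each session is analyzed
#' through the full detection pipeline.
#'
#' @param n_participants Number of simulated walkers. Default 12.
#' @param modes Cueing modes each participant walks under.
#' @param cfg Base [walk_config()] (per-participant seed and hazard gain are
#'   derived from it).
#' @param strategy_cfg A [strategy_config()].
#' @param base_seed Master seed for severities and session seeds.
#' @param task Task label for the sessions.
#' @return List with `results` (list of `session_result`), `clinical` (data
#'   frame) and `truths` (list of `walk_truth` keyed `pid.mode`).
#' @export
simulate_cohort <- function(n_participants = 20,
                            modes = c("none", "continuous", "on_demand"),
                            cfg = walk_config(), strategy_cfg = strategy_config(),
                            base_seed = 1L, task = "single") {
  gc_assert(n_participants >= 1, "need at least one participant", "config")
  set.seed(base_seed)
  sev <- stats::runif(n_participants, 0.4, 2.2)
  updrs <- round(pmax(5, 12 + 18 * (sev - 0.4) + stats::rnorm(n_participants, 0, 2)))
  onset <- round(pmax(0.5, 2 + 4 * (sev - 0.4) + stats::rnorm(n_participants, 0, 1)), 1)
  hy <- pmin(4, pmax(1, round(1 + 1.5 * (sev - 0.4))))
  clinical <- data.frame(participant_id = sprintf("p%02d", seq_len(n_participants)),
                         updrs_iii = updrs, hy = hy, onset_years = onset,
                         stringsAsFactors = FALSE)
  results <- list()
  truths <- list()
  for (i in seq_len(n_participants)) {
    cfg_i <- cfg
    cfg_i$seed <- as.integer(base_seed + 7919L * i)
    if (!is.null(cfg_i$freeze)) {
      cfg_i$freeze$hazard_base <- cfg_i$freeze$hazard_base * sev[i]^2
      cfg_i$freeze$hazard_cv_gain <- cfg_i$freeze$hazard_cv_gain * sev[i]
      cfg_i$freeze$hazard_max <- min(1, cfg_i$freeze$hazard_max * sev[i])
    }
    if (!is.null(cfg_i$burst))
      cfg_i$burst$cv_multiplier <- cfg_i$burst$cv_multiplier * sev[i]
    for (mode in modes) {
      ses <- closed_loop_session(cfg_i, mode, strategy_cfg)
      res <- analyze_session(ses$log, annotations = ses$truth$fog, mode = mode,
                             strategy_cfg = strategy_cfg,
                             participant_id = clinical$participant_id[i],
                             group = "pd", task = task)
      key <- paste(clinical$participant_id[i], mode, sep = ".")
      results[[key]] <- res
      truths[[key]] <- ses$truth
    }
  }
  list(results = results, clinical = clinical, truths = truths)
}

#' Run a cohort analysis from a manifest
#'
#' The manifest (YAML or JSON) lists sessions
#' (`log`, `annotations` (optional), `mode`, `group`, `task`, `participant`)
#' and optionally a `clinical` CSV path
#' (`participant_id,updrs_iii,hy,onset_years`). Paths are resolved relative to
#' the manifest file. Produces the per-stratum summary, the mode percent
#' changes and (when clinical data are given) the FoG-clinical correlation
#' table.
#'
#' @param manifest_path Path to the manifest file.
#' @param out Optional path for the JSON report.
#' @return List of class `cohort_report` with `sessions`, `comparison` and
#'   `correlations` (or `NULL`).
#' @export
run_cohort <- function(manifest_path, out = NULL) {
  gc_assert(file.exists(manifest_path),
            sprintf("file not found: %s", manifest_path), "io")
  ext <- tolower(sub(".*\\.([A-Za-z]+)$", "\\1", manifest_path))
  man <- if (ext == "json") jsonlite::read_json(manifest_path,
                                                simplifyVector = FALSE)
  else yaml::read_yaml(manifest_path)
  base <- dirname(manifest_path)
  rel <- function(p) if (file.exists(p)) p else file.path(base, p)
  gc_assert(length(man$sessions) > 0, "manifest lists no sessions", "config")
  results <- lapply(man$sessions, function(s) {
    log <- read_sensor_log(rel(s$log))
    ann <- if (!is.null(s$annotations)) read_annotations(rel(s$annotations))
    analyze_session(log, ann, mode = s$mode,
                    participant_id = s$participant,
                    group = s$group, task = s$task)
  })
  comparison <- compare_modes(results)
  correlations <- NULL
  if (!is.null(man$clinical)) {
    clin <- utils::read.csv(rel(man$clinical), stringsAsFactors = FALSE)
    correlations <- correlate_fog_with_clinical(results, clin)
  }
  report <- structure(list(sessions = gc_bind_results(results),
                           comparison = comparison,
                           correlations = correlations),
                      class = "cohort_report")
  if (!is.null(out)) {
    jsonlite::write_json(list(sessions = report$sessions,
                              summary = comparison$summary,
                              changes = comparison$changes,
                              correlations = correlations),
                         out, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  }
  report
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %d session(s)\n", nrow(x$sessions)))
  print(x$comparison)
  invisible(x)
}
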