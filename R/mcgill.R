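# McGill oximetry scoring (MOS, 1-4) from a raw overnight SpO2 trace:
# artifact rejection -> desaturation-event detection against a running
# baseline -> greedy event clustering -> tiered score assignment.
#
# The numeric criteria (4% drop, <90/<85/<80 nadir tiers, 3 clusters of 5+
# events within a 10-minute window) follow the McGill oximetry scoring
# scheme; every threshold is an overridable field of mos_config() because
# sites differ in how strictly they apply them.

#' McGill oximetry scoring configuration
#'
#' All thresholds of the scoring pipeline, overridable per call.
#'
#' @param min_drop minimum SpO2 fall below the running baseline for a
#'   desaturation event, percent (default 4).
#' @param min_event_duration minimum event duration, seconds (default 10).
#' @param baseline_window length of the trailing window whose median defines
#'   the running baseline, seconds (default 120). A trailing (not centred)
#'   median is used so slow overnight drift does not mask events.
#' @param cluster_window an event joins the current cluster when its start is
#'   within this many seconds of the previous event's end (default 600).
#' @param min_events_per_cluster events needed for a cluster to qualify
#'   (default 5).
#' @param required_clusters qualifying clusters needed for an abnormal score
#'   (default 3).
#' @param depth_thresholds named numeric vector `c(mos2=, mos3=, mos4=)`: an
#'   event counts toward a tier when its nadir is strictly below the tier
#'   threshold (defaults 90/85/80; strict inequality, so a nadir of exactly
#'   90.0 does not count as "below 90").
#' @param required_deep_events events below the tier threshold needed for
#'   that tier (default 3).
#' @param artifact_floor SpO2 below this is treated as artifact unless
#'   sustained, percent (default 70).
#' @param max_jump largest physiologically plausible change between adjacent
#'   samples, percent (default 25); isolated spikes beyond it are removed.
#' @param min_study_duration traces shorter than this are still scored but
#'   flagged "short study" in the report, seconds (default 4 h).
#' @return list of class `mos_config`.
#' @export
mos_config <- function(min_drop = 4, min_event_duration = 10,
                       baseline_window = 120, cluster_window = 600,
                       min_events_per_cluster = 5, required_clusters = 3,
                       depth_thresholds = c(mos2 = 90, mos3 = 85, mos4 = 80),
                       required_deep_events = 3, artifact_floor = 70,
                       max_jump = 25, min_study_duration = 4 * 3600) {
  stopifnot(min_drop > 0, min_event_duration > 0, baseline_window > 0,
            cluster_window > 0, min_events_per_cluster >= 1,
            required_clusters >= 1, required_deep_events >= 1)
  dt <- depth_thresholds
  if (!all(c("mos2", "mos3", "mos4") %in% names(dt)) ||
      !(dt[["mos4"]] < dt[["mos3"]] && dt[["mos3"]] < dt[["mos2"]])) {
    stop("depth_thresholds must be named mos2/mos3/mos4 with mos4 < mos3 < mos2",
         call. = FALSE)
  }
  structure(list(min_drop = min_drop, min_event_duration = min_event_duration,
                 baseline_window = baseline_window, cluster_window = cluster_window,
                 min_events_per_cluster = min_events_per_cluster,
                 required_clusters = required_clusters,
                 depth_thresholds = dt,
                 required_deep_events = required_deep_events,
                 artifact_floor = artifact_floor, max_jump = max_jump,
                 min_study_duration = min_study_duration),
            class = "mos_config")
}

#' Construct an oximetry trace
#'
#' @param time strictly increasing sample times, seconds from study start.
#' @param spo2 SpO2 percent values in \[0, 100\], aligned to `time`.
#' @param sampling_interval nominal sampling interval, seconds; inferred from
#'   the median time step when omitted.
#' @return list of class `oximetry_trace` with fields `time`, `spo2`,
#'   `sampling_interval`.
#' @export
oximetry_trace <- function(time, spo2, sampling_interval = NULL) {
  time <- as.numeric(time); spo2 <- as.numeric(spo2)
  if (length(time) != length(spo2)) {
    stop("validation error: time and spo2 must have equal length", call. = FALSE)
  }
  if (length(time) >= 2 && any(diff(time) <= 0)) {
    stop("validation error: timestamps must be strictly increasing", call. = FALSE)
  }
  if (any(is.na(spo2)) || any(spo2 < 0 | spo2 > 100)) {
    stop("validation error: spo2 must be within 0-100 with no missing samples",
         call. = FALSE)
  }
  if (is.null(sampling_interval)) {
    sampling_interval <- if (length(time) >= 2) median(diff(time)) else 1
  }
  structure(list(time = time, spo2 = spo2, sampling_interval = sampling_interval),
            class = "oximetry_trace")
}

#' Read an oximetry trace from CSV
#'
#' Expects two columns (seconds, SpO2 percent) with a header row.
#'
#' @param path CSV file path.
#' @return an [oximetry_trace()].
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path)
  if (ncol(raw) < 2) stop("trace CSV must have two columns (seconds, spo2)",
                          call. = FALSE)
  oximetry_trace(raw[[1]], raw[[2]])
}

#' Write an oximetry trace to CSV
#' @param trace an `oximetry_trace`.
#' @param path destination path.
#' @export
write_trace_csv <- function(trace, path) {
  write.csv(data.frame(seconds = trace$time, spo2 = trace$spo2), path,
            row.names = FALSE)
  invisible(path)
}

#' Remove motion artifacts from a trace
#'
#' Two single-pass rules: (i) an isolated sample below `artifact_floor` whose
#' neighbours are at or above the floor is dropped (sustained sub-floor
#' plateaus are physiology and kept); (ii) an isolated spike differing from
#' both neighbours by more than `max_jump` in the same direction is dropped.
#'
#' @param trace an `oximetry_trace`.
#' @param config an [mos_config()].
#' @return the cleaned `oximetry_trace`.
#' @export
reject_artifacts <- function(trace, config = mos_config()) {
  stopifnot(inherits(trace, "oximetry_trace"))
  n <- length(trace$spo2)
  if (n < 2) stop("validation error: trace must have at least 2 samples",
                  call. = FALSE)
  x <- trace$spo2
  prev <- c(x[1], x[-n]); nxt <- c(x[-1], x[n])
  floor_art <- x < config$artifact_floor & prev >= config$artifact_floor &
    nxt >= config$artifact_floor
  spike <- abs(x - prev) > config$max_jump & abs(x - nxt) > config$max_jump &
    (x - prev) * (x - nxt) > 0
  keep <- !(floor_art | spike)
  oximetry_trace(trace$time[keep], trace$spo2[keep], trace$sampling_interval)
}

# Running baseline: trailing median over baseline_window seconds. The first
# window is filled with the median of the first full window so the start of
# the night has a defined baseline.
running_baseline <- function(trace, config) {
  x <- trace$spo2
  k <- max(3L, round(config$baseline_window / trace$sampling_interval))
  if (k %% 2 == 0) k <- k + 1L
  n <- length(x)
  if (n <= k) return(rep(median(x), n))
  base <- as.numeric(zoo::rollmedian(zoo::zoo(x), k, align = "right", fill = NA))
  base[seq_len(k - 1)] <- median(x[seq_len(k)])
  base
}

#' Detect desaturation events
#'
#' Finds maximal episodes where SpO2 sits at least `min_drop` percent below
#' the running baseline for at least `min_event_duration` seconds. Events are
#' non-overlapping and time-ordered; each carries the baseline at onset, the
#' nadir, and the depth (baseline minus nadir).
#'
#' @param trace an artifact-rejected `oximetry_trace`.
#' @param config an [mos_config()].
#' @return data frame with columns `start_time`, `end_time`, `baseline`,
#'   `nadir`, `depth`; zero rows when the night is clean.
#' @export
detect_desaturations <- function(trace, config = mos_config()) {
  stopifnot(inherits(trace, "oximetry_trace"))
  n <- length(trace$spo2)
  empty <- data.frame(start_time = numeric(), end_time = numeric(),
                      baseline = numeric(), nadir = numeric(), depth = numeric())
  if (n < 2) return(empty)
  base <- running_baseline(trace, config)
  below <- (base - trace$spo2) >= config$min_drop
  if (!any(below)) return(empty)
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  out <- lapply(runs, function(j) {
    i0 <- starts[j]; i1 <- ends[j]
    # a single below-threshold sample spans one sampling interval
    dur <- trace$time[i1] - trace$time[i0] + trace$sampling_interval
    if (dur < config$min_event_duration) return(NULL)
    nadir <- min(trace$spo2[i0:i1])
    data.frame(start_time = trace$time[i0],
               end_time = trace$time[i1] + trace$sampling_interval,
               baseline = base[i0], nadir = nadir, depth = base[i0] - nadir)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty else out
}

#' Cluster desaturation events
#'
#' Greedy left-to-right partition: an event joins the current cluster when
#' its start is within `cluster_window` seconds of the previous event's end.
#' Clusters with fewer than `min_events_per_cluster` events are retained in
#' the output but flagged non-qualifying.
#'
#' @param events event data frame from [detect_desaturations()], time-ordered.
#' @param config an [mos_config()].
#' @return list of clusters; each element is a list with fields `events`
#'   (data frame), `n`, and `qualifying` (logical).
#' @export
cluster_desaturations <- function(events, config = mos_config()) {
  if (is.null(events) || nrow(events) == 0) return(list())
  if (is.unsorted(events$start_time)) {
    stop("validation error: events must be time-ordered", call. = FALSE)
  }
  id <- cumsum(c(1, as.integer(
    events$start_time[-1] - events$end_time[-nrow(events)] > config$cluster_window)))
  lapply(split(seq_len(nrow(events)), id), function(idx) {
    ev <- events[idx, , drop = FALSE]
    list(events = ev, n = nrow(ev),
         qualifying = nrow(ev) >= config$min_events_per_cluster)
  })
}

#' Assign a McGill oximetry score
#'
#' Tiered rule on the outputs of detection and clustering: with at least
#' `required_clusters` qualifying clusters, the score is 4 when at least
#' `required_deep_events` events have a nadir below the mos4 threshold
#' (default 80), else 3 with the mos3 threshold (85), else 2 with the mos2
#' threshold (90); otherwise (or without enough clusters) the score is 1
#' (normal or inconclusive). Strict inequality at every threshold.
#'
#' @param events event data frame.
#' @param clusters output of [cluster_desaturations()].
#' @param config an [mos_config()].
#' @return integer score 1-4 with attribute `rule` naming the rule that fired.
#' @export
assign_mos <- function(events, clusters, config = mos_config()) {
  n_qual <- if (length(clusters)) sum(vapply(clusters, `[[`, TRUE, "qualifying")) else 0L
  nadirs <- if (!is.null(events) && nrow(events)) events$nadir else numeric()
  dt <- config$depth_thresholds
  enough <- function(thr) sum(nadirs < thr) >= config$required_deep_events
  if (n_qual >= config$required_clusters) {
    if (enough(dt[["mos4"]])) return(structure(4L, rule = "clusters+nadir<mos4"))
    if (enough(dt[["mos3"]])) return(structure(3L, rule = "clusters+nadir<mos3"))
    if (enough(dt[["mos2"]])) return(structure(2L, rule = "clusters+nadir<mos2"))
  }
  structure(1L, rule = "no qualifying abnormality")
}

#' Score an oximetry trace
#'
#' Full pipeline: artifact rejection, desaturation detection, clustering,
#' score assignment. Deterministic: the same trace and configuration always
#' give the same score and report.
#'
#' @param trace an `oximetry_trace`.
#' @param config an [mos_config()].
#' @return list of class `mos_report`: `mos` (1-4), `rule`, `events`,
#'   `clusters`, `n_qualifying_clusters`, `duration` (seconds) and
#'   `short_study` flag.
#' @export
score_trace <- function(trace, config = mos_config()) {
  clean <- reject_artifacts(trace, config)
  events <- detect_desaturations(clean, config)
  clusters <- cluster_desaturations(events, config)
  mos <- assign_mos(events, clusters, config)
  duration <- diff(range(trace$time)) + trace$sampling_interval
  structure(list(mos = as.integer(mos), rule = attr(mos, "rule"),
                 events = events, clusters = clusters,
                 n_qualifying_clusters =
                   if (length(clusters)) sum(vapply(clusters, `[[`, TRUE, "qualifying")) else 0L,
                 duration = duration,
                 short_study = duration < config$min_study_duration),
            class = "mos_report")
}

#' @export
print.mos_report <- function(x, ...) {
  cat(sprintf("McGill oximetry score: %d  (%s)\n", x$mos, x$rule))
  cat(sprintf("  %d desaturation event(s), %d qualifying cluster(s)\n",
              nrow(x$events), x$n_qualifying_clusters))
  cat(sprintf("  study duration %.1f h%s\n", x$duration / 3600,
              if (x$short_study) "  [short study]" else ""))
  invisible(x)
}
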