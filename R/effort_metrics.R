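#' Motivation indices from press-rate series
#'
#' Two trial-level indices summarize effort allocation:
#' \describe{
#'   \item{invigoration}{how quickly effort is ramped up: the slope (%/s) of
#'     the transition from a rest segment to the initial plateau of the
#'     subsequent work segment, averaged over the trial's rest-to-work
#'     transitions (trial onset counts as rest).}
#'   \item{maintenance}{how durably effort is kept up: the arithmetic mean of
#'     the relative press frequency (% of the participant maximum) over the
#'     whole effort phase.}
#' }
#' Indices are computed on the raw press-rate series; segmentation into work
#' and rest uses an exponentially weighted moving average of the series when
#' a smoothing weight is supplied.
#'
#' @name effort_metrics
NULL

#' Exponentially weighted moving average (ball smoothing)
#'
#' The on-screen ball position is the press-rate series smoothed by
#' `s_t = lambda * x_t + (1 - lambda) * s_(t-1)` with `s_1 = x_1`, so that
#' when pressing stops the ball falls quickly yet slows down. Output is
#' bounded by the input range.
#'
#' @param x numeric series (values >= 0).
#' @param lambda smoothing weight in (0, 1\]; default 0.6.
#' @return smoothed series, same length as `x`.
#' @export
ball_ema <- function(x, lambda = 0.6) {
  if (length(x) == 0) return(numeric(0))
  if (any(x < 0)) stop_field("press-rate values must be >= 0")
  if (lambda <= 0 || lambda > 1) stop_field("lambda must be in (0, 1]")
  as.numeric(stats::filter(lambda * x, 1 - lambda, method = "recursive",
                           init = x[1]))
}

#' Segment a press-rate series into work and rest
#'
#' Work segments are maximal runs with (optionally smoothed) rate at or above
#' `work_threshold`; the complementary runs are rest. Runs shorter than
#' `min_bout` are merged into their neighbors (shortest first), so segments
#' are non-overlapping, ordered, and jointly cover the effort phase.
#'
#' @param series numeric press-rate series (% of maximum).
#' @param sample_rate sampling rate in Hz.
#' @param work_threshold work threshold in % of maximum (default 10);
#'   separates true rest from button-release jitter.
#' @param min_bout minimum bout duration in seconds (default 0.3).
#' @param lambda optional EMA weight applied before thresholding (default
#'   `NULL`: the series is thresholded as given).
#' @return data frame with columns `kind` ("work"/"rest"), `start`, `end`
#'   (seconds; sample k covers ((k-1)/rate, k/rate\]).
#' @export
segment_work_rest <- function(series, sample_rate, work_threshold = 10,
                              min_bout = 0.3, lambda = NULL) {
  r <- seg_runs(series, sample_rate, work_threshold, min_bout, lambda)
  ends <- cumsum(r$lengths) / sample_rate
  starts <- c(0, head(ends, -1))
  data.frame(kind = ifelse(r$values, "work", "rest"),
             start = starts, end = ends)
}

# run-length segmentation core: returns an rle object (values TRUE = work)
seg_runs <- function(series, sample_rate, work_threshold, min_bout,
                     lambda = NULL) {
  if (length(series) == 0) stop_field("series must be non-empty")
  s <- if (is.null(lambda)) series else ball_ema(series, lambda)
  r <- rle(s >= work_threshold)
  min_len <- max(1L, ceiling(min_bout * sample_rate))
  # merge sub-threshold-length runs into neighbors, shortest first
  while (length(r$lengths) > 1 && any(r$lengths < min_len)) {
    i <- which.min(r$lengths)
    if (r$lengths[i] >= min_len) break
    r$values[i] <- !r$values[i]
    r <- rle(inverse.rle(r))
  }
  r
}

# first sample index of the initial plateau of a work segment:
# the first local maximum (end of the strictly increasing ramp) whose height
# gained over the segment onset reaches `prominence`; falls back to the
# (first) segment maximum when no such peak exists.
find_plateau <- function(series, from, to, prominence = 5) {
  seg <- series[from:to]
  n <- length(seg)
  if (n >= 2) {
    for (j in seq_len(n - 1)) {
      if (seg[j + 1] <= seg[j] && seg[j] - seg[1] >= prominence) {
        return(from + j - 1L)
      }
    }
  }
  from + which.max(seg) - 1L
}

slope_fit <- function(y, x) {
  xc <- x - mean(x)
  sum(xc * y) / sum(xc * xc)
}

#' Invigoration slope of a trial
#'
#' For each rest-to-work transition (trial onset counts as rest), locates
#' the first local plateau of the work segment (first local maximum with
#' minimum prominence; segment maximum as fallback) and fits a straight
#' line on the raw series over the rising limb from the first sample of the
#' work segment toward the plateau. Samples at or near the plateau height
#' (at or above 90% of the rise) are excluded from the fit: their values
#' are capped at the plateau and would bias the slope toward zero. The
#' trial index is the mean slope over transitions, in %/s.
#'
#' @param series raw press-rate series (% of maximum).
#' @param segments segmentation from [segment_work_rest()].
#' @param sample_rate sampling rate in Hz.
#' @param prominence minimum rise (percentage points) above the segment
#'   onset for a local maximum to count as the plateau (default 5).
#' @return slope in %/s, or `NA` when the trial has no work segment or no
#'   fittable transition (flagged missing, excluded from models downstream).
#' @export
invigoration_slope <- function(series, segments, sample_rate,
                               prominence = 5) {
  work <- segments$kind == "work"
  if (!any(work)) return(NA_real_)
  froms <- round(segments$start[work] * sample_rate) + 1L
  tos <- round(segments$end[work] * sample_rate)
  slope_over_transitions(series, froms, tos, sample_rate, prominence)
}

slope_over_transitions <- function(series, froms, tos, sample_rate,
                                   prominence, rise_fraction = 0.9) {
  slopes <- numeric(0)
  for (i in seq_along(froms)) {
    from <- froms[i]
    j <- find_plateau(series, from, tos[i], prominence)
    # fit the rising limb only: samples at or near the plateau are
    # rate-capped and would bias the slope toward zero, so the fit stops
    # below `rise_fraction` of the rise from onset to the plateau value
    lim <- series[from] + rise_fraction * (series[j] - series[from])
    cross <- which(series[from:j] >= lim)
    end <- if (length(cross)) from + cross[1] - 2L else j - 1L
    if (end <= from) end <- if (j - 1L > from) j - 1L else j
    if (end > from) {
      t <- (from:end) / sample_rate
      slopes <- c(slopes, slope_fit(series[from:end], t))
    }
  }
  if (length(slopes) == 0) return(NA_real_)
  mean(slopes)
}

#' Effort maintenance of a trial
#'
#' Arithmetic mean of the relative press frequency over the full effort
#' phase, in % of the participant maximum.
#'
#' @param series raw press-rate series.
#' @return mean relative frequency (%).
#' @export
effort_maintenance <- function(series) {
  if (length(series) == 0) stop_field("series must be non-empty")
  mean(series)
}

#' Extract trial indices from one press-rate series
#'
#' @param series raw press-rate series (% of maximum).
#' @param config a [task_config()]; supplies sample rate, segmentation
#'   threshold, minimum bout and the EMA weight used for segmentation.
#' @return one-row data frame: `invigoration`, `maintenance`,
#'   `n_work_segments`, `mean_work_len`, `mean_rest_len`.
#' @export
extract_trial_indices <- function(series, config = task_config()) {
  v <- extract_fast(series, config)
  data.frame(invigoration = v[1], maintenance = v[2],
             n_work_segments = v[3], mean_work_len = v[4],
             mean_rest_len = v[5])
}

# allocation-light extraction used in simulation loops:
# c(invigoration, maintenance, n_work_segments, mean_work_len, mean_rest_len)
extract_fast <- function(series, config) {
  r <- seg_runs(series, config$sample_rate, config$work_threshold,
                config$min_bout, lambda = config$ema_lambda)
  ends <- cumsum(r$lengths)
  froms <- c(1L, head(ends, -1) + 1L)
  work <- r$values
  inv <- if (any(work)) {
    slope_over_transitions(series, froms[work], ends[work],
                           config$sample_rate, config$plateau_prominence)
  } else NA_real_
  c(inv, mean(series), sum(work),
    if (any(work)) mean(r$lengths[work]) / config$sample_rate else 0,
    if (any(!work)) mean(r$lengths[!work]) / config$sample_rate else 0)
}

#' Recompute trial indices for a whole dataset from stored press series
#'
#' @param dataset an [effort_dataset()] whose `press` table is populated.
#' @param config a [task_config()].
#' @return the dataset with `invigoration`, `maintenance` and bout summary
#'   columns replaced by freshly extracted values.
#' @export
extract_indices <- function(dataset, config = task_config()) {
  stopifnot(inherits(dataset, "effort_dataset"))
  if (is.null(dataset$press)) {
    stop_field("dataset stores no press series; re-simulate with keep_series = TRUE")
  }
  key <- interaction(dataset$press$participant, dataset$press$session,
                     dataset$press$trial_index, drop = TRUE)
  idx <- do.call(rbind, lapply(split(dataset$press, key), function(d) {
    d <- d[order(d$sample_index), ]
    cbind(data.frame(participant = d$participant[1], session = d$session[1],
                     trial_index = d$trial_index[1]),
          extract_trial_indices(d$value, config))
  }))
  trials <- dataset$trials
  m <- match(paste(trials$participant, trials$session, trials$trial_index),
             paste(idx$participant, idx$session, idx$trial_index))
  for (f in c("invigoration", "maintenance", "n_work_segments",
              "mean_work_len", "mean_rest_len")) {
    trials[[f]][!is.na(m)] <- idx[[f]][m[!is.na(m)]]
  }
  dataset$trials <- trials
  dataset
}
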