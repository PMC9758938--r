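#' Startle delta index
#'
#' For every sudden-darkness stimulus, the delta index is the mean
#' counts-per-second over the 30 s after the stimulus minus the mean over the
#' 30 s before it, the stimulus second itself being ignored (pre window
#' `[t - w, t)`, post window `(t, t + w]`, second-aligned). Positive deltas
#' mean darkness-induced locomotion.
#'
#' @param trace An [activity_trace()].
#' @param stim_times_s Stimulus seconds (0-based session time), e.g. from
#'   [stimulus_seconds()].
#' @param window_s Window half-width in seconds (default 30).
#' @return A `data.frame` with one row per usable stimulus: `fly_id`,
#'   `trial`, `stim_s`, `pre_mean`, `post_mean`, `delta`. Stimuli too close
#'   to the session edge are skipped with a warning.
#' @export
delta_index <- function(trace, stim_times_s, window_s = 30L) {
  if (!inherits(trace, "activity_trace")) stop("trace must be an activity_trace")
  w <- as.integer(window_s)
  if (w < 1L) stop("window_s must be >= 1")
  t <- as.integer(stim_times_s)
  d <- trace$duration
  ok <- t - w >= 0L & t + w <= d - 1L
  if (any(!ok)) {
    warning(sprintf("%s: skipping %d stimulus(es) too close to the session edge",
                    trace$fly_id, sum(!ok)), call. = FALSE)
  }
  S <- c(0, cumsum(as.numeric(trace$counts)))  # S[j+1] = sum of seconds 0..j-1
  tk <- t[ok]
  pre <- (S[tk + 1L] - S[tk - w + 1L]) / w
  post <- (S[tk + w + 2L] - S[tk + 2L]) / w
  data.frame(fly_id = rep(trace$fly_id, sum(ok)), trial = which(ok),
             stim_s = tk, pre_mean = pre, post_mean = post,
             delta = post - pre, stringsAsFactors = FALSE)
}

#' Delta records for a whole cohort
#'
#' @param traces List of [activity_trace()]s.
#' @inheritParams delta_index
#' @return Row-bound [delta_index()] records for all flies.
#' @export
delta_records <- function(traces, stim_times_s, window_s = 30L) {
  do.call(rbind, lapply(traces, delta_index, stim_times_s = stim_times_s,
                        window_s = window_s))
}

#' Dead-fly exclusion
#'
#' Flies showing no activity in any pre or post stimulus window across the
#' whole session are considered dead and excluded. Activity between windows
#' does not rescue a fly: the rule looks at the scored windows only.
#'
#' @inheritParams delta_records
#' @return A list with `kept` (traces) and `excluded` (character fly ids).
#' @export
exclude_dead <- function(traces, stim_times_s, window_s = 30L) {
  dead <- vapply(traces, function(tr) {
    rec <- suppressWarnings(delta_index(tr, stim_times_s, window_s))
    nrow(rec) > 0L && all(rec$pre_mean == 0) && all(rec$post_mean == 0)
  }, TRUE)
  list(kept = traces[!dead],
       excluded = vapply(traces[dead], `[[`, "", "fly_id"))
}

#' Responder classification
#'
#' Fractions of fly-by-trial cells responding with an increase (`delta > 0`),
#' a decrease (`delta < 0`) or no change (`delta == 0`, exact — counts are
#' integers, so window sums compare exactly).
#'
#' @param records Delta records from [delta_records()].
#' @return A list of class `response_breakdown` with `fraction_increase`,
#'   `fraction_decrease`, `fraction_no_change` and `n_cells`.
#' @export
classify_responses <- function(records) {
  if (!nrow(records)) stop("no delta records to classify")
  n <- nrow(records)
  out <- list(fraction_increase = sum(records$delta > 0) / n,
              fraction_decrease = sum(records$delta < 0) / n,
              fraction_no_change = sum(records$delta == 0) / n,
              n_cells = n)
  class(out) <- "response_breakdown"
  out
}

#' @export
print.response_breakdown <- function(x, ...) {
  cat(sprintf("<response_breakdown> n=%d: %.1f%% increase, %.1f%% decrease, %.1f%% no change\n",
              x$n_cells, 100 * x$fraction_increase, 100 * x$fraction_decrease,
              100 * x$fraction_no_change))
  invisible(x)
}

#' Epoch-averaged deltas
#'
#' Bins trials by stimulus time into half-open recording epochs
#' `[k*L, (k+1)*L)` (30 min by default, counted from the first stimulus) and
#' averages deltas per epoch — per fly or pooled. A 2-h stimulation at 5-min
#' ITI yields 4 epochs of 6 deltas per fly; at 1-min ITI, 4 epochs of 30.
#'
#' @param records Delta records from [delta_records()].
#' @param epoch_len_s Epoch length in seconds (default 1800).
#' @param origin_s Epoch origin; defaults to the earliest stimulus.
#' @param session_len_s Optional stimulation span (s, from `origin_s`) used
#'   to enumerate epochs; empty epochs are then reported with `NA` mean and
#'   flagged.
#' @param by_fly Return per-fly epoch means instead of pooled means.
#' @return A `data.frame` with `epoch` (0-based), `mean_delta`, `n` (and
#'   `fly_id` when `by_fly`), plus `empty` flags when `session_len_s` is
#'   given.
#' @export
epoch_average <- function(records, epoch_len_s = 1800L, origin_s = NULL,
                          session_len_s = NULL, by_fly = FALSE) {
  if (!nrow(records)) stop("no delta records")
  if (is.null(origin_s)) origin_s <- min(records$stim_s)
  epoch <- (records$stim_s - origin_s) %/% epoch_len_s
  if (any(epoch < 0)) stop("origin_s later than some stimuli")
  if (by_fly) {
    key <- interaction(records$fly_id, epoch, drop = TRUE)
    out <- data.frame(
      fly_id = tapply(records$fly_id, key, `[`, 1L),
      epoch = as.integer(tapply(epoch, key, `[`, 1L)),
      mean_delta = as.numeric(tapply(records$delta, key, mean)),
      n = as.integer(tapply(records$delta, key, length)),
      stringsAsFactors = FALSE, row.names = NULL)
    out <- out[order(out$epoch, out$fly_id), , drop = FALSE]
  } else {
    out <- data.frame(
      epoch = as.integer(names(tapply(records$delta, epoch, mean))),
      mean_delta = as.numeric(tapply(records$delta, epoch, mean)),
      n = as.integer(tapply(records$delta, epoch, length)),
      row.names = NULL)
    out <- out[order(out$epoch), , drop = FALSE]
  }
  if (!is.null(session_len_s)) {
    n_epochs <- as.integer(ceiling(session_len_s / epoch_len_s))
    all_ep <- 0:(n_epochs - 1L)
    missing_ep <- setdiff(all_ep, out$epoch)
    if (length(missing_ep)) {
      warning("empty epoch(s): ", paste(missing_ep, collapse = ", "),
              call. = FALSE)
      pad <- out[rep(NA_integer_, length(missing_ep)), , drop = FALSE]
      pad$epoch <- missing_ep
      pad$n <- 0L
      out <- rbind(out, pad)
      out <- out[order(out$epoch), , drop = FALSE]
    }
    out$empty <- out$n == 0L
  }
  rownames(out) <- NULL
  out
}

#' Habituation trend over epochs
#'
#' Convenience pipeline for the repeated-stimulation analysis: per-fly epoch
#' means ([epoch_average()]) feed a one-way ANOVA with a post hoc
#' linear-trend contrast across ordered epochs ([linear_trend()]).
#'
#' @inheritParams epoch_average
#' @return A `trend_result` (see [linear_trend()]).
#' @export
epoch_trend <- function(records, epoch_len_s = 1800L, origin_s = NULL) {
  em <- epoch_average(records, epoch_len_s = epoch_len_s, origin_s = origin_s,
                      by_fly = TRUE)
  groups <- split(em$mean_delta, em$epoch)
  linear_trend(groups, scores = as.numeric(names(groups)))
}

#' Baseline activity and speed
#'
#' Mean counts/s and mean speed over the window preceding the first stimulus
#' (20 min by default). Speed is the mean absolute per-second beam
#' displacement (beam cells per second), the only speed computable from the
#' stored trace.
#'
#' @param trace An [activity_trace()].
#' @param t_end First-stimulus second; the window is `[t_end - window_s,
#'   t_end)`.
#' @param window_s Window length in seconds (default 1200).
#' @return A list with `mean_counts`, `mean_speed` and `n_seconds`.
#' @export
baseline_metrics <- function(trace, t_end, window_s = 1200L) {
  t_end <- as.integer(t_end)
  w <- as.integer(window_s)
  if (t_end < 1L || t_end > trace$duration) stop("t_end outside the session")
  start <- t_end - w
  if (start < 0L) {
    warning(sprintf("%s: baseline window truncated to %d s", trace$fly_id, t_end),
            call. = FALSE)
    start <- 0L
  }
  idx <- (start + 1L):t_end  # R indices of seconds start .. t_end-1
  counts <- trace$counts[idx]
  pos <- trace$position[idx]
  speed <- if (length(pos) > 1L) mean(abs(diff(pos))) else 0
  list(mean_counts = mean(counts), mean_speed = speed,
       n_seconds = length(idx))
}
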