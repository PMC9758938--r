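#' Tube-end occupancy (two-choice food preference)
#'
#' Scores positional dwell at the tube ends: side A is the first `end_beams`
#' beams, side B the last `end_beams` (the default scores each side's last
#' two infrared beams). Occupancy is the percentage of seconds per bin spent
#' in each scoring region; the middle of the tube is unscored, so
#' `pct_a + pct_b <= 100`.
#'
#' Analysis conventionally starts at the first ZT0 after placement (to let
#' anaesthesia and handling effects wash out); `start_s = NULL` applies that
#' default using the trace's `zt0`.
#'
#' @param trace An [activity_trace()].
#' @param end_beams Number of beams per scoring region.
#' @param bin_s Bin length in seconds (default 3600 = hourly).
#' @param start_s Analysis start second, or `NULL` for the first ZT0.
#' @return A `data.frame` with `fly_id`, `bin` (0-based hour index from
#'   analysis start), `zt` (ZT hour at bin start), `pct_a`, `pct_b`, `n_s`
#'   and `complete` (final partial bins are flagged `FALSE`).
#' @export
end_occupancy <- function(trace, end_beams = 2L, bin_s = 3600L,
                          start_s = NULL) {
  nb <- trace$geometry$n_beams
  end_beams <- as.integer(end_beams)
  if (end_beams < 1L || 2L * end_beams >= nb) stop("invalid end_beams")
  if (is.null(start_s)) {
    start_s <- as.integer(round(((24 - trace$zt0) %% 24) * 3600))
  }
  if (start_s >= trace$duration) stop("analysis start beyond session end")
  pos <- trace$position[(start_s + 1L):trace$duration]
  if (length(pos) < bin_s) stop("trace shorter than one bin")
  in_a <- pos <= end_beams
  in_b <- pos >= nb - end_beams + 1L
  bin <- (seq_along(pos) - 1L) %/% bin_s
  n_s <- as.integer(table(bin))
  bins <- as.integer(names(table(bin)))
  df <- data.frame(
    fly_id = trace$fly_id,
    bin = bins,
    zt = zt_at(start_s + bins * bin_s, trace$zt0),
    pct_a = 100 * as.numeric(tapply(in_a, bin, mean)),
    pct_b = 100 * as.numeric(tapply(in_b, bin, mean)),
    n_s = n_s,
    complete = n_s == bin_s,
    stringsAsFactors = FALSE, row.names = NULL)
  if (any(!df$complete)) {
    warning(sprintf("%s: final partial bin (%d s) flagged", trace$fly_id,
                    df$n_s[!df$complete][1L]), call. = FALSE)
  }
  df
}

#' Zone-colour occupancy (place preference)
#'
#' For closed-loop sessions: the percentage of seconds per bin a fly's
#' occupied zone showed blue versus green, under the session's swap-aware
#' colour mapping. Zones partition the tube, so `pct_blue + pct_green = 100`.
#'
#' @param assignment A [zone_assignment()] from [run_closed_loop()] (or
#'   [read_zone_csv()]).
#' @param bin_s Bin length in seconds (default 3600).
#' @param start_s Analysis start second; defaults to the start of feedback
#'   control (the end of habituation).
#' @return A `data.frame` with `fly_id`, `bin`, `hour` (from analysis
#'   start), `pct_blue`, `pct_green`, `n_s`, `complete`.
#' @export
zone_occupancy <- function(assignment, bin_s = 3600L, start_s = NULL) {
  if (!inherits(assignment, "zone_assignment")) {
    stop("assignment must be a zone_assignment")
  }
  rule <- attr(assignment, "rule")
  if (is.null(start_s)) start_s <- attr(assignment, "feedback_start_s")
  duration <- nrow(assignment)
  if (start_s >= duration) stop("analysis start beyond session end")
  sec <- start_s:(duration - 1L)
  if (anyNA(assignment[sec + 1L, ])) stop("gap in zone assignment")
  swap <- rule$swap_at_s
  swapped <- if (is.null(swap)) rep(FALSE, length(sec)) else sec >= swap
  # colour of the occupied zone, swap-aware
  blue_left <- rule$left_color == "blue"
  out <- lapply(seq_len(ncol(assignment)), function(j) {
    z <- assignment[sec + 1L, j]
    in_blue <- ifelse(swapped, (z == 1L) != blue_left, (z == 1L) == blue_left)
    bin <- (sec - start_s) %/% bin_s
    n_s <- as.integer(table(bin))
    bins <- as.integer(names(table(bin)))
    data.frame(fly_id = colnames(assignment)[j],
               bin = bins, hour = bins * bin_s / 3600,
               pct_blue = 100 * as.numeric(tapply(in_blue, bin, mean)),
               n_s = n_s, complete = n_s == bin_s,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  df <- do.call(rbind, out)
  df$pct_green <- 100 - df$pct_blue
  df[, c("fly_id", "bin", "hour", "pct_blue", "pct_green", "n_s", "complete")]
}

#' Correlation of preference with Zeitgeber Time
#'
#' Pools fly-by-bin preference values and Pearson-correlates them with the
#' ZT hour of the bin start — the test for a circadian trend in (e.g.)
#' ethanol-side occupancy. Constant preference has no defined correlation
#' and is flagged rather than computed.
#'
#' @param series A `data.frame` from [end_occupancy()] (rows from all flies),
#'   with a `zt` column.
#' @param value One of its columns to correlate (default `"pct_b"`, the
#'   ethanol side under the standard loading).
#' @param by_fly Average bins within fly before correlating.
#' @return A list with `r`, `p`, `n` and `flagged` (`TRUE` when undefined).
#' @export
zt_correlation <- function(series, value = "pct_b", by_fly = FALSE) {
  if (!all(c("zt", value) %in% names(series))) {
    stop("series must contain 'zt' and '", value, "' columns")
  }
  x <- series$zt
  y <- series[[value]]
  if (by_fly) {
    key <- interaction(series$fly_id, series$zt, drop = TRUE)
    x <- as.numeric(tapply(series$zt, key, `[`, 1L))
    y <- as.numeric(tapply(y, key, mean))
  }
  if (length(y) < 3L) stop("need at least 3 bins")
  if (var(y) == 0 || var(x) == 0) {
    warning("zero variance: ZT correlation undefined", call. = FALSE)
    return(list(r = NA_real_, p = NA_real_, n = length(y), flagged = TRUE))
  }
  ct <- pearson(x, y)
  list(r = ct$r, p = ct$p, n = ct$n, flagged = FALSE)
}
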