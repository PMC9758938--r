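#' Per-fly activity trace
#'
#' One fly in one tube over one session: per-second beam-crossing counts and
#' the beam index nearest the fly at the end of each second. A physically
#' sound trace satisfies the displacement invariant
#' `counts[k] >= |position[k] - position[k-1]|` (a fly cannot change its
#' nearest beam by more cells than beams it interrupted); real hardware can
#' glitch, so violations are reported as warnings, not errors.
#'
#' @param fly_id Opaque identifier (no commas or newlines; it travels in the
#'   CSV header).
#' @param counts Non-negative integer beam crossings per second.
#' @param position Beam index per second, in `[1, n_beams]`.
#' @param t0 Session start as `POSIXct` (whole seconds, UTC recommended).
#' @param zt0 Zeitgeber Time (hours) at `t0`; ZT0 = lights-on.
#' @param geometry A [beam_geometry()].
#' @param check_displacement Warn on displacement-invariant violations.
#' @return An object of class `activity_trace` with fields `fly_id`, `t0`,
#'   `zt0`, `counts`, `position`, `duration`, `geometry`.
#' @export
activity_trace <- function(fly_id, counts, position,
                           t0 = as.POSIXct("2026-01-01 08:00:00", tz = "UTC"),
                           zt0 = 0, geometry = beam_geometry(),
                           check_displacement = TRUE) {
  fly_id <- as.character(fly_id)
  if (length(fly_id) != 1L || is.na(fly_id) || grepl("[,\n]", fly_id)) {
    stop("fly_id must be a single string without commas or newlines")
  }
  counts <- as.integer(counts)
  position <- as.integer(position)
  if (length(counts) != length(position)) {
    stop("counts and position must have identical length")
  }
  if (length(counts) < 1L) stop("trace must contain at least one second")
  if (anyNA(counts) || any(counts < 0L)) stop("counts must be non-negative integers")
  if (anyNA(position) || any(position < 1L) || any(position > geometry$n_beams)) {
    stop("position must be beam indices in [1, n_beams]")
  }
  t0 <- as.POSIXct(t0)
  if (length(t0) != 1L || is.na(t0)) stop("t0 must be a single timestamp")
  t0 <- trunc(t0, units = "secs")
  zt0 <- as.numeric(zt0)
  if (is.na(zt0) || zt0 < 0 || zt0 >= 24) stop("zt0 must be in [0, 24)")
  tr <- structure(
    list(fly_id = fly_id, t0 = t0, zt0 = zt0, counts = counts,
         position = position, duration = length(counts), geometry = geometry),
    class = "activity_trace"
  )
  if (check_displacement) {
    bad <- displacement_violations(tr)
    if (length(bad)) {
      warning(sprintf("displacement invariant violated at second(s) %s%s",
                      paste(head(bad, 5L), collapse = ", "),
                      if (length(bad) > 5L) sprintf(" (+%d more)", length(bad) - 5L) else ""),
              call. = FALSE)
    }
  }
  tr
}

# 0-based seconds k where counts[k] < |position[k] - position[k-1]|.
displacement_violations <- function(trace) {
  d <- abs(diff(trace$position))
  which(trace$counts[-1L] < d)
}

#' @export
print.activity_trace <- function(x, ...) {
  cat(sprintf("<activity_trace> %s: %d s from %s (ZT%.2f), %d crossings\n",
              x$fly_id, x$duration, format(x$t0, "%Y-%m-%d %H:%M:%S"),
              x$zt0, sum(x$counts)))
  invisible(x)
}

#' Stimulus event log
#'
#' Millisecond-resolution record of LED state changes. Events must be sorted
#' by time and, per tube, consecutive events must actually change the light
#' (no duplicate no-op entries).
#'
#' @param time_ms Integer milliseconds from session start.
#' @param tubes List of integer tube-id vectors (or character range strings
#'   such as `"1-16"` / `"1,3,5"`), one per event.
#' @param color One of `off`, `white`, `blue`, `green` per event.
#' @param intensity Fraction in `[0, 1]` per event.
#' @return A `data.frame` of class `stimulus_log` with columns `time_ms`,
#'   `tubes` (list column of sorted integer vectors), `color`, `intensity`.
#' @export
stimulus_log <- function(time_ms = integer(), tubes = list(),
                         color = character(), intensity = numeric()) {
  time_ms <- as.integer(time_ms)
  n <- length(time_ms)
  if (is.character(tubes)) tubes <- lapply(tubes, parse_tube_set)
  tubes <- lapply(tubes, function(v) sort(unique(as.integer(v))))
  color <- as.character(color)
  intensity <- as.numeric(intensity)
  if (length(tubes) != n || length(color) != n || length(intensity) != n) {
    stop("time_ms, tubes, color and intensity must have equal length")
  }
  if (n && (anyNA(time_ms) || any(time_ms < 0L))) {
    stop("time_ms must be non-negative integers")
  }
  color_code(color)  # validates vocabulary
  if (n && (anyNA(intensity) || any(intensity < 0 | intensity > 1))) {
    stop("intensity must lie in [0, 1]")
  }
  if (n && is.unsorted(time_ms)) {
    stop("integrity error: stimulus events must be sorted by time_ms")
  }
  if (n && any(vapply(tubes, length, 1L) == 0L)) stop("every event needs >= 1 tube")
  log <- data.frame(time_ms = time_ms, color = color, intensity = intensity,
                    stringsAsFactors = FALSE)
  log$tubes <- tubes
  log <- log[, c("time_ms", "tubes", "color", "intensity")]
  class(log) <- c("stimulus_log", "data.frame")
  check_no_noop(log)
  log
}

# Per tube, consecutive events must differ in color or intensity.
check_no_noop <- function(log) {
  if (!nrow(log)) return(invisible(log))
  all_tubes <- sort(unique(unlist(log$tubes)))
  for (tb in all_tubes) {
    hit <- vapply(log$tubes, function(v) tb %in% v, TRUE)
    ev <- log[hit, , drop = FALSE]
    if (nrow(ev) > 1L) {
      same <- ev$color[-1L] == ev$color[-nrow(ev)] &
        ev$intensity[-1L] == ev$intensity[-nrow(ev)]
      if (any(same)) {
        stop(sprintf("integrity error: duplicate no-op event for tube %d at %d ms",
                     tb, ev$time_ms[-1L][which(same)[1L]]))
      }
    }
  }
  invisible(log)
}

#' @export
print.stimulus_log <- function(x, ...) {
  cat(sprintf("<stimulus_log> %d event(s)\n", nrow(x)))
  if (nrow(x)) {
    shown <- head(x, 10L)
    for (i in seq_len(nrow(shown))) {
      cat(sprintf("  %8d ms  tubes %-8s %-5s @%.2f\n", shown$time_ms[i],
                  format_tube_set(shown$tubes[[i]]), shown$color[i],
                  shown$intensity[i]))
    }
    if (nrow(x) > 10L) cat(sprintf("  ... %d more\n", nrow(x) - 10L))
  }
  invisible(x)
}

#' Format / parse tube-id sets
#'
#' Tube sets travel in stimulus-log files as compact range strings:
#' `"1-16"`, `"1,3,5"`, `"1-3,7"`.
#'
#' @param tubes Integer vector of tube ids.
#' @return `format_tube_set`: a single string; `parse_tube_set`: a sorted
#'   integer vector.
#' @export
format_tube_set <- function(tubes) {
  tubes <- sort(unique(as.integer(tubes)))
  if (!length(tubes)) stop("empty tube set")
  brk <- c(0L, which(diff(tubes) != 1L), length(tubes))
  parts <- vapply(seq_len(length(brk) - 1L), function(i) {
    run <- tubes[(brk[i] + 1L):brk[i + 1L]]
    if (length(run) == 1L) as.character(run)
    else paste0(run[1L], "-", run[length(run)])
  }, "")
  paste(parts, collapse = ",")
}

#' @rdname format_tube_set
#' @param s A range string.
#' @export
parse_tube_set <- function(s) {
  parts <- strsplit(trimws(s), ",", fixed = TRUE)[[1L]]
  if (!length(parts)) stop("empty tube set string")
  out <- unlist(lapply(parts, function(p) {
    if (grepl("-", p, fixed = TRUE)) {
      ab <- as.integer(strsplit(p, "-", fixed = TRUE)[[1L]])
      if (length(ab) != 2L || anyNA(ab) || ab[1L] > ab[2L]) {
        stop("malformed tube range: ", p)
      }
      ab[1L]:ab[2L]
    } else {
      v <- as.integer(p)
      if (is.na(v)) stop("malformed tube id: ", p)
      v
    }
  }))
  sort(unique(out))
}
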