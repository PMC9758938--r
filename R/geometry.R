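#' Beam geometry of a multi-beam tube monitor
#'
#' Describes the physical layout the whole toolkit assumes: a bank of tube
#' slots, each tube watched by `n_beams` infrared beams at known positions
#' along the tube. The default mirrors a 16-slot monitor with 17 evenly
#' spaced beams per tube.
#'
#' @param n_tubes Number of tube slots.
#' @param n_beams Number of infrared beams per tube (at least 3).
#' @param tube_length Physical tube length in mm.
#' @param beam_positions Optional strictly increasing coordinates (mm) of the
#'   beams, all inside `(0, tube_length)`. Defaults to even spacing.
#' @return An object of class `beam_geometry`.
#' @examples
#' geom <- beam_geometry()
#' geom$beam_positions
#' @export
beam_geometry <- function(n_tubes = 16L, n_beams = 17L, tube_length = 72,
                          beam_positions = NULL) {
  n_tubes <- as.integer(n_tubes)
  n_beams <- as.integer(n_beams)
  if (is.na(n_tubes) || n_tubes < 1L) stop("n_tubes must be a positive integer")
  if (is.na(n_beams) || n_beams < 3L) stop("n_beams must be >= 3")
  if (!is.numeric(tube_length) || tube_length <= 0) stop("tube_length must be > 0")
  if (is.null(beam_positions)) {
    beam_positions <- tube_length * seq_len(n_beams) / (n_beams + 1)
  }
  if (length(beam_positions) != n_beams) {
    stop("beam_positions must have length n_beams")
  }
  if (any(diff(beam_positions) <= 0)) {
    stop("beam_positions must be strictly increasing")
  }
  if (beam_positions[1] <= 0 || beam_positions[n_beams] >= tube_length) {
    stop("beam_positions must lie strictly inside (0, tube_length)")
  }
  structure(
    list(n_tubes = n_tubes, n_beams = n_beams,
         tube_length = as.numeric(tube_length),
         beam_positions = as.numeric(beam_positions)),
    class = "beam_geometry"
  )
}

#' @export
print.beam_geometry <- function(x, ...) {
  cat(sprintf("<beam_geometry> %d tubes x %d beams, tube %.1f mm\n",
              x$n_tubes, x$n_beams, x$tube_length))
  invisible(x)
}

#' Convert session time to Zeitgeber Time
#'
#' ZT0 is lights-on; under a 12:12 cycle the dark phase is ZT12-24. A session
#' that starts at ZT `zt0` maps its elapsed seconds onto the 24-h ZT circle.
#'
#' @param t_s Elapsed session time in seconds (vectorised).
#' @param zt0 ZT hour at session start.
#' @return ZT hours in `[0, 24)`.
#' @examples
#' zt_at(0, zt0 = 2)        # 2
#' zt_at(23 * 3600, zt0 = 2) # 1
#' @export
zt_at <- function(t_s, zt0 = 0) {
  (t_s / 3600 + zt0) %% 24
}

# Nearest beam index (1-based) for continuous positions, given a geometry.
nearest_beam_index <- function(x, geometry) {
  bp <- geometry$beam_positions
  mids <- (bp[-1] + bp[-length(bp)]) / 2
  findInterval(x, mids) + 1L
}
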