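#' Zone assignment container
#'
#' Per-second, per-fly zone labels (1 = left, 2 = right) from a closed-loop
#' run, carrying the [feedback_rule()] and the second at which feedback
#' control started.
#'
#' @param zones Integer matrix, seconds x flies, values 1/2; column names are
#'   fly ids.
#' @param rule The [feedback_rule()] that produced it.
#' @param feedback_start_s First second under feedback control.
#' @return An object of class `zone_assignment`.
#' @export
zone_assignment <- function(zones, rule, feedback_start_s = 0L) {
  if (!is.matrix(zones) || !all(zones %in% c(1L, 2L))) {
    stop("zones must be an integer matrix of 1 (left) / 2 (right)")
  }
  structure(zones, rule = rule,
            feedback_start_s = as.integer(feedback_start_s),
            class = "zone_assignment")
}

#' @export
print.zone_assignment <- function(x, ...) {
  cat(sprintf("<zone_assignment> %d s x %d flies (feedback from %d s)\n",
              nrow(x), ncol(x), attr(x, "feedback_start_s")))
  invisible(x)
}

# Colour each zone shows at time t_s under a rule (swap-aware).
# Returns c(left = , right = ).
zone_colors_at <- function(rule, t_s) {
  swapped <- !is.null(rule$swap_at_s) && t_s >= rule$swap_at_s
  if (swapped) c(left = rule$right_color, right = rule$left_color)
  else c(left = rule$left_color, right = rule$right_color)
}

#' One tick of the closed-loop controller
#'
#' Pure per-second controller logic: map each tube's current beam position to
#' a zone (left of the boundary beam, right of it, or the previous zone when
#' sitting exactly on it — hysteresis against LED chatter), then emit the LED
#' colour of the occupied zone under the swap-aware colour mapping. A command
#' is flagged only when the colour changes, so the resulting log stays
#' deduplicated.
#'
#' @param rule A [feedback_rule()].
#' @param positions Integer beam indices, one per tube.
#' @param prev_zones Previous zone labels (1 = left, 2 = right), or `NA` on
#'   the first tick.
#' @param t_s Current session time in seconds (drives the colour swap).
#' @param prev_colors Previously applied colours, or `NULL` on the first tick
#'   (then every tube gets a command).
#' @return A list with `zones` (integer), `colors` (character) and `command`
#'   (logical; `TRUE` where an LED command must be emitted).
#' @export
controller_step <- function(rule, positions, prev_zones = NULL, t_s = 0L,
                            prev_colors = NULL) {
  positions <- as.integer(positions)
  n <- length(positions)
  if (any(is.na(positions)) || any(positions < 1L)) {
    stop("positions must be beam indices >= 1")
  }
  if (is.null(prev_zones)) prev_zones <- rep(NA_integer_, n)
  zones <- ifelse(positions < rule$boundary_beam, 1L,
                  ifelse(positions > rule$boundary_beam, 2L,
                         as.integer(prev_zones)))
  if (anyNA(zones)) {
    # first tick with a fly exactly on the boundary beam: default left
    message("fly on boundary beam at first tick: defaulting to left zone")
    zones[is.na(zones)] <- 1L
  }
  cmap <- zone_colors_at(rule, t_s)
  colors <- unname(cmap[zones])
  command <- if (is.null(prev_colors)) rep(TRUE, n) else colors != prev_colors
  list(zones = zones, colors = colors, command = command)
}
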