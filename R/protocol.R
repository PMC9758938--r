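#' Zone feedback rule
#'
#' Declarative description of the per-second closed-loop controller: the tube
#' is split at `boundary_beam` into a left and a right zone, each zone owns a
#' colour, and the whole tube is lit in the colour of the zone the fly
#' occupies. At `swap_at_s` the colour mapping (not the accumulated zone
#' labels) is interchanged.
#'
#' @param boundary_beam Beam index dividing the zones; a fly sitting exactly
#'   on it keeps its previous zone (hysteresis). Default 9, the midpoint of a
#'   17-beam tube.
#' @param left_color,right_color Zone colours (must differ).
#' @param swap_at_s Optional session time (s) at which the colour mapping is
#'   interchanged.
#' @param tick_s Controller period in seconds (the acquisition resolution).
#' @return An object of class `feedback_rule`.
#' @export
feedback_rule <- function(boundary_beam = 9L, left_color = "blue",
                          right_color = "green", swap_at_s = NULL,
                          tick_s = 1L) {
  boundary_beam <- as.integer(boundary_beam)
  color_code(c(left_color, right_color))
  if (left_color == right_color) stop("left_color and right_color must differ")
  if (!is.null(swap_at_s)) {
    swap_at_s <- as.integer(swap_at_s)
    if (is.na(swap_at_s) || swap_at_s < 0L) stop("swap_at_s must be >= 0")
  }
  if (tick_s != 1L) stop("only a 1-s controller tick is supported")
  structure(list(boundary_beam = boundary_beam, left_color = left_color,
                 right_color = right_color, swap_at_s = swap_at_s,
                 tick_s = 1L),
            class = "feedback_rule")
}

#' Declarative light protocol
#'
#' A protocol is an open-loop timeline, an optional sudden-darkness pulse
#' train, an optional light:dark cycle, or an optional feedback rule, always
#' preceded by a habituation period under constant white light. The pulse
#' train and the LD cycle are mutually exclusive.
#'
#' @param name Protocol name.
#' @param duration_s Total session length in seconds.
#' @param habituation_s Habituation period (s) under white light before the
#'   programmed stimulation starts. Default 1800 (30 min).
#' @param timeline Optional `data.frame` of open-loop segments with columns
#'   `start_ms`, `end_ms`, `color`, `intensity` (segments may not overlap).
#' @param stimuli Optional pulse train: `list(color = "off", pulse_ms = 1000,
#'   first_at_s, iti_s, n_trials)`. Defaults fill in the sudden-darkness
#'   stimulus (1-s lights-off starting at the end of habituation).
#' @param ld_cycle Optional light:dark cycle: `list(period_h = 24,
#'   light_h = 12, start_zt = 0)`, where `start_zt` is the ZT hour at session
#'   start.
#' @param feedback Optional [feedback_rule()].
#' @return An object of class `protocol_spec`.
#' @seealso [darkness_protocol()], [ld_protocol()], [place_protocol()]
#' @export
protocol_spec <- function(name, duration_s, habituation_s = 1800L,
                          timeline = NULL, stimuli = NULL, ld_cycle = NULL,
                          feedback = NULL) {
  duration_s <- as.integer(duration_s)
  habituation_s <- as.integer(habituation_s)
  if (is.na(duration_s) || duration_s < 1L) stop("duration_s must be >= 1")
  if (is.na(habituation_s) || habituation_s < 0L) stop("habituation_s must be >= 0")
  if (habituation_s > duration_s) stop("habituation exceeds protocol duration")
  if (!is.null(stimuli) && !is.null(ld_cycle)) {
    stop("stimuli pulse train and ld_cycle are mutually exclusive")
  }
  if (!is.null(stimuli)) {
    defaults <- list(color = "off", pulse_ms = 1000L,
                     first_at_s = habituation_s, iti_s = 1800L, n_trials = 6L)
    stimuli <- utils::modifyList(defaults, stimuli)
    stimuli$pulse_ms <- as.integer(stimuli$pulse_ms)
    stimuli$first_at_s <- as.integer(stimuli$first_at_s)
    stimuli$iti_s <- as.integer(stimuli$iti_s)
    stimuli$n_trials <- as.integer(stimuli$n_trials)
    color_code(stimuli$color)
    if (stimuli$n_trials < 1L || stimuli$iti_s < 1L || stimuli$pulse_ms < 1L) {
      stop("stimuli pulse train needs n_trials >= 1, iti_s >= 1, pulse_ms >= 1")
    }
    if (stimuli$pulse_ms > 1000L * stimuli$iti_s) {
      stop("pulse_ms may not exceed the inter-trial interval")
    }
    last_end_s <- stimuli$first_at_s + (stimuli$n_trials - 1L) * stimuli$iti_s +
      stimuli$pulse_ms / 1000
    if (last_end_s > duration_s) {
      stop("validation error: pulse train extends past protocol duration")
    }
  }
  if (!is.null(ld_cycle)) {
    defaults <- list(period_h = 24, light_h = 12, start_zt = 0)
    ld_cycle <- utils::modifyList(defaults, ld_cycle)
    if (ld_cycle$light_h <= 0 || ld_cycle$light_h >= ld_cycle$period_h) {
      stop("ld_cycle needs 0 < light_h < period_h")
    }
    if (ld_cycle$start_zt < 0 || ld_cycle$start_zt >= ld_cycle$period_h) {
      stop("ld_cycle start_zt must be in [0, period_h)")
    }
  }
  if (!is.null(timeline)) {
    req <- c("start_ms", "end_ms", "color", "intensity")
    if (!is.data.frame(timeline) || !all(req %in% names(timeline))) {
      stop("timeline must be a data.frame with start_ms, end_ms, color, intensity")
    }
    timeline <- timeline[order(timeline$start_ms), , drop = FALSE]
    color_code(timeline$color)
    if (any(timeline$end_ms <= timeline$start_ms)) stop("empty timeline segment")
    if (any(timeline$end_ms > duration_s * 1000)) {
      stop("timeline segment extends past protocol duration")
    }
    if (nrow(timeline) > 1L &&
        any(timeline$start_ms[-1L] < timeline$end_ms[-nrow(timeline)])) {
      stop("timeline segments overlap")
    }
  }
  if (!is.null(feedback) && !inherits(feedback, "feedback_rule")) {
    stop("feedback must be a feedback_rule")
  }
  structure(list(name = as.character(name), duration_s = duration_s,
                 habituation_s = habituation_s, timeline = timeline,
                 stimuli = stimuli, ld_cycle = ld_cycle, feedback = feedback),
            class = "protocol_spec")
}

#' @export
print.protocol_spec <- function(x, ...) {
  cat(sprintf("<protocol_spec> '%s': %d s (habituation %d s)\n",
              x$name, x$duration_s, x$habituation_s))
  if (!is.null(x$stimuli)) {
    cat(sprintf("  pulses: %d x %d ms '%s', first at %d s, ITI %d s\n",
                x$stimuli$n_trials, x$stimuli$pulse_ms, x$stimuli$color,
                x$stimuli$first_at_s, x$stimuli$iti_s))
  }
  if (!is.null(x$ld_cycle)) {
    cat(sprintf("  LD cycle: %g:%g h from ZT%g\n", x$ld_cycle$light_h,
                x$ld_cycle$period_h - x$ld_cycle$light_h, x$ld_cycle$start_zt))
  }
  if (!is.null(x$feedback)) {
    cat(sprintf("  feedback: boundary beam %d, left=%s right=%s%s\n",
                x$feedback$boundary_beam, x$feedback$left_color,
                x$feedback$right_color,
                if (!is.null(x$feedback$swap_at_s))
                  sprintf(", swap at %d s", x$feedback$swap_at_s) else ""))
  }
  invisible(x)
}

#' Canonical protocols
#'
#' Convenience constructors for the three assay protocols: the
#' sudden-darkness startle protocol (constant white light, 1-s lights-off
#' pulses at a fixed inter-trial interval after a 30-min habituation), a
#' 12:12 light:dark cycle for long-term recording, and the zone-feedback
#' place-preference protocol.
#'
#' @param iti_s Inter-trial interval in seconds (1800 = the 30-min / 6-trial
#'   protocol; 300 and 60 give the 5-min and 1-min repeated-stimulation
#'   protocols).
#' @param n_trials Number of lights-off pulses; defaults to a stimulation
#'   phase as long as `n_trials * iti_s`.
#' @param habituation_s Habituation period (s).
#' @param pulse_ms Pulse duration (ms); 1000 for the 1-s darkness stimulus.
#' @return A [protocol_spec()].
#' @export
darkness_protocol <- function(iti_s = 1800L, n_trials = 6L,
                              habituation_s = 1800L, pulse_ms = 1000L) {
  duration <- habituation_s + n_trials * iti_s
  protocol_spec(
    name = sprintf("darkness-iti%d", iti_s),
    duration_s = duration, habituation_s = habituation_s,
    stimuli = list(color = "off", pulse_ms = pulse_ms,
                   first_at_s = habituation_s, iti_s = iti_s,
                   n_trials = n_trials)
  )
}

#' @rdname darkness_protocol
#' @param hours Total recording length in hours.
#' @param start_zt ZT hour at session start.
#' @export
ld_protocol <- function(hours = 48, start_zt = 0, habituation_s = 0L) {
  protocol_spec(name = sprintf("ld12:12-%gh", hours),
                duration_s = round(hours * 3600), habituation_s = habituation_s,
                ld_cycle = list(period_h = 24, light_h = 12,
                                start_zt = start_zt))
}

#' @rdname darkness_protocol
#' @param conditioning_h Hours of closed-loop conditioning after habituation.
#' @param swap_at_h Optional hour (of conditioning) at which zone colours are
#'   interchanged.
#' @param boundary_beam,left_color,right_color Passed to [feedback_rule()].
#' @export
place_protocol <- function(conditioning_h = 5, habituation_s = 1800L,
                           swap_at_h = NULL, boundary_beam = 9L,
                           left_color = "blue", right_color = "green") {
  swap_at_s <- if (!is.null(swap_at_h)) habituation_s + round(swap_at_h * 3600)
  protocol_spec(
    name = sprintf("place-%gh%s", conditioning_h,
                   if (is.null(swap_at_h)) "" else sprintf("-swap%gh", swap_at_h)),
    duration_s = habituation_s + round(conditioning_h * 3600),
    habituation_s = habituation_s,
    feedback = feedback_rule(boundary_beam = boundary_beam,
                             left_color = left_color,
                             right_color = right_color,
                             swap_at_s = swap_at_s)
  )
}

#' Compile a protocol into an open-loop stimulus log
#'
#' Deterministically expands the declarative protocol into the
#' millisecond-resolution LED event log a rig would execute: white light from
#' t = 0 with the programmed lights-off pulses for the darkness protocol,
#' white/off toggles at phase boundaries for an LD cycle, or the explicit
#' timeline segments. For feedback protocols only the habituation backdrop is
#' compiled; zone-driven events are produced at run time by
#' [run_closed_loop()].
#'
#' @param spec A [protocol_spec()].
#' @param geometry A [beam_geometry()]; events address all its tubes.
#' @return A [stimulus_log()].
#' @examples
#' log <- compile_protocol(darkness_protocol())
#' subset(as.data.frame(log), color == "off")$time_ms / 1000
#' @export
compile_protocol <- function(spec, geometry = beam_geometry()) {
  if (!inherits(spec, "protocol_spec")) stop("spec must be a protocol_spec")
  all_tubes <- seq_len(geometry$n_tubes)
  ev_t <- integer(); ev_col <- character(); ev_int <- numeric()
  add <- function(t_ms, color, intensity) {
    ev_t <<- c(ev_t, as.integer(t_ms))
    ev_col <<- c(ev_col, color)
    ev_int <<- c(ev_int, intensity)
  }
  if (!is.null(spec$stimuli)) {
    st <- spec$stimuli
    add(0L, "white", 1)
    for (k in seq_len(st$n_trials) - 1L) {
      t_on <- (st$first_at_s + k * st$iti_s) * 1000L
      add(t_on, st$color, if (st$color == "off") 0 else 1)
      add(t_on + st$pulse_ms, "white", 1)
    }
  } else if (!is.null(spec$ld_cycle)) {
    ld <- spec$ld_cycle
    phase_at <- function(t_s) (ld$start_zt + t_s / 3600) %% ld$period_h
    light0 <- phase_at(0) < ld$light_h
    add(0L, if (light0) "white" else "off", if (light0) 1 else 0)
    # every boundary where ZT phase hits 0 (lights-on) or light_h (lights-off)
    bound_zt <- sort(c(0, ld$light_h))
    t <- 0
    state <- light0
    repeat {
      ph <- phase_at(t)
      nxt <- bound_zt[bound_zt > ph + 1e-9]
      dt <- if (length(nxt)) (nxt[1L] - ph) * 3600 else (ld$period_h - ph) * 3600
      t <- t + dt
      if (t >= spec$duration_s - 1e-9) break
      state <- !state
      add(round(t * 1000), if (state) "white" else "off", if (state) 1 else 0)
    }
  } else if (!is.null(spec$timeline)) {
    tl <- spec$timeline
    cursor <- 0
    for (i in seq_len(nrow(tl))) {
      if (tl$start_ms[i] > cursor) add(cursor, "off", 0)
      add(tl$start_ms[i], tl$color[i], tl$intensity[i])
      cursor <- tl$end_ms[i]
    }
    if (cursor < spec$duration_s * 1000) add(cursor, "off", 0)
  } else {
    # feedback-only (or bare) protocol: habituation backdrop
    add(0L, "white", 1)
  }
  ord <- order(ev_t)
  ev_t <- ev_t[ord]; ev_col <- ev_col[ord]; ev_int <- ev_int[ord]
  # drop no-ops introduced by adjacent identical states
  if (length(ev_t) > 1L) {
    keep <- c(TRUE, ev_col[-1L] != ev_col[-length(ev_col)] |
                ev_int[-1L] != ev_int[-length(ev_int)])
    ev_t <- ev_t[keep]; ev_col <- ev_col[keep]; ev_int <- ev_int[keep]
  }
  stimulus_log(time_ms = ev_t,
               tubes = replicate(length(ev_t), all_tubes, simplify = FALSE),
               color = ev_col, intensity = ev_int)
}

#' Stimulus seconds of a pulse-train protocol
#'
#' The seconds (0-based session time) during which the protocol's
#' sudden-darkness pulses occur; these are the trial times the startle
#' analysis aligns on.
#'
#' @param spec A [protocol_spec()] with a `stimuli` pulse train.
#' @return Integer vector of stimulus seconds.
#' @export
stimulus_seconds <- function(spec) {
  if (is.null(spec$stimuli)) stop("protocol has no stimulus pulse train")
  st <- spec$stimuli
  st$first_at_s + (seq_len(st$n_trials) - 1L) * st$iti_s
}

# Per-second ambient colour codes for one tube, expanded from an open-loop
# stimulus log (last event at or before each second wins).
expand_colors <- function(log, tube, duration_s) {
  hit <- vapply(log$tubes, function(v) tube %in% v, TRUE)
  ev <- log[hit, , drop = FALSE]
  if (!nrow(ev)) return(rep(color_code("white"), duration_s))
  sec <- 0:(duration_s - 1L)
  idx <- findInterval(sec * 1000, ev$time_ms)
  codes <- c(color_code("white"), color_code(ev$color))
  codes[idx + 1L]
}
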