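#' Generative parameters of one simulated fly
#'
#' The agent model is a 1-D continuous random walk in the tube with
#' reflecting walls. Each second the fly moves with probability
#' `clamp(p_move * phase_factor + effective_beta, 0, 1)`; a moving fly
#' displaces by a zero-mean Gaussian (sd `step_scale` mm) plus drift terms,
#' and scores `max(1, beam cells crossed)` crossings. A sudden-darkness
#' stimulus raises the movement rate by an exponentially decaying increment
#' (`startle_gain`, time constant `startle_tau`); repeated stimuli
#' desensitise it through a habituation load that decays the effective gain
#' by `habit_decay` per stimulus and recovers with time constant
#' `habit_recovery` — so short inter-trial intervals habituate more than long
#' ones.
#'
#' @param p_move Baseline per-second movement probability.
#' @param step_scale Displacement sd per moving second, mm (the default
#'   geometry spaces beams 4 mm apart).
#' @param startle_gain Additive movement-probability increment right after a
#'   lights-off stimulus; 0 = non-responder, negative = freezer.
#' @param startle_tau Decay time constant of the startle increment (s); the
#'   response has largely faded by 30 s.
#' @param startle_sign_mix Probabilities `c(none, negative, positive)` that a
#'   cohort fly is a non-, negative or positive responder (used by
#'   [make_cohort()] when heterogeneity is on).
#' @param habit_decay Per-stimulus multiplicative decay of the effective
#'   startle gain (kappa; 1 = no habituation).
#' @param habit_recovery Recovery time constant of the habituation load (s).
#' @param light_factor,dark_factor Multiplicative activity factors in the
#'   light/dark phase of an LD cycle.
#' @param food_bias Drift weights (mm/s) `c(a, b)` toward the near tube end
#'   (end A at x = 0, end B at x = tube_length).
#' @param ethanol_dark_boost Additional drift (mm/s) toward end B (the
#'   ethanol end) during the dark phase.
#' @param blue_aversion Innate drift (mm/s) out of the occupied zone while
#'   the tube is lit blue.
#' @param learn_rate Per-second growth of the position-bound avoidance weight
#'   for the side where blue light is experienced (0 = innate-only).
#' @param learn_cap Saturation of the learned avoidance weights (mm/s).
#' @param fly_id Optional identifier.
#' @return An object of class `fly_params`.
#' @export
fly_params <- function(p_move = 0.25, step_scale = 4, startle_gain = 0.4,
                       startle_tau = 12,
                       startle_sign_mix = c(none = 0, negative = 0, positive = 1),
                       habit_decay = 0.85, habit_recovery = 600,
                       light_factor = 1, dark_factor = 0.5,
                       food_bias = c(a = 0, b = 0), ethanol_dark_boost = 0,
                       blue_aversion = 0, learn_rate = 0, learn_cap = 1,
                       fly_id = NULL) {
  if (p_move < 0 || p_move > 1) stop("p_move must lie in [0, 1]")
  if (step_scale <= 0) stop("step_scale must be > 0")
  if (startle_tau <= 0 || habit_recovery <= 0) stop("time constants must be > 0")
  if (habit_decay < 0 || habit_decay > 1) stop("habit_decay must lie in [0, 1]")
  startle_sign_mix <- as.numeric(startle_sign_mix)
  if (length(startle_sign_mix) != 3L || any(startle_sign_mix < 0) ||
      abs(sum(startle_sign_mix) - 1) > 1e-9) {
    stop("invalid mixture weights: startle_sign_mix must be 3 probabilities summing to 1")
  }
  names(startle_sign_mix) <- c("none", "negative", "positive")
  if (light_factor < 0 || dark_factor < 0) stop("phase factors must be >= 0")
  food_bias <- as.numeric(food_bias)
  if (length(food_bias) == 1L) food_bias <- c(food_bias, food_bias)
  if (length(food_bias) != 2L || any(food_bias < 0)) {
    stop("food_bias must be two non-negative drift weights c(a, b)")
  }
  names(food_bias) <- c("a", "b")
  if (ethanol_dark_boost < 0 || blue_aversion < 0 || learn_rate < 0) {
    stop("drift weights must be >= 0")
  }
  if (learn_cap <= 0) stop("learn_cap must be > 0")
  structure(list(p_move = p_move, step_scale = step_scale,
                 startle_gain = startle_gain, startle_tau = startle_tau,
                 startle_sign_mix = startle_sign_mix,
                 habit_decay = habit_decay, habit_recovery = habit_recovery,
                 light_factor = light_factor, dark_factor = dark_factor,
                 food_bias = food_bias, ethanol_dark_boost = ethanol_dark_boost,
                 blue_aversion = blue_aversion, learn_rate = learn_rate,
                 learn_cap = learn_cap, fly_id = fly_id),
            class = "fly_params")
}

# Parameter list handed to the C++ core.
cpp_params <- function(params) {
  list(p_move = params$p_move, step_scale = params$step_scale,
       startle_gain = params$startle_gain, startle_tau = params$startle_tau,
       habit_decay = params$habit_decay, habit_recovery = params$habit_recovery,
       light_factor = params$light_factor, dark_factor = params$dark_factor,
       food_bias_a = unname(params$food_bias["a"]),
       food_bias_b = unname(params$food_bias["b"]),
       ethanol_dark_boost = params$ethanol_dark_boost,
       blue_aversion = params$blue_aversion, learn_rate = params$learn_rate,
       learn_cap = params$learn_cap)
}

#' Instantaneous state of one simulated fly
#'
#' @param x Continuous position in `[0, tube_length]` mm.
#' @param effective_beta Current startle increment to the movement rate.
#' @param habit_load Habituation load (effective stimulus count).
#' @param last_stim_s Time of the last stimulus (s), `-1` if none yet.
#' @param learned_left,learned_right Learned avoidance weights per side.
#' @param t_s Current session time (s).
#' @return An object of class `fly_state`.
#' @export
fly_state <- function(x, effective_beta = 0, habit_load = 0,
                      last_stim_s = -1, learned_left = 0, learned_right = 0,
                      t_s = 0) {
  structure(list(x = x, effective_beta = effective_beta,
                 habit_load = habit_load, last_stim_s = last_stim_s,
                 learned_left = learned_left, learned_right = learned_right,
                 t_s = t_s),
            class = "fly_state")
}

#' Advance one fly by one second
#'
#' Single tick of the agent model (see [fly_params()] for the dynamics).
#' Mainly useful for inspecting the mechanics; whole sessions run through
#' [simulate_session()].
#'
#' @param state A [fly_state()].
#' @param params A [fly_params()].
#' @param light Colour experienced this second (`off`/`white`/`blue`/`green`).
#' @param dark Is this second in the dark phase of an LD cycle?
#' @param geometry A [beam_geometry()].
#' @param boundary_beam Zone boundary used by the blue-aversion drift.
#' @return A list with the updated `state`, integer `crossings` and
#'   `beam_position`.
#' @export
step_fly <- function(state, params, light = "white", dark = FALSE,
                     geometry = beam_geometry(),
                     boundary_beam = (geometry$n_beams + 1L) %/% 2L) {
  res <- sim_fly_cpp(
    x0 = state$x, duration = 1L, beam_pos = geometry$beam_positions,
    tube_len = geometry$tube_length, par = cpp_params(params),
    dark_phase = dark, stim_sec = integer(),
    color_ol = color_code(light),
    feedback = FALSE, feedback_start = 0L, boundary_beam = boundary_beam,
    left_color_pre = 2L, right_color_pre = 3L,
    left_color_post = 3L, right_color_post = 2L, swap_at_s = -1L,
    state0 = unclass(state))
  st <- res$state
  new_state <- fly_state(x = st$x, effective_beta = st$effective_beta,
                         habit_load = st$habit_load,
                         last_stim_s = st$last_stim_s,
                         learned_left = st$learned_left,
                         learned_right = st$learned_right,
                         t_s = state$t_s + 1)
  list(state = new_state, crossings = res$counts[1L],
       beam_position = res$position[1L])
}

#' Register a sudden-darkness stimulus
#'
#' Sets the effective startle increment to
#' `startle_gain * habit_decay^n_eff`, where the habituation load `n_eff`
#' has relaxed toward zero with time constant `habit_recovery` since the last
#' stimulus and then increments by one. This is the desensitisation kernel:
#' 1-min inter-trial intervals accumulate load faster than 5-min ones.
#'
#' @param state A [fly_state()].
#' @param params A [fly_params()].
#' @param t_s Stimulus time (s); defaults to the state's clock.
#' @return The updated `fly_state`.
#' @export
apply_lights_off <- function(state, params, t_s = state$t_s) {
  load <- state$habit_load
  if (state$last_stim_s >= 0) {
    load <- load * exp(-(t_s - state$last_stim_s) / params$habit_recovery)
  }
  state$effective_beta <- params$startle_gain * params$habit_decay^load
  state$habit_load <- load + 1
  state$last_stim_s <- t_s
  state
}

#' Effective startle gain over a stimulus train
#'
#' Deterministic recursion giving the effective startle increment at each
#' stimulus of a train, under the habituation kernel of [apply_lights_off()].
#'
#' @param params A [fly_params()].
#' @param stim_times_s Stimulus times in seconds (increasing).
#' @return Numeric vector, one effective gain per stimulus.
#' @examples
#' p <- fly_params(habit_decay = 0.7, habit_recovery = 600)
#' effective_startle(p, seq(0, by = 60, length.out = 5))
#' @export
effective_startle <- function(params, stim_times_s) {
  st <- fly_state(x = 0)
  out <- numeric(length(stim_times_s))
  for (i in seq_along(stim_times_s)) {
    st <- apply_lights_off(st, params, t_s = stim_times_s[i])
    out[i] <- st$effective_beta
  }
  out
}

#' Draw a heterogeneous cohort
#'
#' Expands a template [fly_params()] into `n` flies. With heterogeneity on,
#' each fly's startle gain is drawn from the template's
#' `startle_sign_mix` responder mixture (non-responders get gain 0, negative
#' responders `-negative_scale * startle_gain`), and `p_move` may be jittered.
#' With heterogeneity off the cohort is `n` identical copies.
#'
#' @param template A [fly_params()].
#' @param n Cohort size (>= 1).
#' @param heterogeneity `NULL`/`FALSE` for identical copies, `TRUE` for the
#'   template's responder mixture, or a list with any of `negative_scale`
#'   (default 0.5) and `p_move_sd` (default 0).
#' @param seed Optional RNG seed, so cohort composition is stable across
#'   protocols.
#' @return A list of `fly_params`, with `fly_id`s `fly001`, `fly002`, ...
#' @export
make_cohort <- function(template, n, heterogeneity = NULL, seed = NULL) {
  if (!inherits(template, "fly_params")) stop("template must be fly_params")
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  opts <- list(negative_scale = 0.5, p_move_sd = 0)
  het <- !is.null(heterogeneity) && !identical(heterogeneity, FALSE)
  if (is.list(heterogeneity)) opts <- utils::modifyList(opts, heterogeneity)
  cohort <- vector("list", n)
  classes <- if (het) {
    sample(c("none", "negative", "positive"), n, replace = TRUE,
           prob = template$startle_sign_mix)
  } else rep("template", n)
  for (i in seq_len(n)) {
    p <- template
    p$fly_id <- sprintf("fly%03d", i)
    if (het) {
      p$startle_gain <- switch(classes[i],
        none = 0,
        negative = -opts$negative_scale * abs(template$startle_gain),
        positive = abs(template$startle_gain))
      if (opts$p_move_sd > 0) {
        p$p_move <- min(0.95, max(0.01, rnorm(1, template$p_move, opts$p_move_sd)))
      }
    }
    cohort[[i]] <- p
  }
  attr(cohort, "responder_class") <- classes
  cohort
}

#' Cohort presets for the standard fly lines
#'
#' Calibration presets for the three lines the assays use: a red-eyed
#' wild type (`csorc`, zero-delta rate 59%), a white-eyed mutant (`w1118`,
#' zero-delta rate 31%, more sensitive to repeated stimulation) and a
#' fragile-X model (`fmr1`, no darkness response).
#'
#' @param line One of `"csorc"`, `"w1118"`, `"fmr1"`.
#' @return A list with `template` ([fly_params()]) and `heterogeneity`
#'   (list), ready for [make_cohort()].
#' @export
cohort_preset <- function(line = c("csorc", "w1118", "fmr1")) {
  line <- match.arg(line)
  switch(line,
    csorc = list(
      template = fly_params(startle_gain = 0.4, habit_decay = 0.85,
                            habit_recovery = 600,
                            startle_sign_mix = c(none = 0.59, negative = 0.08,
                                                 positive = 0.33)),
      heterogeneity = list(negative_scale = 0.5, p_move_sd = 0.05)),
    w1118 = list(
      template = fly_params(startle_gain = 0.45, habit_decay = 0.80,
                            habit_recovery = 1800,
                            startle_sign_mix = c(none = 0.31, negative = 0.08,
                                                 positive = 0.61)),
      heterogeneity = list(negative_scale = 0.5, p_move_sd = 0.05)),
    fmr1 = list(
      template = fly_params(startle_gain = 0,
                            startle_sign_mix = c(none = 1, negative = 0,
                                                 positive = 0)),
      heterogeneity = list())
  )
}

#' Simulate a session of flies under a protocol
#'
#' Runs the agent model for every fly of a cohort (at most one per tube slot)
#' under an open-loop or closed-loop protocol. Open-loop protocols are
#' compiled with [compile_protocol()]; for feedback protocols the per-second
#' controller runs inside the loop with one-tick latency and the stimulus log
#' is assembled from the applied colours. Reproducible given `seed`.
#'
#' @param spec A [protocol_spec()].
#' @param cohort A list of [fly_params()] (length <= `geometry$n_tubes`).
#' @param seed Optional RNG seed.
#' @param geometry A [beam_geometry()].
#' @param t0 Session start timestamp.
#' @param zt0 ZT hour at session start; defaults to the LD cycle's `start_zt`
#'   (0 if the protocol has no LD cycle).
#' @return An object of class `photobeam_session`: a list with `traces`
#'   (list of [activity_trace()]), `stim_log` ([stimulus_log()]), `zones`
#'   ([zone_assignment()] or `NULL`), `stim_sec`, `x0`, `spec`, `seed`.
#' @export
simulate_session <- function(spec, cohort, seed = NULL,
                             geometry = beam_geometry(),
                             t0 = as.POSIXct("2026-01-01 08:00:00", tz = "UTC"),
                             zt0 = NULL) {
  if (!inherits(spec, "protocol_spec")) stop("spec must be a protocol_spec")
  if (inherits(cohort, "fly_params")) cohort <- list(cohort)
  n <- length(cohort)
  if (n < 1L) stop("usage error: empty cohort")
  if (n > geometry$n_tubes) {
    stop(sprintf("usage error: cohort of %d exceeds the %d tube slots", n,
                 geometry$n_tubes))
  }
  if (is.null(zt0)) {
    zt0 <- if (!is.null(spec$ld_cycle)) spec$ld_cycle$start_zt else 0
  }
  duration <- spec$duration_s
  feedback <- !is.null(spec$feedback)

  dark <- if (!is.null(spec$ld_cycle)) {
    ld <- spec$ld_cycle
    ((ld$start_zt + (0:(duration - 1L)) / 3600) %% ld$period_h) >= ld$light_h
  } else logical(0)

  stim_sec <- if (!is.null(spec$stimuli)) stimulus_seconds(spec) else integer(0)

  color_ol <- integer(0)
  open_log <- NULL
  rule <- spec$feedback
  if (!feedback) {
    open_log <- compile_protocol(spec, geometry)
    # compiled logs address all tubes identically; expand once
    color_ol <- expand_colors(open_log, 1L, duration)
  }

  if (!is.null(seed)) set.seed(seed)
  traces <- vector("list", n)
  zones <- if (feedback) matrix(NA_integer_, duration, n)
  colors_fb <- if (feedback) matrix(NA_integer_, duration, n)
  x0s <- numeric(n)
  lc <- if (feedback) color_code(rule$left_color) else 2L
  rc <- if (feedback) color_code(rule$right_color) else 3L
  swap <- if (feedback && !is.null(rule$swap_at_s)) rule$swap_at_s else -1L

  for (i in seq_len(n)) {
    params <- cohort[[i]]
    if (!inherits(params, "fly_params")) stop("cohort must contain fly_params")
    x0s[i] <- runif(1, 0, geometry$tube_length)
    res <- sim_fly_cpp(
      x0 = x0s[i], duration = duration, beam_pos = geometry$beam_positions,
      tube_len = geometry$tube_length, par = cpp_params(params),
      dark_phase = dark, stim_sec = as.integer(stim_sec),
      color_ol = color_ol, feedback = feedback,
      feedback_start = spec$habituation_s,
      boundary_beam = if (feedback) rule$boundary_beam
                      else (geometry$n_beams + 1L) %/% 2L,
      left_color_pre = lc, right_color_pre = rc,
      left_color_post = rc, right_color_post = lc,
      swap_at_s = as.integer(swap), state0 = list())
    fid <- if (is.null(params$fly_id)) sprintf("fly%03d", i) else params$fly_id
    traces[[i]] <- activity_trace(fid, counts = res$counts,
                                  position = res$position, t0 = t0, zt0 = zt0,
                                  geometry = geometry,
                                  check_displacement = FALSE)
    if (feedback) {
      zones[, i] <- res$zone
      colors_fb[, i] <- res$color
    }
  }

  fly_ids <- vapply(traces, `[[`, "", "fly_id")
  if (feedback) {
    colnames(zones) <- fly_ids
    za <- zone_assignment(zones, rule = rule,
                          feedback_start_s = spec$habituation_s)
    stim_log <- colors_to_log(colors_fb)
  } else {
    za <- NULL
    stim_log <- open_log
  }
  structure(list(traces = traces, stim_log = stim_log, zones = za,
                 stim_sec = stim_sec, x0 = x0s, spec = spec, seed = seed),
            class = "photobeam_session")
}

# Collapse per-second applied colours (seconds x tubes matrix of codes) into
# a deduplicated, sorted stimulus log with one-tube events.
colors_to_log <- function(colors) {
  t_ms <- integer(); tubes <- integer(); col <- integer()
  for (j in seq_len(ncol(colors))) {
    r <- rle(colors[, j])
    starts <- c(0L, cumsum(r$lengths)[-length(r$lengths)])
    t_ms <- c(t_ms, starts * 1000L)
    tubes <- c(tubes, rep(j, length(starts)))
    col <- c(col, r$values)
  }
  ord <- order(t_ms, tubes)
  stimulus_log(time_ms = t_ms[ord],
               tubes = as.list(tubes[ord]),
               color = color_name(col[ord]),
               intensity = as.numeric(col[ord] != 0L))
}

#' @export
print.photobeam_session <- function(x, ...) {
  cat(sprintf("<photobeam_session> '%s': %d flies x %d s, %d stimulus events%s\n",
              x$spec$name, length(x$traces), x$spec$duration_s,
              nrow(x$stim_log),
              if (!is.null(x$zones)) " (closed loop)" else ""))
  invisible(x)
}

#' Run a closed-loop place-preference session
#'
#' Thin wrapper over [simulate_session()] for protocols with a
#' [feedback_rule()]: every second the controller reads each fly's zone and
#' applies the zone's colour to its whole tube on the next tick.
#'
#' @inheritParams simulate_session
#' @return A `photobeam_session` (with non-`NULL` `zones`).
#' @export
run_closed_loop <- function(spec, cohort, seed = NULL,
                            geometry = beam_geometry(), ...) {
  if (is.null(spec$feedback)) stop("spec has no feedback rule")
  simulate_session(spec, cohort, seed = seed, geometry = geometry, ...)
}

#' Simulate a cohort larger than one monitor
#'
#' Splits a cohort into batches of at most `geometry$n_tubes` flies, runs one
#' session per batch (seeds `seed`, `seed + 1`, ...) and pools the results —
#' the in-silico analogue of running several monitors in parallel.
#'
#' @inheritParams simulate_session
#' @return A list with pooled `traces`, `zones` (column-bound, or `NULL`),
#'   `stim_sec` and the per-batch `sessions`.
#' @export
simulate_batches <- function(spec, cohort, seed = NULL,
                             geometry = beam_geometry(), ...) {
  n <- length(cohort)
  idx <- split(seq_len(n), ceiling(seq_len(n) / geometry$n_tubes))
  sessions <- lapply(seq_along(idx), function(b) {
    simulate_session(spec, cohort[idx[[b]]],
                     seed = if (is.null(seed)) NULL else seed + b - 1L,
                     geometry = geometry, ...)
  })
  traces <- unlist(lapply(sessions, `[[`, "traces"), recursive = FALSE)
  zones <- NULL
  if (!is.null(sessions[[1L]]$zones)) {
    zm <- do.call(cbind, lapply(sessions, `[[`, "zones"))
    colnames(zm) <- vapply(traces, `[[`, "", "fly_id")
    zones <- zone_assignment(zm, rule = attr(sessions[[1L]]$zones, "rule"),
                             feedback_start_s = attr(sessions[[1L]]$zones,
                                                     "feedback_start_s"))
  }
  list(traces = traces, zones = zones, stim_sec = sessions[[1L]]$stim_sec,
       sessions = sessions)
}
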