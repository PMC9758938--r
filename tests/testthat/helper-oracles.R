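# Independent brute-force oracles and fixture builders. Everything here is
# deliberately written as plain, slow, obvious R so it cannot share a defect
# with the implementation paths it checks.

# Random but physically valid activity trace: a bounded random walk over
# beams, counts = |step| + extra jitter (so the displacement invariant holds).
rand_trace <- function(duration = 400L, geometry = beam_geometry(),
                       fly_id = "rnd", zt0 = 0) {
  nb <- geometry$n_beams
  pos <- integer(duration)
  pos[1] <- sample.int(nb, 1L)
  steps <- sample(-2:2, duration - 1L, replace = TRUE)
  for (k in 2:duration) pos[k] <- min(nb, max(1L, pos[k - 1L] + steps[k - 1L]))
  extra <- rpois(duration, 0.4)
  counts <- c(rpois(1, 1), abs(diff(pos))) + extra
  activity_trace(fly_id, counts = counts, position = pos, zt0 = zt0,
                 geometry = geometry)
}

# Delta index by direct summation over explicit second windows.
bf_delta <- function(trace, t, w = 30L) {
  cnt <- trace$counts  # index s+1 holds second s
  pre <- cnt[(t - w + 1L):t]
  post <- cnt[(t + 2L):(t + w + 1L)]
  mean(post) - mean(pre)
}

# End occupancy by per-second membership counting.
bf_end_occupancy <- function(trace, end_beams = 2L, bin_s = 3600L,
                             start_s = 0L) {
  nb <- trace$geometry$n_beams
  pos <- trace$position[(start_s + 1L):trace$duration]
  n_bins <- length(pos) %/% bin_s
  t(vapply(seq_len(n_bins), function(b) {
    seg <- pos[((b - 1L) * bin_s + 1L):(b * bin_s)]
    c(a = 100 * sum(seg <= end_beams) / bin_s,
      b = 100 * sum(seg >= nb - end_beams + 1L) / bin_s)
  }, c(a = 0, b = 0)))
}

# Classical one-way ANOVA by explicit sums of squares.
bf_anova <- function(groups) {
  y <- unlist(groups)
  grand <- mean(y)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2, 1))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  dfb <- length(groups) - 1L
  dfw <- length(y) - length(groups)
  Fv <- (ssb / dfb) / (ssw / dfw)
  list(F = Fv, p = pf(Fv, dfb, dfw, lower.tail = FALSE))
}

# Hysteresis zone sequence recomputed from recorded positions.
bf_zones <- function(positions, boundary, init_zone) {
  z <- integer(length(positions))
  prev <- init_zone
  for (s in seq_along(positions)) {
    p <- positions[s]
    if (p < boundary) prev <- 1L else if (p > boundary) prev <- 2L
    z[s] <- prev
  }
  z
}

# Per-second colour for one tube, re-expanded from a stimulus log by a plain
# event walk.
bf_expand_colors <- function(log, tube, duration) {
  col <- rep("white", duration)
  cur <- "white"
  ev_i <- 1L
  df <- as.data.frame(log)
  for (s in 0:(duration - 1L)) {
    while (ev_i <= nrow(df) && df$time_ms[ev_i] <= s * 1000) {
      if (tube %in% df$tubes[[ev_i]]) cur <- df$color[ev_i]
      ev_i <- ev_i + 1L
    }
    col[s + 1L] <- cur
  }
  col
}

# Independent Monte-Carlo implementation of the startle cohort (identical
# responders, no drift, light phase): vectorised over flies, one loop over
# seconds, explicit reflection and cell-boundary counting.
mc_startle_counts <- function(n, params, duration, stim_sec,
                              geometry = beam_geometry()) {
  L <- geometry$tube_length
  nb <- geometry$n_beams
  bp <- geometry$beam_positions
  mids <- (bp[-1] + bp[-nb]) / 2
  cell <- function(x) findInterval(x, mids) + 1L
  # deterministic effective-gain schedule shared by all flies
  eb_t <- numeric(duration)
  load <- 0; last <- -1; eb <- 0
  stim <- as.integer(stim_sec)
  for (s in 0:(duration - 1L)) {
    if (s %in% stim) {
      if (last >= 0) load <- load * exp(-(s - last) / params$habit_recovery)
      eb <- params$startle_gain * params$habit_decay^load
      load <- load + 1; last <- s
    }
    eb_t[s + 1L] <- eb
    eb <- eb * exp(-1 / params$startle_tau)
  }
  x <- runif(n, 0, L)
  counts <- matrix(0L, duration, n)
  for (s in seq_len(duration)) {
    q <- min(1, max(0, params$p_move + eb_t[s]))
    move <- runif(n) < q
    xt <- x + rnorm(n, 0, params$step_scale)
    stopifnot(all(xt > -L & xt < 2 * L))  # single reflection is enough
    xr <- ifelse(xt < 0, -xt, ifelse(xt > L, 2 * L - xt, xt))
    old <- cell(x); new <- cell(xr)
    cross <- ifelse(xt < 0, (old - 1L) + (new - 1L),
                    ifelse(xt > L, (nb - old) + (nb - new), abs(new - old)))
    counts[s, move] <- pmax(1L, cross[move])
    x <- ifelse(move, xr, x)
  }
  counts
}

# Mean delta index of an mc_startle_counts() cohort, by direct summation.
mc_mean_delta <- function(counts, stim_sec, w = 30L) {
  deltas <- sapply(stim_sec, function(t) {
    pre <- colMeans(counts[(t - w + 1L):t, , drop = FALSE])
    post <- colMeans(counts[(t + 2L):(t + w + 1L), , drop = FALSE])
    post - pre
  })
  mean(deltas)
}

# Acceptance region for an observed rejection count under Binomial(n, p):
# central interval holding >= `conf` of the mass.
binom_band <- function(n, p = 0.05, conf = 0.99) {
  a <- (1 - conf) / 2
  c(qbinom(a, n, p), qbinom(1 - a, n, p)) / n
}
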