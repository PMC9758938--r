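test_that("an immobile fly produces all-zero counts and a constant position", {
  spec <- darkness_protocol()
  still <- fly_params(p_move = 0, startle_gain = 0)
  ses <- simulate_session(spec, list(still), seed = 1)
  tr <- ses$traces[[1L]]
  expect_true(all(tr$counts == 0L))
  expect_length(unique(tr$position), 1L)
})

test_that("movement frequency matches the binomial expectation", {
  spec <- protocol_spec("free-run", duration_s = 1e5)
  fly <- fly_params(p_move = 0.3, startle_gain = 0)
  ses <- simulate_session(spec, list(fly), seed = 42)
  frac <- mean(ses$traces[[1L]]$counts > 0L)
  tol <- 3 * sqrt(0.3 * 0.7 / 1e5)
  expect_lt(abs(frac - 0.3), tol)
})

test_that("a forced displacement from beam 3 to beam 7 scores 4 crossings", {
  geom <- beam_geometry()
  # deterministic step: negligible noise, drift = the beam-3 -> beam-7 gap,
  # delivered through the innate blue-aversion term (fly in left zone)
  gap <- geom$beam_positions[7] - geom$beam_positions[3]
  p <- fly_params(p_move = 1, step_scale = 1e-9, startle_gain = 0,
                  blue_aversion = gap)
  st <- fly_state(x = geom$beam_positions[3])
  out <- step_fly(st, p, light = "blue", geometry = geom)
  expect_identical(out$crossings, 4L)
  expect_identical(out$beam_position, 7L)
})

test_that("every movement second scores at least one crossing", {
  spec <- protocol_spec("free-run", duration_s = 5000)
  fly <- fly_params(p_move = 0.5, startle_gain = 0, step_scale = 0.5)
  ses <- simulate_session(spec, list(fly), seed = 9)
  cnt <- ses$traces[[1L]]$counts
  expect_true(all(cnt %in% c(0L, cnt[cnt > 0L])))
  expect_gte(min(cnt[cnt > 0L]), 1L)
  # tiny steps still interrupt the local beam: fraction of moving seconds
  # matches p_move even when most steps stay within one cell
  expect_lt(abs(mean(cnt > 0L) - 0.5), 3 * sqrt(0.25 / 5000))
})

test_that("the habituation kernel desensitises faster at short ITIs", {
  p <- fly_params(startle_gain = 0.4, habit_decay = 0.7, habit_recovery = 600)
  # first stimulus of a responder carries the full gain
  st <- apply_lights_off(fly_state(x = 0), p, t_s = 100)
  expect_identical(st$effective_beta, 0.4)
  # kappa = 1: no habituation at any ITI
  p1 <- fly_params(startle_gain = 0.4, habit_decay = 1)
  eb1 <- effective_startle(p1, seq(0, by = 60, length.out = 24))
  expect_true(all(eb1 == 0.4))
  # kappa < 1: 1-min trains end up weaker than 5-min trains
  eb_fast <- effective_startle(p, seq(0, by = 60, length.out = 24))
  eb_slow <- effective_startle(p, seq(0, by = 300, length.out = 4))
  expect_lt(mean(eb_fast), mean(eb_slow))
  # and the load relaxes: far-apart stimuli recover toward the full gain
  eb_sparse <- effective_startle(p, seq(0, by = 6000, length.out = 4))
  expect_gt(min(eb_sparse), 0.39)
})

test_that("the session engine applies the same startle kernel as the recursion", {
  spec <- darkness_protocol(iti_s = 60L, n_trials = 20L, habituation_s = 120L)
  p <- fly_params(startle_gain = 0.35, habit_decay = 0.8, habit_recovery = 450)
  geom <- beam_geometry()
  set.seed(3)
  res <- photobeam:::sim_fly_cpp(
    x0 = 10, duration = spec$duration_s, beam_pos = geom$beam_positions,
    tube_len = geom$tube_length, par = photobeam:::cpp_params(p),
    dark_phase = logical(), stim_sec = stimulus_seconds(spec),
    color_ol = integer(), feedback = FALSE, feedback_start = 0L,
    boundary_beam = 9L, left_color_pre = 2L, right_color_pre = 3L,
    left_color_post = 3L, right_color_post = 2L, swap_at_s = -1L,
    state0 = list())
  expect_equal(res$eb_at_stim,
               effective_startle(p, stimulus_seconds(spec)), tolerance = 1e-12)
})

test_that("sessions are bit-reproducible under a fixed seed", {
  spec <- darkness_protocol(iti_s = 300L, n_trials = 6L, habituation_s = 600L)
  coh <- make_cohort(fly_params(), 6, heterogeneity = TRUE, seed = 11)
  a <- simulate_session(spec, coh, seed = 7)
  b <- simulate_session(spec, coh, seed = 7)
  expect_identical(lapply(a$traces, `[[`, "counts"),
                   lapply(b$traces, `[[`, "counts"))
  expect_identical(lapply(a$traces, `[[`, "position"),
                   lapply(b$traces, `[[`, "position"))
  c <- simulate_session(spec, coh, seed = 8)
  expect_false(identical(lapply(a$traces, `[[`, "counts"),
                         lapply(c$traces, `[[`, "counts")))
})

test_that("the displacement invariant holds for every simulated trace", {
  specs <- list(
    darkness_protocol(iti_s = 120L, n_trials = 10L, habituation_s = 120L),
    ld_protocol(hours = 1.5),
    place_protocol(conditioning_h = 0.4, habituation_s = 180L)
  )
  params <- list(
    fly_params(),
    fly_params(p_move = 0.6, step_scale = 9, food_bias = c(0.2, 0.3),
               ethanol_dark_boost = 0.2),
    fly_params(p_move = 0.4, blue_aversion = 0.8, learn_rate = 5e-4)
  )
  for (i in seq_along(specs)) {
    ses <- simulate_session(specs[[i]], make_cohort(params[[i]], 4), seed = 20 + i)
    for (tr in ses$traces) {
      expect_length(displacement_violations <- photobeam:::displacement_violations(tr), 0)
      expect_identical(length(tr$counts), length(tr$position))
    }
  }
})

test_that("cohort draws follow the responder mixture and are seed-stable", {
  tpl <- fly_params(startle_gain = 0.4,
                    startle_sign_mix = c(none = 0.59, negative = 0.08,
                                         positive = 0.33))
  coh <- make_cohort(tpl, 1000, heterogeneity = TRUE, seed = 31)
  cls <- attr(coh, "responder_class")
  frac <- table(factor(cls, c("none", "negative", "positive"))) / 1000
  for (nm in names(frac)) {
    p0 <- tpl$startle_sign_mix[nm]
    expect_lt(abs(frac[[nm]] - p0), 3 * sqrt(p0 * (1 - p0) / 1000) + 1e-9)
  }
  gains <- vapply(coh, `[[`, 1, "startle_gain")
  expect_true(all(gains[cls == "none"] == 0))
  expect_true(all(gains[cls == "negative"] < 0))
  expect_true(all(gains[cls == "positive"] == 0.4))
  # identical under the same seed, identical copies with heterogeneity off
  expect_identical(make_cohort(tpl, 1000, heterogeneity = TRUE, seed = 31), coh)
  flat <- make_cohort(tpl, 5)
  expect_identical(unique(vapply(flat, `[[`, 1, "startle_gain")), 0.4)
})

test_that("LD phase modulates activity by the light/dark factor ratio", {
  spec <- ld_protocol(hours = 48)
  fly <- fly_params(p_move = 0.3, startle_gain = 0, light_factor = 1,
                    dark_factor = 0.5)
  ses <- simulate_session(spec, list(fly), seed = 13)
  cnt <- ses$traces[[1L]]$counts
  zt <- zt_at(0:(spec$duration_s - 1L), zt0 = 0)
  ratio <- mean(cnt[zt < 12]) / mean(cnt[zt >= 12])
  expect_lt(abs(ratio - 2), 0.15)
})

test_that("oversized cohorts are rejected and batching restores them", {
  spec <- darkness_protocol(iti_s = 60L, n_trials = 3L, habituation_s = 60L)
  coh <- make_cohort(fly_params(), 20)
  expect_error(simulate_session(spec, coh, seed = 1), "tube slots")
  res <- simulate_batches(spec, coh, seed = 1)
  expect_length(res$traces, 20L)
  expect_identical(vapply(res$traces, `[[`, "", "fly_id"),
                   vapply(coh, `[[`, "", "fly_id"))
})
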