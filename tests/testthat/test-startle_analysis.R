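# A trace with prescribed counts (positions immobile so no displacement
# noise interferes with the counts under test).
flat_trace <- function(counts, fly_id = "f") {
  suppressWarnings(
    activity_trace(fly_id, counts = counts, position = rep(5L, length(counts)),
                   check_displacement = FALSE))
}

test_that("delta index is post-mean minus pre-mean, stimulus second excluded", {
  # constant 2/s before, 3/s after, and an outlier at the stimulus second
  # that must be ignored
  cnt <- c(rep(2L, 40), 99L, rep(3L, 40))
  tr <- flat_trace(cnt)
  rec <- delta_index(tr, stim_times_s = 40L)
  expect_identical(nrow(rec), 1L)
  expect_equal(rec$pre_mean, 2)
  expect_equal(rec$post_mean, 3)
  expect_equal(rec$delta, 1)

  z <- flat_trace(rep(0L, 200))
  recz <- delta_index(z, c(50L, 100L, 150L))
  expect_equal(recz$delta, c(0, 0, 0))
})

test_that("delta index equals brute-force window resummation", {
  set.seed(55)
  for (rep in 1:10) {
    tr <- rand_trace(500L)
    stim <- sort(sample(40:460, 4))
    rec <- delta_index(tr, stim)
    for (i in seq_along(stim)) {
      expect_equal(rec$delta[i], bf_delta(tr, stim[i]), tolerance = 1e-12)
    }
  }
})

test_that("stimuli too close to the session edge are skipped with a warning", {
  tr <- flat_trace(rep(1L, 100))
  expect_warning(rec <- delta_index(tr, c(10L, 50L)), "session edge")
  expect_identical(nrow(rec), 1L)
  expect_identical(rec$trial, 2L)  # original trial index preserved
})

test_that("delta index is linear in the counts", {
  set.seed(60)
  tr <- rand_trace(400L)
  stim <- c(60L, 200L, 330L)
  tr3 <- flat_trace(3L * tr$counts)
  expect_equal(delta_index(tr3, stim)$delta, 3 * delta_index(tr, stim)$delta,
               tolerance = 1e-12)
})

test_that("dead-fly exclusion looks only at the scored windows", {
  stim <- c(100L, 300L)
  dead <- flat_trace(rep(0L, 400), "dead")
  # active only between trials: all pre/post windows still zero -> dead
  sneaky_cnt <- rep(0L, 400); sneaky_cnt[200] <- 50L
  sneaky <- flat_trace(sneaky_cnt, "sneaky")
  # a single count inside one window rescues the fly
  alive_cnt <- rep(0L, 400); alive_cnt[310] <- 1L
  alive <- flat_trace(alive_cnt, "alive")
  res <- exclude_dead(list(dead, sneaky, alive), stim)
  expect_identical(res$excluded, c("dead", "sneaky"))
  expect_identical(vapply(res$kept, `[[`, "", "fly_id"), "alive")
})

test_that("responder classification partitions fly-by-trial cells exactly", {
  rec <- data.frame(delta = c(1, -1, 0))
  brk <- classify_responses(rec)
  expect_equal(brk$fraction_increase, 1 / 3)
  expect_equal(brk$fraction_decrease, 1 / 3)
  expect_equal(brk$fraction_no_change, 1 / 3)
  expect_equal(brk$fraction_increase + brk$fraction_decrease +
                 brk$fraction_no_change, 1)
  brk0 <- classify_responses(data.frame(delta = rep(0, 7)))
  expect_equal(brk0$fraction_no_change, 1)
  expect_equal(brk0$fraction_increase, 0)
})

test_that("epoch averaging bins 5-min and 1-min ITI sessions as 4x6 and 4x30", {
  for (cfg in list(list(iti = 300L, per_epoch = 6L),
                   list(iti = 60L, per_epoch = 30L))) {
    spec <- darkness_protocol(iti_s = cfg$iti, n_trials = 7200L %/% cfg$iti)
    ses <- simulate_session(spec, make_cohort(fly_params(), 3), seed = 77)
    rec <- delta_records(ses$traces, ses$stim_sec)
    em <- epoch_average(rec, epoch_len_s = 1800L)
    expect_identical(em$epoch, 0:3)
    expect_identical(em$n, rep(3L * cfg$per_epoch, 4))  # pooled over 3 flies
    by_fly <- epoch_average(rec, epoch_len_s = 1800L, by_fly = TRUE)
    expect_identical(unique(by_fly$n), cfg$per_epoch)
    # conservation: epoch means recombine to the grand total
    expect_equal(sum(em$n * em$mean_delta), sum(rec$delta), tolerance = 1e-9)
  }
})

test_that("constant deltas give constant epoch means and empty epochs flag", {
  rec <- data.frame(fly_id = "f", trial = 1:6, stim_s = seq(0, 1500, by = 300),
                    pre_mean = 0, post_mean = 0.5, delta = 0.5)
  em <- epoch_average(rec, epoch_len_s = 600L)
  expect_true(all(em$mean_delta == 0.5))
  expect_warning(em2 <- epoch_average(rec, epoch_len_s = 600L,
                                      session_len_s = 3000L),
                 "empty epoch")
  expect_identical(em2$epoch, 0:4)
  expect_true(em2$empty[5L])
  expect_true(is.na(em2$mean_delta[5L]))
})

test_that("baseline metrics recover activity and speed from the trace", {
  still <- flat_trace(rep(0L, 1500))
  bm <- baseline_metrics(still, t_end = 1400L)
  expect_equal(bm$mean_counts, 0)
  expect_equal(bm$mean_speed, 0)

  # alternating beams 5 <-> 6 every second: 1 count/s and 1 beam/s
  n <- 1500L
  pos <- rep(c(5L, 6L), length.out = n)
  alt <- activity_trace("alt", counts = rep(1L, n), position = pos)
  bm2 <- baseline_metrics(alt, t_end = 1300L)
  expect_equal(bm2$mean_counts, 1)
  expect_equal(bm2$mean_speed, 1)

  # brute-force agreement on a random trace
  set.seed(91)
  tr <- rand_trace(1500L)
  bm3 <- baseline_metrics(tr, t_end = 1450L)
  idx <- 251:1450
  expect_equal(bm3$mean_counts, mean(tr$counts[idx]), tolerance = 1e-12)
  expect_equal(bm3$mean_speed, mean(abs(diff(tr$position[idx]))),
               tolerance = 1e-12)

  expect_warning(bm4 <- baseline_metrics(tr, t_end = 600L), "truncated")
  expect_identical(bm4$n_seconds, 600L)
})

test_that("pre/post activity correlate across heterogeneously active flies", {
  spec <- darkness_protocol(iti_s = 300L, n_trials = 6L, habituation_s = 600L)
  tpl <- fly_params(p_move = 0.3, startle_gain = 0.3)
  coh <- make_cohort(tpl, 48, heterogeneity = list(p_move_sd = 0.12), seed = 17)
  res <- simulate_batches(spec, coh, seed = 18)
  rec <- delta_records(res$traces, res$stim_sec)
  agg_pre <- tapply(rec$pre_mean, rec$fly_id, mean)
  agg_post <- tapply(rec$post_mean, rec$fly_id, mean)
  ct <- pearson(as.numeric(agg_pre), as.numeric(agg_post))
  expect_gt(ct$r, 0)
  expect_lt(ct$p, 0.05)
})
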