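test_that("sigmoid fitting recovers symmetric and noiseless parameters", {
  # symmetric inflection at token 4
  f <- fit_sigmoid(c(0, 0, 0, .5, 1, 1, 1))
  expect_true(f$converged)
  expect_equal(f$beta0, 4, tolerance = 1e-3)
  # noiseless inverse problem: recovery to 1e-4
  truth <- logistic_p(1:7, 4.2, 2.5)
  f2 <- fit_sigmoid(truth)
  expect_equal(f2$beta0, 4.2, tolerance = 1e-4)
  expect_equal(f2$beta1, 2.5, tolerance = 1e-4)
  # model identity: P(beta0) = 0.5 for any converged fit
  for (fit in list(f, f2))
    expect_lt(abs(predict(fit, fit$beta0) - 0.5), 1e-9)
})

test_that("degenerate and decreasing proportion vectors are flagged", {
  flat <- fit_sigmoid(rep(0.5, 7))
  expect_false(flat$converged)
  expect_equal(flat$beta1, 0)
  expect_warning(fit_sigmoid(rev(logistic_p(1:7, 4, 2))), "decrease")
  expect_error(fit_sigmoid(0.5), "at least 2")
})

test_that("token re-indexing shifts the boundary and leaves the slope", {
  p <- logistic_p(1:7, 3.7, 1.9)
  base <- fit_sigmoid(p, tokens = 1:7)
  shifted <- fit_sigmoid(p, tokens = 1:7 + 0.5)
  expect_equal(shifted$beta0 - base$beta0, 0.5, tolerance = 1e-4)
  expect_equal(shifted$beta1, base$beta1, tolerance = 1e-4)
})

test_that("Monte-Carlo recovery of the boundary from Bernoulli data", {
  set.seed(11)
  est <- replicate(500, {
    p_hat <- vapply(1:7, function(tok)
      mean(rbinom(30, 1, logistic_p(tok, 3.6, 1.8))), numeric(1))
    fit_sigmoid(p_hat)$beta0
  })
  expect_lt(abs(median(est) - 3.6), 0.1)
})

test_that("boundary_shift is a signed difference with magnitude", {
  f1 <- fit_sigmoid(logistic_p(1:7, 4.8, 2))
  f2 <- fit_sigmoid(logistic_p(1:7, 4.0, 2))
  bs <- boundary_shift(f1, f2)
  expect_equal(bs$delta, 0.8, tolerance = 1e-3)
  expect_equal(bs$magnitude, 0.8, tolerance = 1e-3)
  expect_equal(boundary_shift(f2, f2)$delta, 0)
  expect_true(bs$converged)
})

test_that("RT filtering applies the closed window and conserves counts", {
  f <- filter_rts(c(100, 250, 900, 2500, 3000))
  expect_equal(f$kept, c(250, 900, 2500))
  expect_equal(f$n_excluded, 2)
  expect_equal(filter_rts(numeric(0)),
               list(kept = numeric(0), n_excluded = 0L))
  inrange <- c(300, 1200, 2400)
  expect_equal(filter_rts(inrange)$kept, inrange)
  for (rts in list(runif(50, 0, 4000), c(NA, 500), numeric(0))) {
    f2 <- filter_rts(rts)
    expect_equal(length(f2$kept) + f2$n_excluded, length(rts))
  }
})

test_that("median RT per token follows the generative inverted V", {
  tr <- data.table::data.table(token = rep(1:3, each = 3),
                               rt_ms = c(800, 900, 1000, 500, 600, 700,
                                         300, 400, 3000))
  prof <- median_rt_per_token(tr)
  expect_equal(prof$median_rt, c(900, 600, 350))
  expect_equal(prof$n_excluded, c(0L, 0L, 1L))
  # simulated observer: boundary token slower than the endpoint mean
  log <- simulate_experiment(small_design(10L),
                             quiet_observer(rt_sigma = 0.2),
                             n_subjects = 3, seed = 8,
                             include_trajectories = FALSE)
  prof2 <- median_rt_per_token(trials_summary(log))
  expect_gt(prof2$median_rt[4], mean(prof2$median_rt[c(1, 7)]))
})

test_that("fit_psychometrics pools serial directions and fits all cells", {
  log <- small_log(n_subjects = 2, include_trajectories = FALSE)
  fits <- fit_psychometrics(log)
  expect_setequal(unique(fits$condition),
                  c("random", "serial", "forward", "reverse"))
  # 2 subjects x 2 snr x 4 condition rows
  expect_equal(nrow(fits), 2 * 2 * 4)
  serial_n <- fits[condition == "serial"]$n_trials
  expect_true(all(serial_n == 2 * fits[condition == "forward"]$n_trials))
})

test_that("split-half reliability is 1 for duplicated halves and high for
           stable observers", {
  log <- small_log(n_subjects = 4, trials_per_token = 6L,
                   include_trajectories = FALSE)
  # duplicated halves: second half replaced by a copy of the first
  trials <- trials_summary(log)
  first <- trials[, .SD[trial_index <= max(trial_index) / 2],
                  by = .(subject_id, block_id)]
  dup <- data.table::copy(first)[, trial_index := trial_index +
                                   max(trial_index), by = .(subject_id, block_id)]
  both <- rbind(first, dup)
  both[, c("sample_t_ms", "sample_x", "sample_y") := NA_real_]
  sh <- split_half_reliability(both)
  expect_equal(sh$r, 1, tolerance = 1e-12)
  # stable simulated observers: strong but imperfect correlation
  log2 <- simulate_experiment(design_spec(trials_per_token = 15L),
                              observer_population(warp_sd_between = 0.75),
                              n_subjects = 12, seed = 13,
                              include_trajectories = FALSE)
  sh2 <- split_half_reliability(log2)
  expect_gt(sh2$r, 0.6)
})
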