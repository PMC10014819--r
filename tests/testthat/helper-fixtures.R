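# shared fixtures: small designs and observers keep unit tests fast;
# full-size runs live only in the acceptance tests

small_design <- function(trials_per_token = 5L)
  design_spec(trials_per_token = trials_per_token)

quiet_observer <- function(...) {
  # deterministic-trajectory observer: no jitter, no RT noise
  args <- utils::modifyList(list(rt_sigma = 0, traj_jitter = 0), list(...))
  do.call(observer_params, args)
}

small_log <- function(n_subjects = 3, trials_per_token = 5L, seed = 42,
                      include_trajectories = TRUE, population = NULL) {
  simulate_experiment(small_design(trials_per_token),
                      population %||% observer_population(),
                      n_subjects = n_subjects, seed = seed,
                      include_trajectories = include_trajectories)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent fine-grid oracle for the area between a path and its chord:
# densify the polyline, then integrate |signed deviation| / signed deviation
# of the densified path against the chord by simple Riemann summation
auc_oracle <- function(x, y, n_dense = 20000) {
  t0 <- seq_along(x)
  td <- seq(1, length(x), length.out = n_dense)
  xd <- approx(t0, x, td)$y
  yd <- approx(t0, y, td)$y
  chord <- c(xd[n_dense] - xd[1], yd[n_dense] - yd[1])
  u <- chord / sqrt(sum(chord^2))
  along <- (xd - xd[1]) * u[1] + (yd - yd[1]) * u[2]
  dev <- (xd - xd[1]) * u[2] - (yd - yd[1]) * u[1]
  mid <- (dev[-1] + dev[-n_dense]) / 2
  # dev is positive to the right of the chord; bowing left counts positive
  list(signed = -sum(mid * diff(along)),
       absolute = sum(abs(mid) * diff(along)))
}

# smooth random trajectory from bottom-center to the right target
random_smooth_track <- function(n = 101, wiggle = 0.15) {
  t <- seq(0, 1, length.out = n)
  x <- 0.5 + (0.925 - 0.5) * t + wiggle * sin(pi * t) * runif(1, -1, 1)
  y <- 0.125 + (0.925 - 0.125) * t + wiggle * sin(2 * pi * t) * runif(1, -1, 1)
  list(x = x, y = y)
}
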