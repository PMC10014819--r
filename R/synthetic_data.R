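#' Generative parameters of a synthetic listener
#'
#' The observer identifies token `x` as the /a/ endpoint with probability
#' `P(a) = 1 / (1 + exp(-beta1 * (x - b_eff)))`. Under random order the
#' effective boundary `b_eff` equals `beta0`; under serial order it is
#' displaced by `warp` in the direction of presentation (`beta0 + warp` on
#' forward passes, `beta0 - warp` on reverse passes), so a positive `warp`
#' makes the percept lag the stimulus change (hysteresis).
#'
#' Reaction times follow a deterministic median structure -- a base RT plus a
#' Gaussian ambiguity bump peaking at the effective boundary, minus constant
#' facilitation terms for serial order and for noise -- multiplied by
#' lognormal trial noise.
#'
#' Cursor trajectories are a two-phase kinematic sketch: a vertical
#' "hesitation" rise whose duration grows with category ambiguity
#' `h = 1 - |2 p_a - 1|` plus a baseline stimulus uncertainty (nonzero in
#' noise), followed by smooth exponential attraction toward the chosen
#' response box. Under serial order in noise the hesitation is shrunk by
#' `curvature_noise_reduction_serial`, producing straighter, more directed
#' tracks.
#'
#' @param beta0 nominal category boundary, token units.
#' @param beta1 identification slope, per token (> 0).
#' @param warp signed boundary displacement under serial order, token units.
#' @param rt_base baseline median RT, ms.
#' @param rt_ambiguity_gain peak RT increase at the boundary, ms.
#' @param rt_serial_facilitation RT speedup under serial order, ms.
#' @param rt_noise_speedup RT speedup in noise, ms.
#' @param rt_sigma lognormal dispersion of trial RTs.
#' @param traj_attraction attraction rate toward the chosen target, 1/s.
#' @param traj_curvature_gain maps ambiguity to the fraction of the trial
#'   spent in the vertical hesitation phase.
#' @param traj_uncertainty_noise baseline ambiguity added in noise blocks
#'   (stimulus uncertainty present even for endpoint tokens).
#' @param curvature_noise_reduction_serial fractional shrinkage of hesitation
#'   under serial order in noise, in `[0, 1]`.
#' @param traj_jitter SD of per-sample positional jitter, normalized screen
#'   units.
#' @return an object of class `observer_params`.
#' @export
observer_params <- function(beta0 = 4, beta1 = 2, warp = 0.5,
                            rt_base = 650, rt_ambiguity_gain = 300,
                            rt_serial_facilitation = 75,
                            rt_noise_speedup = 30, rt_sigma = 0.25,
                            traj_attraction = 8, traj_curvature_gain = 0.45,
                            traj_uncertainty_noise = 0.5,
                            curvature_noise_reduction_serial = 0.5,
                            traj_jitter = 0.01) {
  stopifnot(beta1 > 0, rt_base >= 0, rt_ambiguity_gain >= 0,
            rt_serial_facilitation >= 0, rt_noise_speedup >= 0,
            rt_sigma >= 0,
            curvature_noise_reduction_serial >= 0,
            curvature_noise_reduction_serial <= 1)
  structure(as.list(environment()), class = "observer_params")
}

#' Population distribution over observers
#'
#' Subject-level parameters are drawn independently: `beta0 ~ N(beta0_mean,
#' beta0_sd)`, `beta1 ~ N(beta1_mean, beta1_sd)` truncated below at
#' `beta1_min`, and the signed warp `~ N(warp_mean, warp_sd_between)` --
#' fixed within subject, capturing the large between-listener variability
#' and high within-listener repeatability of boundary shifts. A subject's
#' serial-in-noise curvature reduction is coupled to the magnitude of their
#' warp through `warp_curvature_coupling`, so listeners who warp more also
#' straighten their tracks more (the behavioral-trajectory link the
#' correlation analysis probes).
#'
#' @param beta0_mean,beta0_sd population mean/SD of the boundary.
#' @param beta1_mean,beta1_sd,beta1_min population distribution of the slope.
#' @param warp_mean,warp_sd_between population distribution of the warp.
#' @param warp_curvature_coupling added curvature reduction per token unit of
#'   `|warp| - |warp_mean|`.
#' @param ... fixed observer parameters forwarded to [observer_params()].
#' @return an object of class `observer_population`.
#' @export
observer_population <- function(beta0_mean = 4, beta0_sd = 0.5,
                                beta1_mean = 2, beta1_sd = 0.4,
                                beta1_min = 0.5,
                                warp_mean = 0.5, warp_sd_between = 0.75,
                                warp_curvature_coupling = 0.3, ...) {
  structure(list(beta0_mean = beta0_mean, beta0_sd = beta0_sd,
                 beta1_mean = beta1_mean, beta1_sd = beta1_sd,
                 beta1_min = beta1_min, warp_mean = warp_mean,
                 warp_sd_between = warp_sd_between,
                 warp_curvature_coupling = warp_curvature_coupling,
                 fixed = list(...)),
            class = "observer_population")
}

#' Draw subject-level observers from a population
#'
#' @param population an [observer_population()].
#' @param n_subjects number of subjects.
#' @param seed integer seed.
#' @return a list of [observer_params()].
#' @export
draw_observers <- function(population, n_subjects, seed = 1L) {
  p <- population
  with_seed(seed, {
    lapply(seq_len(n_subjects), function(i) {
      beta0 <- rnorm(1, p$beta0_mean, p$beta0_sd)
      beta1 <- max(p$beta1_min, rnorm(1, p$beta1_mean, p$beta1_sd))
      warp <- rnorm(1, p$warp_mean, p$warp_sd_between)
      args <- c(list(beta0 = beta0, beta1 = beta1, warp = warp), p$fixed)
      obs <- do.call(observer_params, args)
      extra <- p$warp_curvature_coupling * (abs(warp) - abs(p$warp_mean))
      obs$curvature_noise_reduction_serial <- min(0.95, max(0.05,
        obs$curvature_noise_reduction_serial + extra))
      obs
    })
  })
}

order_direction <- function(order) {
  switch(order, forward = 1, reverse = -1, random = 0,
         stop("unknown order '", order, "'"))
}

effective_boundary <- function(params, order) {
  params$beta0 + params$warp * order_direction(order)
}

#' Simulate one identification response
#'
#' `P(a)` is the logistic of `beta1 * (token - b_eff)` where the effective
#' boundary `b_eff` is the warped boundary under serial order (see
#' [observer_params()]); the response is a Bernoulli draw from the current
#' RNG stream.
#'
#' @param params an [observer_params()].
#' @param token token index.
#' @param order `"random"`, `"forward"`, or `"reverse"`.
#' @param snr masking condition label (unused by the response model).
#' @return list with `response` (`"u"` or `"a"`) and `p_a`.
#' @export
simulate_response <- function(params, token, order, snr = "clean") {
  p_a <- stats::plogis(params$beta1 * (token - effective_boundary(params, order)))
  list(response = if (rbinom(1, 1, p_a) == 1) "a" else "u", p_a = p_a)
}

#' Deterministic RT structure (median RT)
#'
#' @param params an [observer_params()].
#' @param token token index.
#' @param order,snr condition labels.
#' @return median RT in ms before trial noise.
#' @export
rt_structure <- function(params, token, order, snr) {
  b_eff <- effective_boundary(params, order)
  serial <- order %in% c("forward", "reverse")
  params$rt_base +
    params$rt_ambiguity_gain * exp(-params$beta1^2 * (token - b_eff)^2 / 2) -
    params$rt_serial_facilitation * serial -
    params$rt_noise_speedup * (snr == "noise")
}

#' Simulate one reaction time
#'
#' The deterministic median structure from [rt_structure()] multiplied by
#' `lognormal(0, rt_sigma)` trial noise, floored at 1 ms.
#'
#' @inheritParams rt_structure
#' @return RT in ms.
#' @export
simulate_rt <- function(params, token, order, snr) {
  pmax(1, rt_structure(params, token, order, snr) *
         rlnorm(1, 0, params$rt_sigma))
}

# response-box geometry (normalized screen units; y grows upward)
screen_geometry <- function() {
  list(start = c(0.5, 0.125),           # start threshold at 1/8 screen height
       box_size = 0.15,                 # 15% x 15% corner boxes
       left = c(0.075, 0.925), right = c(0.925, 0.925))
}

#' Simulate one cursor trajectory
#'
#' 100 Hz path from bottom-center (the start threshold at 1/8 screen height)
#' to the chosen response box: a vertical hesitation rise whose duration is
#' `traj_curvature_gain * (h + u)` of the trial (ambiguity
#' `h = 1 - |2 p_a - 1|`, baseline uncertainty `u` in noise), shrunk by
#' `curvature_noise_reduction_serial` under serial order in noise, followed
#' by exponential attraction toward the box center with rate
#' `traj_attraction` per 0.8 s of normalized trial time (quick decisions move
#' proportionally faster, so the path's shape over normalized time is
#' duration-invariant), plus per-sample jitter. The final sample is clamped
#' into the response box (hover terminates the trial). Total duration equals
#' the trial RT.
#'
#' @param params an [observer_params()].
#' @param p_a identification probability of the trial.
#' @param response `"u"` (left target) or `"a"` (right target).
#' @param rt_ms trial duration, ms (must cover at least two samples).
#' @param order,snr condition labels.
#' @return a data.table with `t_ms`, `x`, `y` on a 10 ms grid.
#' @export
simulate_trajectory <- function(params, p_a, response, rt_ms,
                                order = "random", snr = "clean") {
  n <- round(rt_ms / 10)
  if (n < 2) stop("simulate_trajectory: rt too short for two samples")
  geom <- screen_geometry()
  target <- if (response == "a") geom$right else geom$left
  h <- 1 - abs(2 * p_a - 1)
  u <- if (snr == "noise") params$traj_uncertainty_noise else 0
  shrink <- if (order %in% c("forward", "reverse") && snr == "noise")
    1 - params$curvature_noise_reduction_serial else 1
  rise_frac <- min(0.85, params$traj_curvature_gain * (h + u) * shrink)
  n1 <- floor(rise_frac * n)
  x <- numeric(n); y <- numeric(n)
  pos <- geom$start
  y_turn <- geom$start[2] + rise_frac * (target[2] - geom$start[2])
  # attraction acts on normalized trial time (0.8 s reference duration)
  g <- 1 - exp(-params$traj_attraction * 0.8 / n)
  for (i in seq_len(n)) {
    if (i <= n1) {
      pos <- c(geom$start[1],
               geom$start[2] + (i / max(1, n1)) * (y_turn - geom$start[2]))
    } else {
      pos <- pos + g * (target - pos)
    }
    if (params$traj_jitter > 0) pos <- pos + rnorm(2, 0, params$traj_jitter)
    pos <- pmin(1, pmax(0, pos))
    x[i] <- pos[1]; y[i] <- pos[2]
  }
  half <- geom$box_size
  x[n] <- min(max(x[n], target[1] - half / 2), target[1] + half / 2)
  y[n] <- min(max(y[n], target[2] - half / 2), target[2] + half / 2)
  data.table::data.table(t_ms = seq(0, by = 10, length.out = n), x = x, y = y)
}

#' Simulate a complete experiment
#'
#' Generates a full balanced long-format trial log: for each subject, one
#' observer is drawn from the population (warp fixed within subject), the six
#' blocks are run in a seeded random order, and every trial yields a
#' response, an RT and (optionally) a 100 Hz trajectory. All randomness
#' derives from `seed` through per-subject substreams, so logs are exactly
#' reproducible and independent of `n_subjects` ordering.
#'
#' @param design a [design_spec()].
#' @param population an [observer_population()] (or a single
#'   [observer_params()] used for every subject).
#' @param n_subjects number of subjects.
#' @param seed root integer seed.
#' @param include_trajectories generate cursor samples (set `FALSE` for
#'   response-only simulations, which are much faster).
#' @return a trial-log data.table in the [read_trial_log()] schema; the drawn
#'   observers are attached as attribute `"observers"`.
#' @export
simulate_experiment <- function(design, population = observer_population(),
                                n_subjects = 29L, seed = 1L,
                                include_trajectories = TRUE) {
  stopifnot(n_subjects >= 1)
  seeds <- derive_seeds(seed, n_subjects + 1L)
  observers <- if (inherits(population, "observer_params"))
    rep(list(population), n_subjects)
  else draw_observers(population, n_subjects, seed = seeds[n_subjects + 1L])
  subject_logs <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    subject_logs[[s]] <- with_seed(seeds[s], {
      simulate_subject(design, observers[[s]], sprintf("S%02d", s),
                       include_trajectories)
    })
  }
  log <- data.table::rbindlist(subject_logs)
  data.table::setkeyv(log, c("subject_id", "block_id", "trial_index"))
  attr(log, "observers") <- observers
  log[]
}

# one subject: block order, trials, trajectories; uses the current RNG stream
simulate_subject <- function(design, obs, subject_id, include_trajectories) {
  plan <- block_plan(design, seed = sample.int(.Machine$integer.max - 1L, 1))
  block_logs <- vector("list", nrow(plan))
  for (b in seq_len(nrow(plan))) {
    ord <- plan$order[b]; snr <- plan$snr[b]
    tokens <- make_trial_sequence(design, ord,
                                  seed = sample.int(.Machine$integer.max - 1L, 1))
    nt <- length(tokens)
    p_a <- stats::plogis(obs$beta1 * (tokens - effective_boundary(obs, ord)))
    resp <- ifelse(rbinom(nt, 1, p_a) == 1, "a", "u")
    rt <- pmax(1, rt_structure(obs, tokens, ord, snr) * rlnorm(nt, 0, obs$rt_sigma))
    rt <- round(rt / 10) * 10          # RT logged on the 10 ms sample grid
    rt <- pmax(20, rt)
    if (include_trajectories) {
      trajs <- vector("list", nt)
      for (i in seq_len(nt))
        trajs[[i]] <- simulate_trajectory(obs, p_a[i], resp[i], rt[i], ord, snr)
      lens <- vapply(trajs, nrow, integer(1))
      block_logs[[b]] <- data.table::data.table(
        subject_id = subject_id, block_id = plan$block_id[b],
        trial_index = rep(seq_len(nt), lens), token = rep(tokens, lens),
        order = ord, snr = snr, response = rep(resp, lens),
        rt_ms = rep(rt, lens),
        sample_t_ms = unlist(lapply(trajs, `[[`, "t_ms")),
        sample_x = unlist(lapply(trajs, `[[`, "x")),
        sample_y = unlist(lapply(trajs, `[[`, "y")))
    } else {
      block_logs[[b]] <- data.table::data.table(
        subject_id = subject_id, block_id = plan$block_id[b],
        trial_index = seq_len(nt), token = tokens, order = ord, snr = snr,
        response = resp, rt_ms = rt, sample_t_ms = NA_real_,
        sample_x = NA_real_, sample_y = NA_real_)
    }
  }
  data.table::rbindlist(block_logs)
}
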