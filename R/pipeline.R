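#' Build a run configuration
#'
#' Collects everything a full reproducible run needs: continuum and design
#' parameters, observer-population parameters, sample size, analysis options
#' and the root seed. The configuration is serializable to JSON
#' ([write_run_config()]) and its MD5 hash is embedded in every output.
#'
#' @param continuum a [continuum_spec()].
#' @param design a [design_spec()].
#' @param population an [observer_population()].
#' @param n_subjects number of simulated subjects.
#' @param seed root seed for all stochastic stages.
#' @param n_points normalized-time grid size for trajectories.
#' @param alpha significance level of the running t-test.
#' @param noise_duration_ms duration of the masker file, ms.
#' @param snr_db mixing SNR for the noise-condition stimuli, dB.
#' @return an object of class `run_config`.
#' @export
run_config <- function(continuum = continuum_spec(), design = design_spec(),
                       population = observer_population(), n_subjects = 29L,
                       seed = 1L, n_points = 101L, alpha = 0.01,
                       noise_duration_ms = 5000, snr_db = 0) {
  structure(list(continuum = continuum, design = design,
                 population = population, n_subjects = as.integer(n_subjects),
                 seed = as.integer(seed), n_points = as.integer(n_points),
                 alpha = alpha, noise_duration_ms = noise_duration_ms,
                 snr_db = snr_db),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(rapply(unclass(config), identity, how = "list"),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(
    continuum = do.call(continuum_spec, j$continuum),
    design = do.call(design_spec, j$design[c("snr_conditions",
                                             "order_conditions",
                                             "trials_per_token", "n_tokens")]),
    population = do.call(observer_population,
                         j$population[setdiff(names(j$population), "fixed")]),
    n_subjects = j$n_subjects, seed = j$seed, n_points = j$n_points,
    alpha = j$alpha, noise_duration_ms = j$noise_duration_ms,
    snr_db = j$snr_db)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_run_config(config, tmp)
  unname(tools::md5sum(tmp))
}

log_event <- function(con, stage, ...) {
  rec <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                stage = stage), list(...))
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
}

#' Run the full pipeline
#'
#' Executes synth -> simulate -> psychometrics -> mousetrack -> stats on a
#' single [run_config()], writing each stage's outputs under `out_dir`:
#' stimulus WAVs plus sidecar, the long-format trial log, psychometric fits
#' and RT profiles, per-trial geometry and proximity curves with
#' significant-run report, ANOVA/contrast/correlation tables, a JSON-lines
#' event log, and a markdown report with summary figures. Identical
#' configurations regenerate byte-identical CSV/JSON outputs. Stages whose
#' outputs already exist are skipped when `resume = TRUE`.
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @param resume skip stages whose outputs are present.
#' @return invisibly, a list of the principal result tables.
#' @export
run_all <- function(config, out_dir, resume = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  write_run_config(config, file.path(out_dir, "config.json"))
  events <- file(file.path(out_dir, "events.jsonl"),
                 if (resume) "a" else "w")
  on.exit(close(events))
  seeds <- derive_seeds(config$seed, 3L)

  # stage 1: stimuli
  stim_dir <- file.path(out_dir, "stimuli")
  if (!resume || !file.exists(file.path(stim_dir, "stimuli.json"))) {
    stim <- write_stimulus_set(config$continuum, stim_dir,
                               config$noise_duration_ms, seed = seeds[1])
    mix <- mix_at_snr(stim$vowels[[1]], stim$noise, config$snr_db)
    log_event(events, "synth", config_hash = hash,
              n_tokens = config$continuum$n_steps,
              snr_db = config$snr_db,
              mix_clip_scale = attr(mix, "clip_scale"))
  }

  # stage 2: simulated experiment
  trials_path <- file.path(out_dir, "trials.csv")
  if (!resume || !file.exists(trials_path)) {
    log <- simulate_experiment(config$design, config$population,
                               config$n_subjects, seed = seeds[2])
    write_trial_log(log, trials_path)
    log_event(events, "simulate", config_hash = hash,
              n_subjects = config$n_subjects, n_rows = nrow(log))
  }
  log <- read_trial_log(trials_path)
  trials <- trials_summary(log)

  # stage 3: psychometrics + RTs
  fits <- fit_psychometrics(log)
  data.table::fwrite(fits, file.path(out_dir, "fits.csv"))
  rt_prof <- trials[, median_rt_per_token(.SD),
                    by = .(snr, condition = order_class(order))]
  data.table::fwrite(rt_prof, file.path(out_dir, "rt_profile.csv"))
  n_rt_excluded <- trials[, filter_rts(rt_ms)$n_excluded]
  sh <- split_half_reliability(log)
  log_event(events, "psychometrics", config_hash = hash,
            n_fits = nrow(fits), n_unconverged = sum(!fits$converged),
            n_rt_excluded = n_rt_excluded,
            split_half_r = sh$r, split_half_dropped = sh$n_dropped)

  # stage 4: mouse-tracking geometry
  geom <- track_geometry(log, n_points = config$n_points)
  data.table::fwrite(
    geom[, .(subject_id, block_id, trial_index, token, order, snr, response,
             rt_ms, auc_signed, auc_absolute)],
    file.path(out_dir, "geometry.csv"))
  prox <- condition_proximity(geom)
  prox_long <- prox[, .(t_index = seq_along(p[[1]]), proximity = p[[1]]),
                    by = .(subject_id, snr, condition)]
  data.table::fwrite(prox_long, file.path(out_dir, "proximity_curves.csv"))
  runs <- lapply(config$design$snr_conditions, function(sn) {
    rt_ <- running_ttest(proximity_matrix(prox, sn, "serial"),
                         proximity_matrix(prox, sn, "random"),
                         alpha = config$alpha)
    list(snr = sn, runs = rt_$runs)
  })
  names(runs) <- config$design$snr_conditions
  jsonlite::write_json(
    lapply(runs, function(r) r$runs),
    file.path(out_dir, "proximity_runs.json"), digits = NA, pretty = TRUE)
  log_event(events, "mousetrack", config_hash = hash,
            n_trials = nrow(geom))

  # stage 5: condition-level statistics
  auc_cells <- geom[, .(auc = mean(auc_signed)),
                    by = .(subject_id, snr, condition = order_class(order))]
  anova_auc <- rm_anova(auc_cells, "auc", c("snr", "condition"))
  data.table::fwrite(anova_auc, file.path(out_dir, "anova_auc.csv"))
  rt_cells <- trials[, {
    f <- filter_rts(rt_ms)
    .(rt = as.numeric(median(f$kept)))
  }, by = .(subject_id, snr, condition = order_class(order), token)]
  anova_rt <- rm_anova(rt_cells, "rt", c("snr", "condition", "token"))
  data.table::fwrite(anova_rt, file.path(out_dir, "anova_rt.csv"))
  contrasts <- holm_contrasts(auc_cells[snr == "noise"], "auc", "condition")
  data.table::fwrite(contrasts, file.path(out_dir, "contrasts.csv"))
  correlations <- warping_correlation_table(fits, auc_cells, trials)
  data.table::fwrite(correlations, file.path(out_dir, "correlations.csv"))
  log_event(events, "stats", config_hash = hash)

  # stage 6: report
  render_report(out_dir, config, hash, trials, fits, rt_prof, geom, prox,
                runs, anova_auc, anova_rt, contrasts, correlations, sh)
  log_event(events, "report", config_hash = hash)
  invisible(list(fits = fits, rt_profile = rt_prof, geometry = geom,
                 proximity = prox, runs = runs, anova_auc = anova_auc,
                 anova_rt = anova_rt, contrasts = contrasts,
                 correlations = correlations, split_half = sh))
}

# per-subject warping magnitude (mean |shift| over serial directions) and
# curvature change, correlated within each SNR stratum; plus RT-vs-curvature
# at the midpoint token
warping_correlation_table <- function(fits, auc_cells, trials) {
  shifts <- data.table::dcast(
    fits[condition %in% c("random", "forward", "reverse")],
    subject_id + snr ~ condition, value.var = "beta0")
  shifts[, delta_beta0 := (abs(forward - random) + abs(reverse - random)) / 2]
  auc_change <- data.table::dcast(auc_cells, subject_id + snr ~ condition,
                                  value.var = "auc")
  auc_change[, delta_auc := serial - random]
  merged <- shifts[auc_change, on = c("subject_id", "snr")]
  mid <- round(stats::median(unique(trials$token)))
  rt_mid <- trials[token == mid, {
    f <- filter_rts(rt_ms)
    .(rt = as.numeric(median(f$kept)))
  }, by = .(subject_id, snr)]
  merged <- rt_mid[merged, on = c("subject_id", "snr")]
  out <- merged[, {
    cb <- warping_correlation(delta_beta0, delta_auc)
    cr <- warping_correlation(rt, delta_auc)
    .(measure = c("delta_beta0_vs_delta_auc", "rt_tk_mid_vs_delta_auc"),
      r = c(cb$r, cr$r), p = c(cb$p, cr$p), n = c(cb$n, cr$n))
  }, by = snr]
  out[]
}

fmt_tab <- function(dt, digits = 4) {
  dt <- data.table::as.data.table(dt)
  num <- vapply(dt, is.numeric, logical(1))
  for (cn in names(dt)[num]) dt[[cn]] <- signif(dt[[cn]], digits)
  header <- paste("|", paste(names(dt), collapse = " | "), "|")
  sep <- paste("|", paste(rep("---", ncol(dt)), collapse = " | "), "|")
  body <- apply(dt, 1, function(r) paste("|", paste(r, collapse = " | "), "|"))
  c(header, sep, body)
}

render_report <- function(out_dir, config, hash, trials, fits, rt_prof,
                          geom, prox, runs, anova_auc, anova_rt, contrasts,
                          correlations, sh) {
  fig_dir <- file.path(out_dir, "figures")
  dir.create(fig_dir, showWarnings = FALSE)
  # figure 1: grand-average psychometric functions
  grDevices::png(file.path(fig_dir, "psychometric.png"), 700, 500)
  pr <- trials[!is.na(response),
               .(p = mean(response == "a")),
               by = .(snr, condition = order_class(order), token)]
  graphics::plot(NULL, xlim = range(pr$token), ylim = c(0, 1),
                 xlab = "token", ylab = "proportion /a/",
                 main = "Identification by condition")
  i <- 1
  for (key in split(pr, by = c("snr", "condition"))) {
    data.table::setorder(key, token)
    graphics::lines(key$token, key$p, col = i, lwd = 2)
    i <- i + 1
  }
  graphics::legend("topleft", legend = names(split(pr, by = c("snr", "condition"))),
                   col = seq_len(i - 1), lwd = 2, bty = "n")
  grDevices::dev.off()
  # figure 2: RT profiles
  grDevices::png(file.path(fig_dir, "rt_profile.png"), 700, 500)
  graphics::plot(NULL, xlim = range(rt_prof$token),
                 ylim = range(rt_prof$median_rt, na.rm = TRUE),
                 xlab = "token", ylab = "median RT (ms)",
                 main = "RT profile (inverted-V at the boundary)")
  i <- 1
  for (key in split(rt_prof, by = c("snr", "condition"))) {
    data.table::setorder(key, token)
    graphics::lines(key$token, key$median_rt, col = i, lwd = 2)
    i <- i + 1
  }
  grDevices::dev.off()
  # figure 3: mean endpoint tracks
  grDevices::png(file.path(fig_dir, "mean_tracks.png"), 600, 600)
  graphics::plot(NULL, xlim = c(0, 1), ylim = c(0, 1), xlab = "x", ylab = "y",
                 main = "Mean endpoint-token tracks")
  i <- 1
  for (key in split(geom, by = c("snr", "order"))) {
    mx <- colMeans(do.call(rbind, key$x_norm))
    my <- colMeans(do.call(rbind, key$y_norm))
    graphics::lines(mx, my, col = i, lwd = 2)
    i <- i + 1
  }
  grDevices::dev.off()
  # figure 4: proximity curves
  grDevices::png(file.path(fig_dir, "proximity.png"), 700, 500)
  graphics::plot(NULL, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "normalized time", ylab = "proximity",
                 main = "Proximity to target")
  i <- 1
  tgrid <- seq(0, 1, length.out = config$n_points)
  for (key in split(prox, by = c("snr", "condition"))) {
    graphics::lines(tgrid, colMeans(do.call(rbind, key$p)), col = i, lwd = 2)
    i <- i + 1
  }
  grDevices::dev.off()
  # figure 5: warping vs curvature change
  grDevices::png(file.path(fig_dir, "correlation.png"), 700, 500)
  fits_dt <- data.table::as.data.table(fits)
  shifts <- data.table::dcast(
    fits_dt[condition %in% c("random", "forward", "reverse")],
    subject_id + snr ~ condition, value.var = "beta0")
  shifts[, delta := (abs(forward - random) + abs(reverse - random)) / 2]
  auc_cells <- geom[, .(auc = mean(auc_signed)),
                    by = .(subject_id, snr, condition = order_class(order))]
  ac <- data.table::dcast(auc_cells, subject_id + snr ~ condition,
                          value.var = "auc")
  ac[, dauc := serial - random]
  mg <- shifts[ac, on = c("subject_id", "snr")]
  graphics::plot(mg$delta, mg$dauc,
                 col = ifelse(mg$snr == "noise", 2, 1), pch = 19,
                 xlab = "|delta beta0| (random vs serial)",
                 ylab = "auc change (serial - random)",
                 main = "Warping vs trajectory change")
  graphics::legend("topright", legend = c("clean", "noise"), col = c(1, 2),
                   pch = 19, bty = "n")
  grDevices::dev.off()

  lines_out <- c(
    "# Perceptual warping pipeline report", "",
    sprintf("Config hash: `%s`; seed %d; %d subjects.", hash, config$seed,
            config$n_subjects), "",
    "## Behavioral identification", "",
    "![psychometric](figures/psychometric.png)", "",
    sprintf("Split-half reliability of beta0: r = %.3f (p = %.3g, n = %d).",
            sh$r, sh$p, sh$n), "",
    "Per-condition psychometric fits (first rows):", "",
    fmt_tab(utils::head(fits, 8)), "",
    "## Reaction times", "",
    "![rt](figures/rt_profile.png)", "",
    "Repeated-measures ANOVA on per-token median RTs:", "",
    fmt_tab(anova_rt), "",
    "## Mouse trajectories", "",
    "![tracks](figures/mean_tracks.png)", "",
    "ANOVA on endpoint-token trajectory curvature (signed a.u.c.):", "",
    fmt_tab(anova_auc), "",
    "Holm-adjusted order contrasts in noise:", "",
    fmt_tab(contrasts), "",
    "## Proximity over normalized time", "",
    "![proximity](figures/proximity.png)", "",
    unlist(lapply(names(runs), function(sn) {
      r <- runs[[sn]]$runs
      if (nrow(r) == 0)
        sprintf("- %s: no significant serial-vs-random samples.", sn)
      else
        sprintf("- %s: significant runs at t* in [%s].", sn,
                paste(sprintf("%.2f-%.2f", r$t_norm_start, r$t_norm_end),
                      collapse = ", "))
    })), "",
    "## Warping-trajectory correlations", "",
    "![correlation](figures/correlation.png)", "",
    fmt_tab(correlations), "")
  writeLines(lines_out, file.path(out_dir, "report.md"))
}
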