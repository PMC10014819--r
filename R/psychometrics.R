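#' Logistic identification function
#'
#' `P(x) = 1 / (1 + exp(-beta1 * (x - beta0)))`: probability of labeling
#' token `x` as the upper (/a/) endpoint. `beta0` is the category boundary
#' (the 50% point) and `beta1` the slope.
#'
#' @param x token index (vectorized).
#' @param beta0 boundary, token units.
#' @param beta1 slope, per token.
#' @return identification probabilities.
#' @export
logistic_p <- function(x, beta0, beta1) stats::plogis(beta1 * (x - beta0))

#' Fit the identification sigmoid
#'
#' Weighted least squares on per-token proportions: minimizes
#' `sum(w * (p - P(x))^2)` over `(beta0, beta1)` by bounded quasi-Newton
#' (L-BFGS-B) from the fixed start `beta0 = mid-continuum`, `beta1 = 1`, with
#' `beta0` constrained to one token beyond the continuum ends and `beta1` to
#' `(0, 20]`. Deterministic given the data. All-constant proportions are
#' non-identifiable: the fit returns `beta1 = 0` with `converged = FALSE`
#' rather than an error; decreasing data are fit as-is with a warning.
#'
#' @param proportions per-token fraction of /a/ responses.
#' @param tokens token indices (default `1..length(proportions)`).
#' @param weights per-token weights (e.g. trial counts); default equal.
#' @return an object of class `psychometric_fit` with fields `beta0`,
#'   `beta1`, `sse`, `converged`, `n_trials_used`.
#' @export
#' @examples
#' fit_sigmoid(c(0, 0, 0, .5, 1, 1, 1))$beta0 # 4
fit_sigmoid <- function(proportions, tokens = seq_along(proportions),
                        weights = rep(1, length(proportions))) {
  ok <- is.finite(proportions) & is.finite(tokens)
  p <- proportions[ok]; x <- tokens[ok]; w <- weights[ok]
  if (length(p) < 2) stop("fit_sigmoid: need at least 2 tokens")
  out <- structure(list(beta0 = NA_real_, beta1 = NA_real_, sse = NA_real_,
                        converged = FALSE, n_trials_used = sum(w)),
                   class = "psychometric_fit")
  if (stats::var(p) == 0) {          # flat data: boundary undefined
    out$beta0 <- mean(range(x)); out$beta1 <- 0; out$sse <- 0
    return(out)
  }
  if (p[which.max(x)] < p[which.min(x)])
    warning("fit_sigmoid: proportions decrease with token index; ",
            "fitting as-is (check the response coding)")
  sse <- function(par) sum(w * (p - logistic_p(x, par[1], par[2]))^2)
  opt <- optim(c(mean(range(x)), 1), sse, method = "L-BFGS-B",
               lower = c(min(x) - 1, 1e-6), upper = c(max(x) + 1, 20),
               control = list(factr = 1e4, maxit = 500))
  out$beta0 <- opt$par[1]; out$beta1 <- opt$par[2]; out$sse <- opt$value
  out$converged <- opt$convergence == 0
  out
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf("psychometric fit: beta0 = %.3f, beta1 = %.3f (sse %.4g, %s)\n",
              x$beta0, x$beta1, x$sse,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
predict.psychometric_fit <- function(object, x, ...) {
  logistic_p(x, object$beta0, object$beta1)
}

#' Boundary shift between two fits
#'
#' @param fit_serial,fit_random converged [fit_sigmoid()] objects.
#' @return list with `delta` (signed `beta0_serial - beta0_random`),
#'   `magnitude` (`|delta|`) and `converged` (both inputs converged).
#' @export
boundary_shift <- function(fit_serial, fit_random) {
  delta <- fit_serial$beta0 - fit_random$beta0
  list(delta = delta, magnitude = abs(delta),
       converged = isTRUE(fit_serial$converged) && isTRUE(fit_random$converged))
}

#' Filter reaction times to the analysis window
#'
#' Retains RTs inside the closed interval `[250, 2500]` ms; values outside
#' are outliers (fast guesses, attentional lapses).
#'
#' @param rts numeric RTs, ms.
#' @param window closed lower/upper bounds, ms.
#' @return list with `kept` and `n_excluded`; counts are conserved.
#' @export
filter_rts <- function(rts, window = c(250, 2500)) {
  keep <- !is.na(rts) & rts >= window[1] & rts <= window[2]
  list(kept = rts[keep], n_excluded = sum(!keep))
}

#' Median RT per token
#'
#' Applies the outlier window, then computes the median retained RT per
#' token. Tokens with no retained trials are reported with `NA`.
#'
#' @param trials a per-trial data.table with `token` and `rt_ms` (e.g. from
#'   [trials_summary()]).
#' @param window RT inclusion window, ms.
#' @param n_tokens number of continuum tokens (default: max observed).
#' @return a data.table with `token`, `median_rt`, `n`, `n_excluded`.
#' @export
median_rt_per_token <- function(trials, window = c(250, 2500),
                                n_tokens = max(trials$token)) {
  prof <- trials[, {
    f <- filter_rts(rt_ms, window)
    .(median_rt = if (length(f$kept)) as.numeric(median(f$kept)) else NA_real_,
      n = length(f$kept), n_excluded = f$n_excluded)
  }, by = token]
  all_tok <- data.table::data.table(token = seq_len(n_tokens))
  prof <- prof[all_tok, on = "token"]
  prof[is.na(n), `:=`(n = 0L, n_excluded = 0L)]
  data.table::setorder(prof, token)
  prof[]
}

order_class <- function(order) ifelse(order == "random", "random", "serial")

# proportion-/a/ per token for a set of trials
proportions_by_token <- function(trials, n_tokens) {
  pr <- trials[!is.na(response),
               .(p = mean(response == "a"), n = .N), by = token]
  full <- data.table::data.table(token = seq_len(n_tokens))
  pr <- pr[full, on = "token"]
  data.table::setorder(pr, token)
  pr
}

#' Fit psychometric functions for every subject and condition
#'
#' For each subject and SNR condition, fits the sigmoid to the random block,
#' to the pooled serial blocks (forward and reverse combined -- the standard
#' data reduction), and to each serial direction separately (used for
#' signed-shift and warp-recovery analyses).
#'
#' @param log a trial log (long format or per-trial).
#' @param n_tokens number of continuum tokens.
#' @return a data.table with `subject_id`, `snr`, `condition` (one of
#'   `"random"`, `"serial"`, `"forward"`, `"reverse"`), `beta0`, `beta1`,
#'   `sse`, `converged`, `n_trials`.
#' @export
fit_psychometrics <- function(log, n_tokens = max(log$token)) {
  trials <- trials_summary(log)
  fit_one <- function(tr) {
    pr <- proportions_by_token(tr, n_tokens)
    f <- fit_sigmoid(pr$p, pr$token, ifelse(is.na(pr$n), 0, pr$n))
    list(beta0 = f$beta0, beta1 = f$beta1, sse = f$sse,
         converged = f$converged, n_trials = nrow(tr))
  }
  pooled <- trials[, fit_one(.SD), by = .(subject_id, snr,
                                          condition = order_class(order))]
  per_dir <- trials[order != "random",
                    fit_one(.SD), by = .(subject_id, snr, condition = order)]
  out <- data.table::rbindlist(list(pooled, per_dir))
  data.table::setorder(out, subject_id, snr, condition)
  out[]
}

#' Split-half reliability of the fitted boundary
#'
#' Splits each subject's trials into first and last halves (by trial index
#' within block, pooling all orders and SNRs), fits the sigmoid to each half,
#' and returns the Pearson correlation of `beta0` across subjects. Subjects
#' with an unfittable half are dropped (reported in `n_dropped`).
#'
#' @param log a trial log.
#' @param n_tokens number of continuum tokens.
#' @return list with `r`, `p`, `n`, `n_dropped` and the per-subject table.
#' @export
split_half_reliability <- function(log, n_tokens = max(log$token)) {
  trials <- trials_summary(log)
  trials[, half := ifelse(trial_index <= max(trial_index) / 2, 1L, 2L),
         by = .(subject_id, block_id)]
  fits <- trials[, {
    pr <- proportions_by_token(.SD, n_tokens)
    f <- fit_sigmoid(pr$p, pr$token, ifelse(is.na(pr$n), 0, pr$n))
    .(beta0 = f$beta0, converged = f$converged)
  }, by = .(subject_id, half)]
  wide <- data.table::dcast(fits, subject_id ~ half, value.var = c("beta0", "converged"))
  ok <- wide$converged_1 & wide$converged_2
  n_dropped <- sum(!ok)
  wide <- wide[ok]
  if (nrow(wide) < 3) stop("split_half_reliability: need >= 3 usable subjects")
  ct <- cor.test(wide$beta0_1, wide$beta0_2)
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(wide),
       n_dropped = n_dropped, per_subject = wide[])
}
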