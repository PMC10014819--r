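#' Experiment design specification
#'
#' The design crosses masking condition (clean vs noise at 0 dB SNR) with
#' token presentation order (random, forward serial Tk1->Tk7, reverse serial
#' Tk7->Tk1), one block per cell. Defaults give six blocks of 210 trials
#' (30 per token on a 7-token continuum).
#'
#' @param snr_conditions character vector of masking conditions.
#' @param order_conditions character vector of presentation orders; a subset
#'   of `"random"`, `"forward"`, `"reverse"`.
#' @param trials_per_token trials per token within each block.
#' @param n_tokens number of continuum tokens.
#' @return an object of class `design_spec`.
#' @export
design_spec <- function(snr_conditions = c("clean", "noise"),
                        order_conditions = c("random", "forward", "reverse"),
                        trials_per_token = 30L, n_tokens = 7L) {
  stopifnot(trials_per_token >= 1, n_tokens >= 2)
  bad <- setdiff(order_conditions, c("random", "forward", "reverse"))
  if (length(bad))
    stop("design_spec: unknown order condition(s): ", paste(bad, collapse = ", "))
  structure(list(snr_conditions = snr_conditions,
                 order_conditions = order_conditions,
                 trials_per_token = as.integer(trials_per_token),
                 n_tokens = as.integer(n_tokens)),
            class = "design_spec")
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf("design: %d blocks (%s x %s), %d trials/token x %d tokens = %d trials/block\n",
              length(x$snr_conditions) * length(x$order_conditions),
              paste(x$snr_conditions, collapse = "/"),
              paste(x$order_conditions, collapse = "/"),
              x$trials_per_token, x$n_tokens,
              x$trials_per_token * x$n_tokens))
  invisible(x)
}

#' Token sequence for one block
#'
#' Serial orders are `trials_per_token` concatenated monotone passes over the
#' continuum (strictly increasing for `"forward"`, decreasing for
#' `"reverse"`). The random order draws a fresh seeded permutation of the
#' token set for each pass, which guarantees exactly `trials_per_token`
#' presentations of every token.
#'
#' @param design a [design_spec()].
#' @param order one of `"random"`, `"forward"`, `"reverse"`.
#' @param seed integer seed (used only for `"random"`).
#' @return integer vector of token indices of length
#'   `trials_per_token * n_tokens`.
#' @export
#' @examples
#' length(make_trial_sequence(design_spec(), "forward")) # 210
make_trial_sequence <- function(design, order, seed = 1L) {
  toks <- seq_len(design$n_tokens)
  reps <- design$trials_per_token
  switch(order,
    forward = rep(toks, times = reps),
    reverse = rep(rev(toks), times = reps),
    random = with_seed(seed, as.integer(unlist(
      replicate(reps, sample(toks), simplify = FALSE)))),
    stop("make_trial_sequence: unknown order '", order, "'"))
}

#' Per-subject block plan
#'
#' All `snr x order` cells in a seeded random block order.
#'
#' @param design a [design_spec()].
#' @param seed integer seed for the block-order permutation.
#' @return a data.table with `block_id`, `snr`, `order`.
#' @export
block_plan <- function(design, seed = 1L) {
  cells <- data.table::CJ(order = design$order_conditions,
                          snr = design$snr_conditions, sorted = FALSE)
  perm <- with_seed(seed, sample(nrow(cells)))
  cells <- cells[perm]
  cells[, block_id := seq_len(.N)]
  cells[, .(block_id, snr, order)]
}

trial_log_columns <- c("subject_id", "block_id", "trial_index", "token",
                       "order", "snr", "response", "rt_ms",
                       "sample_t_ms", "sample_x", "sample_y")

#' Write a trial log to CSV
#'
#' The canonical long format: one row per 100 Hz cursor sample, trial-level
#' fields repeated on each row. Trials without trajectory data carry a single
#' row with `NA` sample fields.
#'
#' @param log a trial-log data.table (see [read_trial_log()] for the schema).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(log, path) {
  missing_cols <- setdiff(trial_log_columns, names(log))
  if (length(missing_cols))
    stop("write_trial_log: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  data.table::fwrite(log[, trial_log_columns, with = FALSE], path)
  invisible(path)
}

#' Read and validate a trial log CSV
#'
#' Expected columns: `subject_id`, `block_id`, `trial_index`, `token`,
#' `order`, `snr`, `response`, `rt_ms`, `sample_t_ms`, `sample_x`,
#' `sample_y`. Schema violations raise an error naming the offending column
#' (and row where applicable); non-uniform trajectory sampling triggers a
#' warning.
#'
#' @param path CSV path.
#' @param check_sampling verify the 10 ms sample grid (warning on failure).
#' @return a data.table keyed by subject, block and trial.
#' @export
read_trial_log <- function(path, check_sampling = TRUE) {
  log <- data.table::fread(path,
    colClasses = list(character = c("subject_id", "order", "snr", "response")))
  if (nrow(log) == 0) {
    empty <- data.table::data.table(
      subject_id = character(), block_id = integer(), trial_index = integer(),
      token = integer(), order = character(), snr = character(),
      response = character(), rt_ms = numeric(), sample_t_ms = numeric(),
      sample_x = numeric(), sample_y = numeric())
    return(empty)
  }
  validate_trial_log(log, check_sampling = check_sampling)
  data.table::setkeyv(log, c("subject_id", "block_id", "trial_index"))
  log[]
}

validate_trial_log <- function(log, check_sampling = TRUE) {
  missing_cols <- setdiff(trial_log_columns, names(log))
  if (length(missing_cols))
    stop("trial log: missing column(s): ", paste(missing_cols, collapse = ", "))
  check_col <- function(col, ok) {
    bad <- which(!ok)
    if (length(bad))
      stop(sprintf("trial log: invalid value in column '%s' at row %d",
                   col, bad[1]))
  }
  check_col("token", is.finite(log$token) & log$token >= 1 &
              log$token == round(log$token))
  check_col("order", log$order %in% c("random", "forward", "reverse"))
  check_col("rt_ms", is.na(log$rt_ms) | log$rt_ms > 0)
  check_col("response", is.na(log$response) | log$response %in% c("u", "a"))
  if (check_sampling && any(!is.na(log$sample_t_ms))) {
    dt <- log[!is.na(sample_t_ms),
              .(bad = length(unique(round(diff(sample_t_ms), 6))) > 1),
              by = .(subject_id, block_id, trial_index)]
    if (any(dt$bad))
      warning("trial log: non-uniform trajectory sampling in ",
              sum(dt$bad), " trial(s)")
  }
  invisible(log)
}

#' Per-trial summary of a long-format log
#'
#' Collapses the one-row-per-sample log to one row per trial, dropping the
#' trajectory columns.
#'
#' @param log a trial-log data.table.
#' @return a data.table with one row per trial.
#' @export
trials_summary <- function(log) {
  log[, .SD[1], by = .(subject_id, block_id, trial_index),
      .SDcols = c("token", "order", "snr", "response", "rt_ms")]
}
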