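#' Repeated-measures ANOVA on subject-by-condition cell means
#'
#' Classical within-subject decomposition with subject as a random blocking
#' factor: the model `dv ~ A * B * ... + Error(subject / (A * B * ...))` is
#' fit on one value per subject and cell. Effects are tested against their
#' own subject-by-effect interaction stratum, and effect size is partial
#' eta squared, `SS_effect / (SS_effect + SS_error)`. Subjects with missing
#' cells are removed listwise (reported via a message); effects whose sum of
#' squares is zero are reported with `F = 0`.
#'
#' @param data a data.frame/data.table with one row per subject x cell.
#' @param dv name of the dependent-variable column.
#' @param within character vector of within-subject factor names.
#' @param subject name of the subject identifier column.
#' @return a data.table with `effect`, `df1`, `df2`, `ss_effect`,
#'   `ss_error`, `F`, `p`, `pes`; attribute `"n_subjects"` records the
#'   analyzed sample.
#' @export
rm_anova <- function(data, dv, within, subject = "subject_id") {
  dt <- data.table::as.data.table(data)
  cells <- do.call(data.table::CJ, c(lapply(within, function(f)
    unique(dt[[f]])), list(sorted = FALSE, unique = TRUE)))
  data.table::setnames(cells, within)
  n_cells <- nrow(cells)
  counts <- dt[, .N, by = subject]
  complete <- counts[N == n_cells][[subject]]
  dropped <- setdiff(counts[[subject]], complete)
  if (length(dropped)) {
    message("rm_anova: dropping ", length(dropped),
            " subject(s) with incomplete cells")
    dt <- dt[get(subject) %in% complete]
  }
  if (length(complete) < 2) stop("rm_anova: need at least 2 complete subjects")
  dt[[subject]] <- factor(dt[[subject]])
  for (f in within) dt[[f]] <- factor(dt[[f]])
  fixed <- paste(within, collapse = " * ")
  form <- stats::as.formula(paste0(dv, " ~ ", fixed,
                                   " + Error(", subject, "/(", fixed, "))"))
  fit <- aov(form, data = dt)
  y <- dt[[dv]]
  zero_tol <- 1e-12 * max(sum((y - mean(y))^2), .Machine$double.eps)
  out <- list()
  for (stratum in summary(fit)) {
    tab <- stratum[[1]]
    rn <- trimws(rownames(tab))
    resid_row <- which(rn == "Residuals")
    if (!length(resid_row)) next
    ss_err <- tab[resid_row, "Sum Sq"]
    df_err <- tab[resid_row, "Df"]
    for (i in setdiff(seq_len(nrow(tab)), resid_row)) {
      ss <- tab[i, "Sum Sq"]
      null_effect <- ss <= zero_tol
      Fv <- if (null_effect) 0
        else if (ss_err <= zero_tol) Inf
        else (ss / tab[i, "Df"]) / (ss_err / df_err)
      out[[length(out) + 1L]] <- data.table::data.table(
        effect = rn[i], df1 = tab[i, "Df"], df2 = df_err,
        ss_effect = ss, ss_error = ss_err, F = Fv,
        p = if (null_effect) 1 else stats::pf(Fv, tab[i, "Df"], df_err,
                                              lower.tail = FALSE),
        pes = if (ss + ss_err <= zero_tol) 0 else ss / (ss + ss_err))
    }
  }
  res <- data.table::rbindlist(out)
  attr(res, "n_subjects") <- length(complete)
  res[]
}

#' Holm-adjusted pairwise contrasts
#'
#' All pairwise paired t-tests between the levels of one within-subject
#' factor (on subject-level means over the remaining factors), with
#' step-down Holm adjustment; raw p-values are always reported alongside.
#'
#' @param data one row per subject x cell (as for [rm_anova()]).
#' @param dv dependent-variable column name.
#' @param factor_name the factor whose levels are compared.
#' @param subject subject identifier column.
#' @return a data.table with `level_1`, `level_2`, `estimate` (mean
#'   difference), `t`, `df`, `p_raw`, `p_holm`.
#' @export
holm_contrasts <- function(data, dv, factor_name, subject = "subject_id") {
  dt <- data.table::as.data.table(data)
  means <- dt[, .(m = mean(get(dv))), by = c(subject, factor_name)]
  wide <- data.table::dcast(means,
    stats::as.formula(paste(subject, "~", factor_name)), value.var = "m")
  lev <- setdiff(names(wide), subject)
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    d <- wide[[pr[1]]] - wide[[pr[2]]]
    d <- d[is.finite(d)]
    if (sd(d) == 0) {
      tt <- list(statistic = if (mean(d) == 0) 0 else Inf * sign(mean(d)),
                 parameter = length(d) - 1,
                 p.value = if (mean(d) == 0) 1 else 0)
    } else tt <- t.test(d)
    data.table::data.table(level_1 = pr[1], level_2 = pr[2],
                           estimate = mean(d),
                           t = unname(tt$statistic), df = unname(tt$parameter),
                           p_raw = tt$p.value)
  })
  res <- data.table::rbindlist(rows)
  res[, p_holm := p.adjust(p_raw, method = "holm")]
  res[]
}

#' Correlation between boundary warping and trajectory change
#'
#' Pearson correlation (two-tailed) between per-subject measures -- e.g. the
#' magnitude of the boundary shift `|delta beta0|` between random and serial
#' orders against the serial-minus-random change in trajectory curvature --
#' computed separately per SNR stratum by the caller. Constant input yields
#' an `NA` correlation with `degenerate = TRUE` rather than an error.
#'
#' @param x,y paired per-subject values (>= 4 complete pairs).
#' @return list with `r`, `p`, `n`, `degenerate`.
#' @export
warping_correlation <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) stop("warping_correlation: need >= 4 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(x), degenerate = TRUE))
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       degenerate = FALSE)
}
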