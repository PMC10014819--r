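make_cells <- function(n_subj, effect = 0, interaction = 0, sd = 1,
                       seed = 1) {
  set.seed(seed)
  grid <- data.table::CJ(subject_id = sprintf("S%02d", 1:n_subj),
                         snr = c("clean", "noise"),
                         condition = c("random", "serial"))
  grid[, y := rnorm(.N, sd = sd) +
         effect * (condition == "serial") +
         interaction * (condition == "serial") * (snr == "noise")]
  grid
}

test_that("constant cells give zero F for every effect", {
  cells <- make_cells(6, sd = 0)
  cells[, y := 1]
  res <- rm_anova(cells, "y", c("snr", "condition"))
  expect_true(all(res$F == 0))
  expect_true(all(res$p == 1))
})

test_that("two-level within-subject F equals the squared paired t", {
  cells <- make_cells(10, effect = 0.8, seed = 3)
  means <- cells[, .(y = mean(y)), by = .(subject_id, condition)]
  res <- rm_anova(means, "y", "condition")
  wide <- data.table::dcast(means, subject_id ~ condition, value.var = "y")
  tt <- t.test(wide$serial - wide$random)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(res$p, tt$p.value, tolerance = 1e-9)
  expect_equal(res$df1, 1)
  expect_equal(res$df2, 9)
})

test_that("sums of squares are non-negative and decompose the total", {
  cells <- make_cells(8, effect = 0.5, interaction = 0.7, seed = 5)
  res <- rm_anova(cells, "y", c("snr", "condition"))
  expect_true(all(res$ss_effect >= 0) && all(res$ss_error >= 0))
  # SS_total = subject SS + all effect and error strata
  fit <- aov(y ~ snr * condition + Error(subject_id / (snr * condition)),
             data = within(as.data.frame(cells), {
               subject_id <- factor(subject_id)
               snr <- factor(snr); condition <- factor(condition)
             }))
  all_ss <- sum(vapply(summary(fit),
                       function(s) sum(s[[1]][, "Sum Sq"]), numeric(1)))
  ss_total <- sum((cells$y - mean(cells$y))^2)
  expect_equal(all_ss, ss_total, tolerance = 1e-9 * ss_total)
  # partial eta^2 consistency
  expect_equal(res$pes, res$ss_effect / (res$ss_effect + res$ss_error))
})

test_that("incomplete subjects are dropped listwise with a message", {
  cells <- make_cells(5)
  cells <- cells[!(subject_id == "S01" & snr == "noise" &
                     condition == "serial")]
  expect_message(res <- rm_anova(cells, "y", c("snr", "condition")),
                 "dropping 1")
  expect_equal(attr(res, "n_subjects"), 4)
  expect_error(rm_anova(cells[subject_id == "S02"], "y",
                        c("snr", "condition")), "at least 2")
})

test_that("a generated order-by-SNR interaction in curvature is detected", {
  # magnitudes on the scale of the simulated a.u.c. cell means: a ~0.015
  # units^2 straightening against ~0.005 between-subject dispersion
  hits <- vapply(1:40, function(i) {
    cells <- make_cells(29, interaction = -0.015, sd = 0.005, seed = 100 + i)
    res <- rm_anova(cells, "y", c("snr", "condition"))
    res[effect == "snr:condition"]$p < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.8)
})

test_that("Holm contrasts reproduce the step-down rule", {
  # single pair: adjusted equals raw
  cells <- make_cells(6, effect = 1, seed = 7)
  hc <- holm_contrasts(cells, "y", "condition")
  expect_equal(nrow(hc), 1)
  expect_equal(hc$p_holm, hc$p_raw)
  # identical levels: p = 1 throughout
  cells2 <- make_cells(5, sd = 1, seed = 8)
  cells2[, y := rnorm(5)[match(subject_id, unique(subject_id))]]
  hc2 <- holm_contrasts(cells2, "y", "condition")
  expect_equal(hc2$p_holm, 1)
  # k = 3: enumerate the step-down rule by hand on the raw p-values
  toks <- data.table::CJ(subject_id = sprintf("S%02d", 1:8),
                         token = c("t1", "t2", "t3"))
  set.seed(9)
  toks[, y := rnorm(.N) + 0.9 * (token == "t3")]
  hc3 <- holm_contrasts(toks, "y", "token")
  ord <- order(hc3$p_raw)
  manual <- pmin(1, cummax(hc3$p_raw[ord] * (3:1)))
  expect_equal(hc3$p_holm[ord], manual)
})

test_that("warping correlations behave at the identity and under the null", {
  x <- rnorm(20)
  wc <- warping_correlation(x, x)
  expect_equal(wc$r, 1)
  expect_lt(wc$p, 1e-10)
  expect_true(warping_correlation(rep(1, 10), rnorm(10))$degenerate)
  expect_error(warping_correlation(1:3, 1:3), ">= 4")
  # null calibration: rejection at alpha = 0.05 near 5%
  set.seed(12)
  rej <- vapply(1:2000, function(i)
    warping_correlation(rnorm(29), rnorm(29))$p < 0.05, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.015)
  # p-values uniform under the null (KS sanity check)
  ps <- vapply(1:2000, function(i)
    warping_correlation(rnorm(20), rnorm(20))$p, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("coupling warp magnitude to curvature change yields positive r", {
  set.seed(15)
  mean_r <- mean(vapply(1:50, function(i) {
    warp <- abs(rnorm(29, 0.5, 0.75))
    dauc <- -0.3 * warp + rnorm(29, sd = 0.3)
    warping_correlation(warp, -dauc)$r
  }, numeric(1)))
  expect_gt(mean_r, 0.3)
})
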