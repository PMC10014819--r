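test_that("pixel coordinates normalize to the unit square with clamping", {
  expect_equal(normalize_coordinates(0, 0, 1920, 1080), list(x = 0, y = 0))
  expect_equal(normalize_coordinates(1919, 1079, 1920, 1080),
               list(x = 1, y = 1))
  nc <- normalize_coordinates(960, 135, 1920, 1080)
  expect_equal(nc$x, 960 / 1919)
  expect_equal(nc$y, 135 / 1079)
  expect_warning(out <- normalize_coordinates(-5, 2000, 1920, 1080),
                 "clamped")
  expect_equal(out, list(x = 0, y = 1))
})

test_that("time normalization preserves endpoints and linear geometry", {
  tn <- time_normalize(c(0, 500), c(0.5, 0.9), c(0.1, 0.9))
  expect_equal(nrow(tn), 101)
  # collinearity of a straight 2-point track
  expect_equal(cor(tn$x, tn$y), 1)
  expect_equal(tn$x[1], 0.5); expect_equal(tn$x[101], 0.9)
  # a track already on the grid is unchanged
  t0 <- seq(0, 1000, by = 10)
  x0 <- sin(t0 / 300); y0 <- cos(t0 / 500)
  tn2 <- time_normalize(t0, x0, y0, n_points = length(t0))
  expect_equal(tn2$x, x0, tolerance = 1e-12)
  expect_equal(tn2$y, y0, tolerance = 1e-12)
  # known analytic piecewise path evaluated at matching nodes
  tn3 <- time_normalize(c(0, 100, 300), c(0, 1, 5), c(0, 2, 2), n_points = 7)
  tq <- seq(0, 300, length.out = 7)
  expect_equal(tn3$x, ifelse(tq <= 100, tq / 100, 1 + (tq - 100) / 50),
               tolerance = 1e-9)
  expect_error(time_normalize(0, 0.5, 0.5), "2 samples")
})

test_that("mirroring is an involution and pooling matches brute force", {
  set.seed(4)
  n_tr <- 6
  xs <- t(replicate(n_tr, random_smooth_track()$x))
  ys <- t(replicate(n_tr, random_smooth_track()$y))
  side <- rep(c("left", "right"), 3)
  pooled <- mirror_pool(xs, ys, side)
  expect_equal(pooled$target_side, "right")
  # mirroring twice is the identity
  twice <- mirror_pool(pooled$x_mat, pooled$y_mat, ifelse(side == "left",
                                                          "left", "right"))
  manual_x <- xs
  manual_x[side == "left", ] <- 1 - manual_x[side == "left", ]
  expect_equal(pooled$x_mat, manual_x)
  expect_equal(pooled$mean_track$x, colMeans(manual_x))
  # mirror-image pair pools to either member
  x1 <- random_smooth_track()$x
  pair <- mirror_pool(rbind(1 - x1, x1), rbind(ys[1, ], ys[1, ]),
                      c("left", "right"))
  expect_equal(pair$mean_track$x, x1)
  # right-only input is untouched
  ident <- mirror_pool(xs, ys, rep("right", n_tr))
  expect_equal(ident$x_mat, xs)
})

test_that("area under the curve follows the shoelace oracle", {
  # straight line, any sampling
  t <- seq(0, 1, length.out = 37)
  straight <- compute_auc(0.5 + 0.4 * t, 0.1 + 0.8 * t)
  expect_equal(straight$auc_signed, 0, tolerance = 1e-12)
  expect_equal(straight$auc_absolute, 0, tolerance = 1e-12)
  # right-angle toy path: area 0.25, bowing left of the chord => positive
  toy <- compute_auc(c(0.5, 0.5, 1), c(0, 1, 1))
  expect_equal(toy$auc_signed, 0.25)
  expect_equal(toy$auc_absolute, 0.25, tolerance = 1e-12)
  # mirroring negates the signed area, preserves the absolute one
  set.seed(9)
  for (i in 1:20) {
    tr <- random_smooth_track()
    a <- compute_auc(tr$x, tr$y)
    m <- compute_auc(1 - tr$x, tr$y)
    expect_equal(a$auc_signed + m$auc_signed, 0, tolerance = 1e-12)
    expect_equal(a$auc_absolute, m$auc_absolute, tolerance = 1e-12)
  }
  expect_error(compute_auc(c(0, 1), c(0, 1)), "3 samples")
  expect_true(compute_auc(c(0, 1, 0), c(0, 1, 0))$degenerate)
})

test_that("compute_auc agrees with a fine-grid numerical oracle", {
  set.seed(14)
  for (i in 1:100) {
    tr <- random_smooth_track(n = 101)
    a <- compute_auc(tr$x, tr$y)
    o <- auc_oracle(tr$x, tr$y)
    expect_lt(abs(a$auc_signed - o$signed), 0.01 * max(0.01, abs(o$signed)))
    expect_lt(abs(a$auc_absolute - o$absolute), 0.01 * max(0.01, o$absolute))
  }
})

test_that("proximity is bounded, anchored at the extremes, and linear for a
           constant-speed straight approach", {
  target <- c(0.925, 0.925)
  # straight constant-speed path starting at the farthest point: p(t) = t
  t <- seq(0, 1, length.out = 101)
  x <- 0.5 + (target[1] - 0.5) * t
  y <- 0.125 + (target[2] - 0.125) * t
  pc <- proximity_curve(x, y, target)
  expect_equal(pc$p, t, tolerance = 1e-12)
  expect_equal(pc$p[1], 0)      # farthest sample
  expect_equal(pc$p[101], 1)    # on the target
  # bounds hold on arbitrary tracks
  set.seed(2)
  for (i in 1:50) {
    tr <- random_smooth_track()
    p <- proximity_curve(tr$x, tr$y, target)$p
    expect_true(all(p >= 0 & p <= 1))
  }
  # degenerate: track starting on the target
  deg <- proximity_curve(rep(target[1], 5), rep(target[2], 5), target)
  expect_true(deg$degenerate)
  expect_equal(deg$p, rep(1, 5))
})

test_that("running t-test finds no runs under identity and all under offset", {
  set.seed(6)
  a <- matrix(rnorm(29 * 101), 29)
  same <- running_ttest(a, a)
  expect_equal(nrow(same$runs), 0)
  expect_true(all(same$p == 1))
  shifted <- running_ttest(a + 10, a)
  expect_equal(nrow(shifted$runs), 1)
  expect_equal(shifted$runs$length, 101)
  expect_equal(shifted$runs$t_norm_start, 0)
  expect_equal(shifted$runs$t_norm_end, 1)
  # zero-variance nonzero-constant differences are certain rejections
  b <- a; b[, 5] <- a[, 5] + 1e-9
  const <- running_ttest(a + matrix(2, 29, 101), a)
  expect_true(all(const$stats$p == 0))
  expect_error(running_ttest(a[1:2, ], a[1:2, ]), "3 subject")
})

test_that("per-sample type-I error of the running t-test is nominal", {
  set.seed(31)
  n_sim <- 400
  rej <- vapply(seq_len(n_sim), function(i) {
    a <- matrix(rnorm(29 * 101), 29)
    b <- matrix(rnorm(29 * 101), 29)
    mean(running_ttest(a, b, alpha = 0.01)$stats$significant)
  }, numeric(1))
  expect_lt(abs(mean(rej) - 0.01), 0.003)
})

test_that("track geometry mirrors /u/ trials and pools endpoint tokens", {
  log <- small_log(n_subjects = 2, trials_per_token = 4L)
  geom <- track_geometry(log)
  expect_setequal(unique(geom$token), c(1, 7))
  # mirrored tracks all end at the right target box
  finals <- vapply(geom$x_norm, function(v) v[length(v)], numeric(1))
  expect_true(all(finals >= 0.85))
  prox <- condition_proximity(geom)
  m <- proximity_matrix(prox, "clean", "random")
  expect_equal(dim(m), c(2, 101))
  expect_true(all(m >= 0 & m <= 1))
})
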