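#' Normalize pixel coordinates to the unit square
#'
#' `x / (width - 1)`, `y / (height - 1)`, with y increasing upward toward
#' the response targets (the input is assumed bottom-origin). Positions
#' outside the screen are clamped with a warning.
#'
#' @param x_px,y_px pixel coordinates.
#' @param width,height screen resolution in pixels.
#' @return list with normalized `x` and `y` in `[0, 1]`.
#' @export
normalize_coordinates <- function(x_px, y_px, width, height) {
  stopifnot(width > 0, height > 0)
  x <- x_px / (width - 1)
  y <- y_px / (height - 1)
  if (any(x < 0 | x > 1 | y < 0 | y > 1)) {
    warning("normalize_coordinates: positions outside the screen were clamped")
    x <- pmin(1, pmax(0, x)); y <- pmin(1, pmax(0, y))
  }
  list(x = x, y = y)
}

#' Resample a trajectory onto normalized time
#'
#' Linear interpolation of `x(t)` and `y(t)` onto `n_points` equally spaced
#' points spanning the first sample (threshold crossing) to the last
#' (response termination). Endpoints are preserved exactly, and the common
#' grid makes trajectories comparable sample-by-sample across trials.
#'
#' @param t sample times (ms).
#' @param x,y positions.
#' @param n_points grid size (101 is the mouse-tracking convention).
#' @return a data.table with `t_norm` in `[0, 1]`, `x`, `y`.
#' @export
time_normalize <- function(t, x, y, n_points = 101L) {
  if (length(t) < 2) stop("time_normalize: need at least 2 samples")
  tn <- seq(t[1], t[length(t)], length.out = n_points)
  data.table::data.table(
    t_norm = seq(0, 1, length.out = n_points),
    x = approx(t, x, xout = tn, ties = "ordered")$y,
    y = approx(t, y, xout = tn, ties = "ordered")$y)
}

#' Mirror left-target trajectories and pool with right-target ones
#'
#' Left- and right-hand responses are mirror images; reflecting left-target
#' tracks across the vertical screen midline (`x -> 1 - x`) lets all trials
#' be averaged toward a common (right) target. Mirroring twice is the
#' identity.
#'
#' @param x_mat,y_mat matrices of normalized-time trajectories (trials in
#'   rows, time points in columns).
#' @param target_side `"left"`/`"right"` per trial.
#' @return list with mirrored `x_mat`, unchanged `y_mat`, the common
#'   `target_side = "right"`, and `mean_track` (column means of x and y).
#' @export
mirror_pool <- function(x_mat, y_mat, target_side) {
  x_mat <- as.matrix(x_mat); y_mat <- as.matrix(y_mat)
  stopifnot(nrow(x_mat) == length(target_side))
  left <- target_side == "left"
  x_mat[left, ] <- 1 - x_mat[left, ]
  list(x_mat = x_mat, y_mat = y_mat, target_side = "right",
       mean_track = data.table::data.table(x = colMeans(x_mat),
                                           y = colMeans(y_mat)))
}

#' Trajectory curvature: area between path and chord
#'
#' Signed area of the closed polygon formed by the trajectory and the
#' reversed straight chord from its start to its end point, by the shoelace
#' formula, in normalized screen units squared. The sign is positive when
#' the path bows to the left of the chord -- away from the (right) target,
#' toward the competing response -- so mirroring a trajectory negates it.
#' The absolute variant integrates the unsigned perpendicular deviation from
#' the chord along the chord, so opposite-side excursions cannot cancel.
#'
#' @param x,y trajectory coordinates (>= 3 samples).
#' @param px_scale optional `c(width, height)`; if supplied, areas are also
#'   returned in pixel^2 as attribute `"auc_px"`.
#' @return list with `auc_signed`, `auc_absolute`, `degenerate` (start ==
#'   end).
#' @export
#' @examples
#' compute_auc(c(0.5, 0.5, 1), c(0, 1, 1))$auc_signed # 0.25
compute_auc <- function(x, y, px_scale = NULL) {
  n <- length(x)
  if (n < 3) stop("compute_auc: need at least 3 samples")
  degenerate <- x[1] == x[n] && y[1] == y[n]
  # shoelace over path + reversed chord (the chord closes the polygon)
  cross_sum <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
  auc_signed <- -0.5 * cross_sum
  chord <- c(x[n] - x[1], y[n] - y[1])
  len <- sqrt(sum(chord^2))
  if (len == 0) {
    auc_absolute <- abs(auc_signed)
  } else {
    u <- chord / len
    dx <- x - x[1]; dy <- y - y[1]
    along <- dx * u[1] + dy * u[2]        # projection onto the chord
    dev <- dx * u[2] - dy * u[1]          # signed perpendicular deviation
    auc_absolute <- sum(abs(dev[-n] + dev[-1]) / 2 * diff(along))
  }
  out <- list(auc_signed = auc_signed, auc_absolute = auc_absolute,
              degenerate = degenerate)
  if (!is.null(px_scale))
    attr(out, "auc_px") <- c(signed = auc_signed, absolute = auc_absolute) *
      (px_scale[1] - 1) * (px_scale[2] - 1)
  out
}

#' Proportional Euclidean proximity to the target
#'
#' `p(t) = 1 - d(t) / max(d)` where `d` is the Euclidean distance from the
#' cursor to the response-target center; by default the maximum is taken
#' within the trial (the start point is typically the farthest), so `p = 0`
#' at the trial's most distant sample and `p = 1` on the target.
#'
#' @param x,y trajectory coordinates (normalized-time grid).
#' @param target target center, `c(x, y)`.
#' @param max_distance optional externally fixed scale (e.g. a
#'   per-condition maximum); default the within-trial maximum.
#' @return list with `p` (proximity at each sample) and `degenerate` (track
#'   starts on the target: a curve of ones).
#' @export
proximity_curve <- function(x, y, target = screen_geometry()$right,
                            max_distance = NULL) {
  d <- sqrt((x - target[1])^2 + (y - target[2])^2)
  dmax <- max_distance %||% max(d)
  if (dmax == 0) return(list(p = rep(1, length(d)), degenerate = TRUE))
  list(p = 1 - d / dmax, degenerate = FALSE)
}

#' Running (sample-by-sample) paired t-test
#'
#' At each normalized time point, a two-tailed paired t-test compares the
#' two condition curves across subjects; contiguous runs of samples with
#' `p < alpha` locate when the conditions diverge. If the paired differences
#' at a sample have zero variance, `p` is 1 when they are all zero and 0
#' when they are a nonzero constant.
#'
#' @param a,b numeric matrices (subjects in rows, time points in columns),
#'   paired by row.
#' @param alpha significance level (default 0.01).
#' @param min_run minimum run length to report.
#' @return list with `stats` (data.table: `index`, `t`, `p`, `significant`)
#'   and `runs` (data.table: `start`, `end`, `length`, `t_norm_start`,
#'   `t_norm_end`).
#' @export
running_ttest <- function(a, b, alpha = 0.01, min_run = 1L) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(identical(dim(a), dim(b)))
  n <- nrow(a)
  if (n < 3) stop("running_ttest: need at least 3 subject pairs")
  d <- a - b
  m <- colMeans(d)
  s <- apply(d, 2, sd)
  tt <- ifelse(s > 0, m / (s / sqrt(n)), ifelse(m == 0, 0, Inf * sign(m)))
  p <- ifelse(s > 0, 2 * pt(-abs(tt), df = n - 1), ifelse(m == 0, 1, 0))
  sig <- p < alpha
  T_ <- ncol(a)
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  tgrid <- seq(0, 1, length.out = T_)
  runs <- data.table::data.table(
    start = starts[keep], end = ends[keep], length = r$lengths[keep],
    t_norm_start = tgrid[starts[keep]], t_norm_end = tgrid[ends[keep]])
  list(stats = data.table::data.table(index = seq_len(T_), t = tt, p = p,
                                      significant = sig),
       runs = runs)
}

# split the long log into per-trial trajectory pieces for the given tokens
endpoint_trials <- function(log, tokens) {
  traj <- log[!is.na(sample_t_ms) & token %in% tokens]
  if (nrow(traj) == 0) stop("no trajectory samples for the requested tokens")
  traj
}

#' Per-trial trajectory geometry
#'
#' Time-normalizes each trial's trajectory, mirrors left-target (/u/)
#' responses onto the right target, and computes the area between path and
#' chord. By default only the continuum endpoint tokens are analyzed
#' (endpoint pooling toward the category prototype); pass
#' `tokens = 1:n` for per-token output.
#'
#' @param log a long-format trial log with trajectory samples.
#' @param tokens tokens to include (default the two endpoints).
#' @param n_points normalized-time grid size.
#' @return a data.table with one row per trial: identifiers, condition
#'   labels, `auc_signed`, `auc_absolute`, plus the normalized track in list
#'   columns `x_norm`, `y_norm`.
#' @export
track_geometry <- function(log, tokens = range(log$token), n_points = 101L) {
  traj <- endpoint_trials(log, tokens)
  geom <- traj[, {
    tn <- time_normalize(sample_t_ms, sample_x, sample_y, n_points)
    xs <- tn$x; ys <- tn$y
    if (response[1] == "u") xs <- 1 - xs      # mirror left-target trials
    a <- compute_auc(xs, ys)
    .(token = token[1], order = order[1], snr = snr[1],
      response = response[1], rt_ms = rt_ms[1],
      auc_signed = a$auc_signed, auc_absolute = a$auc_absolute,
      x_norm = list(xs), y_norm = list(ys))
  }, by = .(subject_id, block_id, trial_index)]
  geom[]
}

#' Subject-level proximity curves per condition
#'
#' Computes the proximity of each (mirrored, time-normalized) endpoint-token
#' trajectory to the target, averages within subject for every
#' `snr x order-class` cell (serial = forward and reverse pooled), and
#' returns one curve per subject and condition. Averaging is trial ->
#' subject -> grand mean, so paired tests operate on subject curves.
#'
#' @param geom output of [track_geometry()].
#' @param target target center (right box).
#' @return a data.table with `subject_id`, `snr`, `condition`, and matrix
#'   column-compatible `p_1 ... p_T` proximity values in a list column `p`;
#'   plus helper [proximity_matrix()] to extract condition matrices.
#' @export
condition_proximity <- function(geom, target = screen_geometry()$right) {
  per_trial <- geom[, {
    pc <- proximity_curve(x_norm[[1]], y_norm[[1]], target)
    .(p = list(pc$p))
  }, by = .(subject_id, block_id, trial_index, snr,
            condition = order_class(order))]
  per_trial[, {
    m <- do.call(rbind, p)
    .(p = list(colMeans(m)), n_trials = nrow(m))
  }, by = .(subject_id, snr, condition)]
}

#' Extract a subjects-by-time matrix for one condition
#'
#' @param prox output of [condition_proximity()].
#' @param snr_label,condition_label condition selectors.
#' @return numeric matrix (subjects x time), rows ordered by subject id.
#' @export
proximity_matrix <- function(prox, snr_label, condition_label) {
  sel <- prox[snr == snr_label & condition == condition_label]
  data.table::setorder(sel, subject_id)
  m <- do.call(rbind, sel$p)
  rownames(m) <- sel$subject_id
  m
}
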