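# Trial-level conflict metrics: reaction time, signed maximum absolute
# deviation, sample entropy, and condition-average trajectories.

#' Reaction time of a trial
#'
#' Time from the start of cursor movement (the first retained sample, at
#' `t_ms = 0` by construction) to the click on the response box.
#'
#' @param traj A `uti_trajectory` with timestamps.
#' @return Reaction time in milliseconds.
#' @export
reaction_time <- function(traj) {
  stopifnot(inherits(traj, "uti_trajectory"))
  t <- traj$t_ms
  if (is.null(t)) stop("trajectory has no timestamps", call. = FALSE)
  t[length(t)] - t[1]
}

# Reference point on the conflict side (toward the non-chosen response
# box) for the MAD sign, in the trajectory's own frame.
conflict_reference <- function(traj) {
  if (traj$frame == "unit") {
    n <- nrow(traj$points)
    end_x <- traj$points[n, 1]
    c(if (end_x >= 0) -1 else 1, 1)
  } else {
    # pixel frame: reflect the click about the start column; the competing
    # box sits at the mirrored horizontal position at the same height
    c(2 * traj$start[1] - traj$click[1], traj$click[2])
  }
}

#' Signed maximum absolute deviation (MAD)
#'
#' The largest perpendicular (point-to-line) deviation of the resampled
#' path from the straight trajectory connecting its first and last points.
#' Reported in the trajectory's own frame (pixels when computed before
#' remapping, unit-frame values after). The value is signed positive when
#' the extreme point lies on the side of the straight line toward the
#' non-chosen response box - the direction of attraction toward the
#' competing alternative - and negative otherwise.
#'
#' @param traj A `uti_trajectory` with `arc_length` parameterization
#'   (spatially normalized).
#' @return A single signed number; `NA` for degenerate trajectories (and
#'   the input is flagged when first and last points coincide).
#' @export
mad_signed <- function(traj) {
  stopifnot(inherits(traj, "uti_trajectory"))
  if (traj$degenerate) return(NA_real_)
  if (traj$parameterization != "arc_length") {
    stop("mad_signed() expects a spatially normalized (arc_length) trajectory",
         call. = FALSE)
  }
  pts <- traj$points
  n <- nrow(pts)
  p1 <- pts[1, ]; p2 <- pts[n, ]
  chord <- p2 - p1
  len <- sqrt(sum(chord^2))
  if (len == 0) return(NA_real_)
  # signed point-to-line distance via the 2D cross product
  d <- (chord[1] * (pts[, 2] - p1[2]) - chord[2] * (pts[, 1] - p1[1])) / len
  ref <- conflict_reference(traj)
  ref_side <- sign(chord[1] * (ref[2] - p1[2]) - chord[2] * (ref[1] - p1[1]))
  if (ref_side == 0) ref_side <- 1
  i_max <- which.max(abs(d))
  unname(d[i_max] * ref_side)
}

#' Sample entropy of a series
#'
#' Regularity statistic SampEn(m, r): the negative logarithm of the
#' conditional probability that two subsequences that match within
#' tolerance `r` for `m` consecutive points still match at length `m + 1`.
#' Matches use the Chebyshev (maximum-coordinate) distance and exclude
#' self-matches; the tolerance is expressed as a fraction of the series
#' standard deviation, which makes the statistic invariant to affine
#' transformations of the series.
#'
#' Degenerate cases (zero variance, or no template matches at either
#' length) return 0 with attribute `degenerate = TRUE`, so that perfectly
#' regular series sort below irregular ones instead of propagating
#' infinities.
#'
#' @param series Numeric vector (for trajectories, conventionally the
#'   x-coordinate of the time-normalized 101-point path, where lateral
#'   motion carries the conflict signal).
#' @param m Template length (default 2).
#' @param r_frac Tolerance as a fraction of `sd(series)` (default 0.2).
#' @return SampEn value (dimensionless), possibly with attribute
#'   `degenerate`.
#' @export
sample_entropy <- function(series, m = 2, r_frac = 0.2) {
  n <- length(series)
  if (n < m + 2) {
    stop(sprintf("series too short for sample entropy (need >= %d, got %d)",
                 m + 2, n), call. = FALSE)
  }
  s <- sd(series)
  if (!is.finite(s) || s == 0) {
    return(structure(0, degenerate = TRUE))
  }
  r <- r_frac * s
  # both template lengths use the same n - m starting indices
  nt <- n - m
  base <- abs(outer(series, series, "-"))
  dist_m <- base[seq_len(nt), seq_len(nt), drop = FALSE]
  if (m > 1) {
    for (k in seq_len(m - 1)) {
      dist_m <- pmax(dist_m, base[seq_len(nt) + k, seq_len(nt) + k,
                                  drop = FALSE])
    }
  }
  match_m <- dist_m <= r
  dist_m1 <- pmax(dist_m, base[seq_len(nt) + m, seq_len(nt) + m,
                               drop = FALSE])
  match_m1 <- dist_m1 <= r
  # pairs i != j; subtract the diagonal self-matches
  B <- (sum(match_m) - nt) / 2
  A <- (sum(match_m1) - nt) / 2
  if (A == 0 || B == 0) {
    return(structure(0, degenerate = TRUE))
  }
  -log(A / B)
}

#' Pointwise average trajectory of a group of trials
#'
#' Averages spatially normalized, mirrored unit-frame trajectories point by
#' point, the representation used to visualize how far healthy versus
#' unhealthy trials bend toward the competing response box.
#'
#' @param trajs Non-empty list of `uti_trajectory` objects, all unit-frame,
#'   mirrored, `arc_length`-parameterized with the same point count.
#' @param group Label for the averaged group.
#' @return An object of class `uti_avg_trajectory`: list with `group`,
#'   `points` (mean x/y matrix) and `n_trials`.
#' @export
average_trajectory <- function(trajs, group = "all") {
  if (length(trajs) == 0) stop("empty trajectory list", call. = FALSE)
  for (tr in trajs) {
    stopifnot(inherits(tr, "uti_trajectory"))
    if (tr$frame != "unit" || !tr$mirrored ||
        tr$parameterization != "arc_length") {
      stop("average_trajectory() expects mirrored unit-frame arc_length trajectories",
           call. = FALSE)
    }
  }
  npts <- vapply(trajs, function(tr) nrow(tr$points), integer(1))
  if (length(unique(npts)) != 1) {
    stop("trajectories have differing point counts", call. = FALSE)
  }
  acc <- Reduce(`+`, lapply(trajs, function(tr) tr$points))
  structure(
    list(group = group, points = acc / length(trajs),
         n_trials = length(trajs)),
    class = "uti_avg_trajectory"
  )
}

#' @export
print.uti_avg_trajectory <- function(x, ...) {
  cat(sprintf("<uti_avg_trajectory '%s': mean of %d trials, %d points>\n",
              x$group, x$n_trials, nrow(x$points)))
  invisible(x)
}

#' Maximum deviation of an average trajectory from its chord
#'
#' Convenience summary of an [average_trajectory()]: the largest absolute
#' perpendicular distance of the mean path from the straight line between
#' its endpoints.
#'
#' @param avg A `uti_avg_trajectory`.
#' @return Non-negative number in the unit frame.
#' @export
avg_trajectory_deviation <- function(avg) {
  stopifnot(inherits(avg, "uti_avg_trajectory"))
  pts <- avg$points
  n <- nrow(pts)
  chord <- pts[n, ] - pts[1, ]
  len <- sqrt(sum(chord^2))
  if (len == 0) return(NA_real_)
  d <- (chord[1] * (pts[, 2] - pts[1, 2]) -
          chord[2] * (pts[, 1] - pts[1, 1])) / len
  max(abs(d))
}

#' Compute trial-level metrics for a whole dataset
#'
#' Runs the full per-trial pipeline: build raw trajectories, spatially
#' normalize in the pixel frame for the px-scale MAD, remap and mirror to
#' the unit frame for the unit-scale MAD, and (optionally) temporally
#' normalize for sample entropy. Degenerate trials (zero extent or zero
#' path length) get `NA` metrics and `degenerate = TRUE`; exclusion flags
#' are initialized `FALSE` and are set later by [exclude_outliers()].
#'
#' @param samples,trials Tibbles as returned by [read_samples()] /
#'   [read_trials()] (or [simulate_cohort()]).
#' @param n_points Resampling resolution (101 reference).
#' @param sampen Logical: compute sample entropy (the costliest metric)?
#' @param sampen_m,sampen_r_frac Sample-entropy parameters, see
#'   [sample_entropy()].
#' @return A tibble: `participant_id, trial_id, rt_ms, mad_px, mad_unit,
#'   sample_entropy, degenerate, excluded_rt, excluded_mad`.
#' @export
compute_trial_metrics <- function(samples, trials, n_points = 101,
                                  sampen = TRUE, sampen_m = 2,
                                  sampen_r_frac = 0.2) {
  trajs <- build_trajectories(samples, trials)
  k <- length(trajs)
  rt <- mad_px <- mad_unit <- se <- rep(NA_real_, k)
  deg <- logical(k)
  pid <- tid <- character(k)
  for (i in seq_len(k)) {
    tr <- trajs[[i]]
    pid[i] <- tr$participant_id
    tid[i] <- tr$trial_id
    rt[i] <- reaction_time(tr)
    px_arc <- resample_spatial(tr, n_points)
    unit <- remap_coordinates(tr)
    if (px_arc$degenerate || unit$degenerate) {
      deg[i] <- TRUE
      next
    }
    mad_px[i] <- mad_signed(px_arc)
    unit_arc <- mirror_to_right(resample_spatial(unit, n_points))
    mad_unit[i] <- mad_signed(unit_arc)
    if (sampen) {
      tem <- resample_temporal(unit, n_points)
      se[i] <- as.numeric(sample_entropy(tem$points[, 1], m = sampen_m,
                                         r_frac = sampen_r_frac))
    }
  }
  tibble::tibble(
    participant_id = pid, trial_id = tid, rt_ms = rt,
    mad_px = mad_px, mad_unit = mad_unit, sample_entropy = se,
    degenerate = deg, excluded_rt = FALSE, excluded_mad = FALSE
  )
}

#' Mirrored unit-frame 101-point trajectories for a dataset
#'
#' Convenience wrapper producing the representation [average_trajectory()]
#' consumes, in trial-table order (degenerate trials are dropped).
#'
#' @inheritParams compute_trial_metrics
#' @return A list of mirrored unit-frame `uti_trajectory` objects.
#' @export
unit_trajectories <- function(samples, trials, n_points = 101) {
  trajs <- build_trajectories(samples, trials)
  out <- lapply(trajs, function(tr) {
    u <- remap_coordinates(tr)
    if (u$degenerate) return(NULL)
    u <- resample_spatial(u, n_points)
    if (u$degenerate) return(NULL)
    mirror_to_right(u)
  })
  out[!vapply(out, is.null, logical(1))]
}
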