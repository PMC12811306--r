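# Trajectory preprocessing: per-trial coordinate remap, mirroring, and
# spatial/temporal resampling to the canonical 101-point representation.

#' Construct a raw trajectory
#'
#' Bundles one trial's ordered cursor samples with the geometry needed to
#' remap it: the point where the cursor left the start button and the pixel
#' actually clicked. Timestamps are expected rebased so the first retained
#' sample is at `t_ms = 0` (tracking starts when the cursor leaves the
#' start button).
#'
#' @param participant_id,trial_id Identifiers.
#' @param t_ms Numeric vector of timestamps (ms), strictly increasing from 0.
#' @param x_px,y_px Cursor position in screen pixels (y grows downward).
#' @param start Length-2 numeric, the exit point of the start button (px).
#' @param click Length-2 numeric, the clicked pixel (px).
#' @param response_side `"left"` or `"right"`.
#' @return An object of class `uti_trajectory` in the `pixel` frame with
#'   `raw` parameterization.
#' @export
raw_trajectory <- function(participant_id, trial_id, t_ms, x_px, y_px,
                           start, click, response_side) {
  n <- length(t_ms)
  if (n < 2) {
    stop("a trajectory needs at least 2 samples", call. = FALSE)
  }
  if (t_ms[1] != 0) {
    stop("timestamps must be rebased so the first sample is at t_ms = 0",
         call. = FALSE)
  }
  if (any(diff(t_ms) <= 0)) {
    stop(sprintf("trial %s/%s: t_ms not strictly increasing",
                 participant_id, trial_id), call. = FALSE)
  }
  end_gap <- sqrt((x_px[n] - click[1])^2 + (y_px[n] - click[2])^2)
  if (end_gap > 1 + 1e-9) {
    stop(sprintf(
      "trial %s/%s: last sample is %.2f px from the click point (max 1 px)",
      participant_id, trial_id, end_gap), call. = FALSE)
  }
  structure(
    list(
      participant_id = participant_id,
      trial_id = trial_id,
      points = cbind(x = x_px, y = y_px),
      t_ms = t_ms,
      frame = "pixel",
      parameterization = "raw",
      mirrored = FALSE,
      start = as.numeric(start),
      click = as.numeric(click),
      response_side = response_side,
      degenerate = FALSE,
      degenerate_reason = NA_character_
    ),
    class = "uti_trajectory"
  )
}

#' @export
print.uti_trajectory <- function(x, ...) {
  cat(sprintf(
    "<uti_trajectory %s/%s: %d points, frame=%s, parameterization=%s%s%s>\n",
    x$participant_id, x$trial_id, nrow(x$points), x$frame,
    x$parameterization, if (x$mirrored) ", mirrored" else "",
    if (x$degenerate) paste0(", DEGENERATE (", x$degenerate_reason, ")") else ""))
  invisible(x)
}

mark_degenerate <- function(traj, reason) {
  traj$degenerate <- TRUE
  traj$degenerate_reason <- reason
  traj
}

#' Remap a trajectory into the unit coordinate frame
#'
#' Applies the per-trial affine transformation used to pool trials with
#' different screen geometries: the cursor's exit point from the start
#' button maps to (0, 0) and the clicked pixel maps to (-1, 1) for a left
#' response or (1, 1) for a right response. Each axis is scaled
#' independently, which also flips screen y so that "up" (toward the
#' response boxes) is positive.
#'
#' Trials whose start and click coincide on either axis cannot be anchored;
#' they are flagged degenerate (the points are left untouched) rather than
#' dropped silently.
#'
#' @param traj A `uti_trajectory` in the `pixel` frame.
#' @return The trajectory in the `unit` frame.
#' @export
remap_coordinates <- function(traj) {
  stopifnot(inherits(traj, "uti_trajectory"))
  if (traj$frame != "pixel") {
    stop("remap_coordinates() expects a pixel-frame trajectory", call. = FALSE)
  }
  sx <- traj$start[1]; sy <- traj$start[2]
  cx <- traj$click[1]; cy <- traj$click[2]
  if (cx == sx || cy == sy) {
    return(mark_degenerate(traj, "zero horizontal or vertical extent"))
  }
  tx <- if (traj$response_side == "left") -1 else 1
  # y target is +1; screen y decreases toward the top, so (y - sy)/(cy - sy)
  # flips the axis as a side effect of cy < sy
  new_pts <- cbind(
    x = (traj$points[, 1] - sx) * tx / (cx - sx),
    y = (traj$points[, 2] - sy) / (cy - sy)
  )
  traj$points <- new_pts
  traj$frame <- "unit"
  traj$start <- c(0, 0)
  traj$click <- c(tx, 1)
  traj
}

#' Mirror a unit-frame trajectory onto the right side
#'
#' Left responses are reflected about the vertical midline (x negated) so
#' that every trajectory ends at (1, 1) and trials can be averaged across
#' response sides. Idempotent; right-ending trajectories pass through
#' unchanged but are still tagged as mirrored.
#'
#' @param traj A `uti_trajectory` in the `unit` frame.
#' @return The mirrored trajectory (`mirrored = TRUE`).
#' @export
mirror_to_right <- function(traj) {
  stopifnot(inherits(traj, "uti_trajectory"))
  if (traj$frame != "unit") {
    stop("mirror_to_right() expects a unit-frame trajectory", call. = FALSE)
  }
  n <- nrow(traj$points)
  if (traj$points[n, 1] < 0) {
    traj$points[, 1] <- -traj$points[, 1]
    traj$click[1] <- -traj$click[1]
    traj$start[1] <- -traj$start[1]
    traj$response_side <- "right"
  }
  traj$mirrored <- TRUE
  traj
}

# Cumulative arc length of a polyline (first entry 0).
arc_lengths <- function(pts) {
  seg <- sqrt(rowSums(diff(pts)^2))
  c(0, cumsum(seg))
}

#' Resample a trajectory at equidistant points along its path
#'
#' Spatial normalization: the polyline is re-parameterized by cumulative
#' arc length and linearly interpolated at `n` equally spaced distances
#' covering 0-100% of the movement distance, so every trial is described by
#' the same number of points regardless of its duration. Endpoints are
#' preserved exactly. Timestamps do not survive spatial resampling.
#'
#' @param traj A `uti_trajectory` (any frame).
#' @param n Number of output points (101 in the reference analysis:
#'   0-100% of the movement distance in 1% steps).
#' @return The trajectory with `n` points and `arc_length`
#'   parameterization; degenerate (zero-length) paths are flagged.
#' @export
resample_spatial <- function(traj, n = 101) {
  stopifnot(inherits(traj, "uti_trajectory"))
  if (traj$degenerate) return(traj)
  pts <- traj$points
  if (nrow(pts) < 2) stop("need at least 2 samples", call. = FALSE)
  cum <- arc_lengths(pts)
  total <- cum[length(cum)]
  if (total <= 0) {
    return(mark_degenerate(traj, "zero path length"))
  }
  keep <- c(TRUE, diff(cum) > 0)
  cum_k <- cum[keep]
  xs <- pts[keep, 1]; ys <- pts[keep, 2]
  s_out <- seq(0, total, length.out = n)
  new_pts <- cbind(
    x = approx(cum_k, xs, xout = s_out, rule = 2)$y,
    y = approx(cum_k, ys, xout = s_out, rule = 2)$y
  )
  new_pts[1, ] <- pts[1, ]
  new_pts[n, ] <- pts[nrow(pts), ]
  traj$points <- new_pts
  traj$t_ms <- NULL
  traj$parameterization <- "arc_length"
  traj
}

#' Resample a trajectory at equally spaced time points
#'
#' Temporal normalization: x and y are linearly interpolated at `n` equally
#' spaced times between the first and last timestamps. This is the input
#' convention for [sample_entropy()], which needs a uniformly sampled
#' series.
#'
#' @param traj A `uti_trajectory` with timestamps.
#' @param n Number of output points.
#' @return The trajectory with `n` points, `time` parameterization, and
#'   the resampled `t_ms` grid.
#' @export
resample_temporal <- function(traj, n = 101) {
  stopifnot(inherits(traj, "uti_trajectory"))
  if (traj$degenerate) return(traj)
  t <- traj$t_ms
  if (is.null(t)) {
    stop("temporal resampling needs timestamps (raw parameterization)",
         call. = FALSE)
  }
  if (any(duplicated(t))) {
    stop(sprintf("trial %s/%s: duplicate timestamps",
                 traj$participant_id, traj$trial_id), call. = FALSE)
  }
  t_out <- seq(t[1], t[length(t)], length.out = n)
  new_pts <- cbind(
    x = approx(t, traj$points[, 1], xout = t_out)$y,
    y = approx(t, traj$points[, 2], xout = t_out)$y
  )
  traj$points <- new_pts
  traj$t_ms <- t_out
  traj$parameterization <- "time"
  traj
}

#' Split sample and trial tables into raw trajectories
#'
#' Groups the long-format sample log by trial and attaches each trial's
#' geometry, producing the `uti_trajectory` objects the preprocessing and
#' metric functions consume. Sample rows are matched to trials by
#' `(participant_id, trial_id)`; trials without samples are skipped (the
#' validator reports them).
#'
#' @param samples,trials Tibbles as returned by [read_samples()] and
#'   [read_trials()].
#' @return A list of `uti_trajectory` objects, one per trial with samples,
#'   in trial-table order.
#' @export
build_trajectories <- function(samples, trials) {
  key_s <- paste(samples$participant_id, samples$trial_id, sep = "\r")
  key_t <- paste(trials$participant_id, trials$trial_id, sep = "\r")
  idx <- split(seq_len(nrow(samples)), factor(key_s, levels = key_t))
  out <- vector("list", nrow(trials))
  kept <- logical(nrow(trials))
  for (i in seq_len(nrow(trials))) {
    rows <- idx[[i]]
    if (is.null(rows) || length(rows) == 0) next
    rows <- rows[order(samples$t_ms[rows])]
    out[[i]] <- raw_trajectory(
      trials$participant_id[i], trials$trial_id[i],
      samples$t_ms[rows], samples$x_px[rows], samples$y_px[rows],
      start = c(trials$start_x_px[i], trials$start_y_px[i]),
      click = c(trials$click_x_px[i], trials$click_y_px[i]),
      response_side = trials$response_side[i]
    )
    kept[i] <- TRUE
  }
  out[kept]
}

#' Export resampled trajectories as a long table
#'
#' @param trajs A list of `uti_trajectory` objects sharing one point count.
#' @return A tibble `participant_id, trial_id, point_index, x, y, frame,
#'   parameterization` with `point_index` running 0..n-1.
#' @export
trajectories_to_table <- function(trajs) {
  dplyr::bind_rows(lapply(trajs, function(tr) {
    n <- nrow(tr$points)
    tibble::tibble(
      participant_id = tr$participant_id,
      trial_id = tr$trial_id,
      point_index = seq_len(n) - 1L,
      x = tr$points[, 1],
      y = tr$points[, 2],
      frame = tr$frame,
      parameterization = tr$parameterization
    )
  }))
}
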