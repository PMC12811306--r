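# Independent oracle implementations and small fixture builders used
# across the suite. Oracles deliberately take different computational
# routes than the package functions they check.

# Build a uti_trajectory from bare points (pixel frame unless told
# otherwise), with constant-rate timestamps.
make_traj <- function(x, y, response_side = "right",
                      start = c(x[1], y[1]),
                      click = c(x[length(x)], y[length(y)]),
                      t_ms = seq(0, by = 10, length.out = length(x))) {
  raw_trajectory("p1", "t1", t_ms, x, y, start = start, click = click,
                 response_side = response_side)
}

# A unit-frame, mirrored, arc-length trajectory directly from points
# (bypasses remapping; for geometry tests on synthetic paths).
make_unit_arc <- function(pts, mirrored = TRUE) {
  structure(
    list(participant_id = "p1", trial_id = "t1",
         points = cbind(x = pts[, 1], y = pts[, 2]), t_ms = NULL,
         frame = "unit", parameterization = "arc_length",
         mirrored = mirrored, start = pts[1, ], click = pts[nrow(pts), ],
         response_side = if (pts[nrow(pts), 1] < 0) "left" else "right",
         degenerate = FALSE, degenerate_reason = NA_character_),
    class = "uti_trajectory")
}

# Oracle: maximum point-to-line distance via orthogonal projection
# (vector rejection), an independent route from the cross-product form.
oracle_max_perp <- function(pts) {
  a <- pts[1, ]; b <- pts[nrow(pts), ]
  u <- (b - a) / sqrt(sum((b - a)^2))
  dmax <- 0
  for (i in seq_len(nrow(pts))) {
    v <- pts[i, ] - a
    rej <- v - sum(v * u) * u
    dmax <- max(dmax, sqrt(sum(rej^2)))
  }
  dmax
}

# Oracle: arc-length position of each point of a resampled path on the
# original polyline (walks segments; tolerates tiny perpendicular gaps).
oracle_arc_positions <- function(orig, resampled) {
  seg_start <- orig[-nrow(orig), , drop = FALSE]
  seg_end <- orig[-1, , drop = FALSE]
  seg_len <- sqrt(rowSums((seg_end - seg_start)^2))
  cum0 <- c(0, cumsum(seg_len))
  vapply(seq_len(nrow(resampled)), function(i) {
    p <- resampled[i, ]
    best <- Inf; best_s <- NA_real_
    for (s in seq_len(nrow(seg_start))) {
      if (seg_len[s] == 0) next
      d <- seg_end[s, ] - seg_start[s, ]
      t <- sum((p - seg_start[s, ]) * d) / sum(d^2)
      t <- min(1, max(0, t))
      proj <- seg_start[s, ] + t * d
      gap <- sqrt(sum((p - proj)^2))
      if (gap < best) {
        best <- gap
        best_s <- cum0[s] + t * seg_len[s]
      }
    }
    best_s
  }, numeric(1))
}

# Oracle: O(n^2) literal template-counting sample entropy.
oracle_sampen <- function(x, m, r_frac) {
  n <- length(x)
  r <- r_frac * sd(x)
  count_matches <- function(len) {
    nt <- n - m            # same template count for both lengths
    cnt <- 0L
    for (i in seq_len(nt - 1)) {
      for (j in (i + 1):nt) {
        if (max(abs(x[i:(i + len - 1)] - x[j:(j + len - 1)])) <= r) {
          cnt <- cnt + 1L
        }
      }
    }
    cnt
  }
  B <- count_matches(m)
  A <- count_matches(m + 1)
  if (A == 0 || B == 0) return(0)
  -log(A / B)
}

# Oracle: textbook Welch statistic and Satterthwaite df.
oracle_welch <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# Oracle: correlation from raw sums (computational formula), p from t.
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), n - 2))
}

# Oracle: Cronbach's alpha from the covariance matrix route.
oracle_alpha <- function(m) {
  S <- cov(m)
  k <- ncol(m)
  k / (k - 1) * (1 - sum(diag(S)) / sum(S))
}

# Oracle: F-change from explicit least-squares residual sums of squares
# computed via QR projections.
oracle_f_change <- function(y, X_r, X_f) {
  rss <- function(X) {
    q <- qr(X)
    sum((y - X %*% qr.coef(q, y))^2)
  }
  rss_r <- rss(X_r); rss_f <- rss(X_f)
  df_f <- length(y) - ncol(X_f)
  f <- (rss_r - rss_f) / (rss_f / df_f)
  list(f = f, df2 = df_f, p = pf(f, 1, df_f, lower.tail = FALSE))
}

# Random piecewise-linear trajectory in unit-frame-like coordinates.
random_polyline <- function(n_pts = 8, scale = 1) {
  cbind(x = cumsum(runif(n_pts, 0.05, 1)) * scale,
        y = cumsum(runif(n_pts, -0.5, 1)) * scale)
}

# Minimal three-table fixture: 2 participants x 4 trials with clean
# straight-line cursor paths (geometry matches the default task layout).
tiny_dataset <- function() {
  start <- c(960, 980); left <- c(160, 80); right <- c(1760, 80)
  trials <- list(); samples <- list()
  spec <- expand.grid(pid = c("p01", "p02"), j = 1:4,
                      stringsAsFactors = FALSE)
  spec <- spec[order(spec$pid, spec$j), ]
  for (k in seq_len(nrow(spec))) {
    pid <- spec$pid[k]; j <- spec$j[k]
    food <- if (j %% 2 == 1) "healthy" else "unhealthy"
    tasty <- j <= 2
    box <- if (tasty) left else right
    nsteps <- 10 + j
    tseq <- seq(0, by = 10, length.out = nsteps + 1)
    frac <- seq(0, 1, length.out = nsteps + 1)
    trials[[k]] <- tibble::tibble(
      participant_id = pid, trial_id = paste0("t", j),
      stimulus_id = paste0("s", j), food_type = food,
      classification = if (tasty) "tasty" else "not_tasty",
      response_side = if (tasty) "left" else "right",
      presentation_index = j,
      start_x_px = start[1], start_y_px = start[2],
      click_x_px = box[1], click_y_px = box[2])
    samples[[k]] <- tibble::tibble(
      participant_id = pid, trial_id = paste0("t", j), t_ms = tseq,
      x_px = start[1] + frac * (box[1] - start[1]),
      y_px = start[2] + frac * (box[2] - start[2]))
  }
  participants <- tibble::tibble(
    participant_id = c("p01", "p02"), age = c(30, 45),
    gender = c("female", "male"), education = c("bachelor", "master"),
    condition = "none",
    uti_item_1 = c(2, 6), uti_item_2 = c(3, 6), uti_item_3 = c(2, 7))
  for (kk in 1:20) participants[[paste0("ffq_", kk)]] <- c(4L, 4L)
  list(samples = dplyr::bind_rows(samples),
       trials = dplyr::bind_rows(trials),
       participants = participants)
}
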