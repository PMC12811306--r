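# Synthetic-cohort simulator: agents with a latent UTI trait produce
# choices, cursor trajectories, explicit-scale and FFQ responses in the
# exact three-table interchange format, with ground truth retained for
# recovery testing.

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

#' Simulation configuration
#'
#' All generative parameters of the synthetic cohort, with defaults that
#' emulate the reference task design: 10 healthy + 10 unhealthy stimuli
#' shown twice (40 trials per participant), a 1920 x 1080 screen with the
#' start button at the bottom center and response boxes in the upper
#' corners ("tasty" upper-left), and 100-Hz cursor sampling.
#'
#' The latent model: each agent draws a UTI trait `u ~ N(0, 1)`; a hedonic
#' goal condition shifts the momentarily active trait to
#' `u* = u + delta_cond` (state activation on top of a stable trait).
#' Choices follow `P(tasty) = logistic(alpha0 + alpha1 * [unhealthy] -
#' alpha2 * max(u*, 0) * [healthy])`, so stronger UTI reduces tasty
#' judgments of healthy foods only. Trial conflict is
#' `softplus(kappa0 + kappa1 * u* * [healthy & tasty] + kappa2 *
#' [not tasty])`: the UTI cost concentrates on trials where a healthy item
#' is affirmed as tasty, and "not tasty" responses carry a general
#' conflict bump. Conflict lengthens movement time (`gamma_ms` per unit)
#' and pulls the cursor toward the competing response box (`pull_px` per
#' 10-ms step per unit).
#'
#' Self-reports are driven by an explicit belief factor
#' `e = rho_explicit * u + sqrt(1 - rho_explicit^2) * nu`, `nu ~ N(0,1)`:
#' the scale items load on `e` with loading `lambda` and item noise
#' `sigma_item`. A reliable scale (high inter-item agreement) can thus
#' still correlate only moderately with the trait that drives behavior -
#' the dissociation characteristic of implicit-explicit measurement,
#' without which a reliable scale would pin the behavioral validity
#' correlations near 1. The diet quality score targets
#' `10 - dqs_slope * u` with noise `sigma_dqs` (diet follows the
#' behavioral trait), and FFQ responses are constructed to score to that
#' target under the default DQS configuration.
#'
#' @param n_participants Number of agents.
#' @param seed Integer seed; the same seed reproduces the tables
#'   bit-identically.
#' @param n_healthy_stimuli,n_unhealthy_stimuli,repetitions Task design
#'   (defaults 10, 10, 2).
#' @param screen,start_px,left_box_px,right_box_px Geometry in pixels
#'   (screen y grows downward).
#' @param dt_ms Cursor sampling interval (10 ms = 100 Hz).
#' @param kappa0,kappa1,kappa2 Conflict intercept, healthy-tasty x UTI
#'   slope, and not-tasty bump.
#' @param delta_cond Latent-trait shift in the hedonic condition.
#' @param alpha0,alpha1,alpha2 Choice-model logits: baseline tasty logit,
#'   unhealthy bonus, healthy x UTI penalty.
#' @param lambda,sigma_item Explicit-scale loading and item noise.
#' @param rho_explicit Correlation between the explicit belief factor and
#'   the behavioral trait `u`.
#' @param dqs_slope,sigma_dqs Diet-quality dependence on the trait and its
#'   noise.
#' @param base_duration_ms,gamma_ms Movement duration intercept and
#'   conflict slope (before multiplicative lognormal noise
#'   `sigma_duration` on the log scale).
#' @param pull_px Lateral pull toward the competing box, px per step per
#'   conflict unit, decaying linearly to zero over the first half of the
#'   movement.
#' @param sigma_xy Positional Gaussian noise per step (px).
#' @param capture_radius_px Radius around the click point that terminates
#'   the movement.
#' @param step_cap Hard cap on steps per trial (guards pathological
#'   configurations).
#' @return A list of class `uti_sim_config`.
#' @export
sim_config <- function(n_participants = 200,
                       seed = 1L,
                       n_healthy_stimuli = 10,
                       n_unhealthy_stimuli = 10,
                       repetitions = 2,
                       screen = c(1920, 1080),
                       start_px = c(960, 980),
                       left_box_px = c(160, 80),
                       right_box_px = c(1760, 80),
                       dt_ms = 10,
                       kappa0 = 0.5,
                       kappa1 = 0.55,
                       kappa2 = 1.5,
                       delta_cond = 0.5,
                       alpha0 = 1.1,
                       alpha1 = 0.5,
                       alpha2 = 1.0,
                       lambda = 1.3,
                       sigma_item = 0.9,
                       rho_explicit = 0.55,
                       dqs_slope = 0.8,
                       sigma_dqs = 2.0,
                       base_duration_ms = 800,
                       gamma_ms = 110,
                       pull_px = 2.6,
                       sigma_xy = 7,
                       sigma_duration = 0.13,
                       capture_radius_px = 2,
                       step_cap = 10000) {
  cfg <- list(
    n_participants = as.integer(n_participants), seed = as.integer(seed),
    n_healthy_stimuli = as.integer(n_healthy_stimuli),
    n_unhealthy_stimuli = as.integer(n_unhealthy_stimuli),
    repetitions = as.integer(repetitions),
    screen = screen, start_px = start_px, left_box_px = left_box_px,
    right_box_px = right_box_px, dt_ms = dt_ms,
    kappa0 = kappa0, kappa1 = kappa1, kappa2 = kappa2,
    delta_cond = delta_cond,
    alpha0 = alpha0, alpha1 = alpha1, alpha2 = alpha2,
    lambda = lambda, sigma_item = sigma_item,
    rho_explicit = rho_explicit,
    dqs_slope = dqs_slope, sigma_dqs = sigma_dqs,
    base_duration_ms = base_duration_ms, gamma_ms = gamma_ms,
    pull_px = pull_px, sigma_xy = sigma_xy,
    sigma_duration = sigma_duration,
    capture_radius_px = capture_radius_px, step_cap = as.integer(step_cap)
  )
  if (cfg$n_participants < 1 || cfg$n_healthy_stimuli < 1 ||
      cfg$n_unhealthy_stimuli < 1 || cfg$repetitions < 1) {
    stop("all design counts must be positive", call. = FALSE)
  }
  if (cfg$dt_ms <= 0 || cfg$base_duration_ms <= 0 || cfg$step_cap < 2) {
    stop("invalid timing configuration", call. = FALSE)
  }
  if (abs(cfg$rho_explicit) > 1) {
    stop("rho_explicit must lie in [-1, 1]", call. = FALSE)
  }
  structure(cfg, class = "uti_sim_config")
}

#' Simulate one cursor trajectory
#'
#' Generates the 10-ms cursor samples of a single movement from the start
#' point to the clicked pixel. At each step the cursor moves toward the
#' target at the closed-loop speed needed to arrive on schedule, is pulled
#' laterally toward the competing response box with magnitude proportional
#' to the trial's conflict (decaying linearly over the first half of the
#' movement), and receives isotropic Gaussian positional noise. Total
#' scheduled duration is `base_duration_ms + gamma_ms * conflict` times
#' multiplicative lognormal noise; the movement terminates when the cursor
#' enters the capture radius of the click point, whose coordinates become
#' the last sample. Draws from the current RNG stream.
#'
#' @param start,click Length-2 pixel coordinates.
#' @param competing Length-2 pixel coordinates of the non-chosen box.
#' @param conflict Non-negative conflict value for this trial.
#' @param config A `uti_sim_config` (motor parameters are read from it).
#' @return A list `t_ms, x_px, y_px` (equal-length vectors, `t_ms` from 0
#'   in `dt_ms` steps).
#' @export
simulate_trajectory <- function(start, click, competing, conflict, config) {
  stopifnot(conflict >= 0)
  dt <- config$dt_ms
  t_total <- (config$base_duration_ms + config$gamma_ms * conflict) *
    exp(rnorm(1, 0, config$sigma_duration))
  n <- max(2L, as.integer(round(t_total / dt)))
  if (n > config$step_cap) {
    stop(sprintf(
      "trajectory would need %d steps (cap %d): pathological configuration",
      n, config$step_cap), call. = FALSE)
  }
  d0 <- start - click
  chord <- click - start
  chord_len <- sqrt(sum(chord^2))
  if (chord_len == 0) stop("start and click coincide", call. = FALSE)
  perp <- c(-chord[2], chord[1]) / chord_len
  if (sum(perp * (competing - start)) < 0) perp <- -perp

  # closed-loop controller: pos_{k+1} = pos_k + (click - pos_k)/steps_left
  #                                   + pull_k + noise_k
  # has the closed form  d_k = (n-k) * (d0/n + sum_{j<k} w_j/(n-1-j))
  # for the deviation d_k = pos_k - click, which we evaluate vectorized.
  k <- seq_len(n)
  decay <- pmax(0, 1 - 2 * (k - 1) / n)
  w <- cbind(perp[1] * config$pull_px * conflict * decay,
             perp[2] * config$pull_px * conflict * decay)
  if (config$sigma_xy > 0) {
    w <- w + matrix(rnorm(2L * n, 0, config$sigma_xy), ncol = 2)
  }
  denom <- n - k          # = n - 1 - (k - 1), the j-th divisor for j = k-1
  w[n, ] <- 0             # last step's disturbance never propagates
  denom[n] <- 1
  cs_x <- cumsum(w[, 1] / denom)
  cs_y <- cumsum(w[, 2] / denom)
  dx <- (n - k) * (d0[1] / n + cs_x)
  dy <- (n - k) * (d0[2] / n + cs_y)
  dist <- sqrt(dx^2 + dy^2)
  n_end <- which(dist <= config$capture_radius_px)[1]
  if (is.na(n_end)) n_end <- n
  xs <- c(start[1], click[1] + dx[seq_len(n_end)])
  ys <- c(start[2], click[2] + dy[seq_len(n_end)])
  xs[n_end + 1L] <- click[1]
  ys[n_end + 1L] <- click[2]
  list(t_ms = dt * (0:n_end), x_px = xs, y_px = ys)
}

# Distribute a DQS total over five component levels in {1,2,3} and emit
# FFQ item responses that score back to exactly that total under the
# default configuration.
ffq_from_dqs <- function(dqs_total, config_dqs) {
  n_comp <- length(config_dqs)
  lv <- rep(1L, n_comp)
  remaining <- dqs_total - n_comp
  for (ci in sample.int(n_comp)) {
    add <- min(2L, remaining)
    lv[ci] <- lv[ci] + add
    remaining <- remaining - add
    if (remaining == 0L) break
  }
  n_items <- length(unlist(lapply(config_dqs, `[[`, "items")))
  ffq <- integer(n_items)
  for (ci in seq_len(n_comp)) {
    comp <- config_dqs[[ci]]
    healthy_level <- if (comp$direction == "healthy") lv[ci] else 4L - lv[ci]
    v <- c(2L, 4L, 6L)[healthy_level]   # mean frequency inside the band
    per <- length(comp$items)
    jitter <- integer(per)
    if (per >= 2) {
      pick <- sample.int(per, 2)        # +/-1 on two items keeps the mean
      jitter[pick] <- c(-1L, 1L)
    }
    ffq[comp$items] <- v + jitter
  }
  ffq
}

#' Simulate a synthetic cohort
#'
#' Generates the full three-table dataset plus ground truth for
#' `config$n_participants` agents under the generative model documented in
#' [sim_config()]. Output is deterministic given `config$seed` (one seeded
#' stream, agents generated sequentially).
#'
#' @param config A `uti_sim_config`.
#' @param conditions Optional character vector (length 1 or
#'   `n_participants`) of experimental conditions
#'   (`none/utilitarian/hedonic`); default all `"none"`. Only `"hedonic"`
#'   shifts the active trait.
#' @return A list of class `uti_cohort` with `participants`, `trials`,
#'   `samples` (the three interchange tibbles), and `truth`: a list of
#'   `agents` (`participant_id, u, u_star, condition`) and `trials`
#'   (`participant_id, trial_id, conflict, p_tasty`). Ground truth is
#'   never leaked into the three public tables.
#' @export
simulate_cohort <- function(config = sim_config(), conditions = "none") {
  stopifnot(inherits(config, "uti_sim_config"))
  np <- config$n_participants
  conditions <- rep(as.character(conditions), length.out = np)
  if (!all(conditions %in% CONDITIONS)) {
    stop(sprintf("conditions must be among: %s",
                 paste(CONDITIONS, collapse = ", ")), call. = FALSE)
  }
  set.seed(config$seed)
  dqs_cfg <- dqs_default_config()
  n_items_ffq <- length(unlist(lapply(dqs_cfg, `[[`, "items")))

  stim <- tibble::tibble(
    stimulus_id = c(sprintf("h%02d", seq_len(config$n_healthy_stimuli)),
                    sprintf("u%02d", seq_len(config$n_unhealthy_stimuli))),
    food_type = c(rep("healthy", config$n_healthy_stimuli),
                  rep("unhealthy", config$n_unhealthy_stimuli))
  )
  n_trials <- nrow(stim) * config$repetitions

  pids <- sprintf("p%03d", seq_len(np))
  t_ids <- sprintf("t%02d", seq_len(n_trials))
  u_all <- ustar_all <- numeric(np)
  age_all <- numeric(np)
  gender_all <- edu_all <- character(np)
  uti_all <- matrix(0, np, 3)
  ffq_all <- matrix(0L, np, n_items_ffq)
  trial_acc <- vector("list", np)
  truth_acc <- vector("list", np)
  samp_t <- samp_x <- samp_y <- vector("list", np)
  samp_len <- vector("list", np)

  for (i in seq_len(np)) {
    cond <- conditions[i]
    u <- rnorm(1)
    u_star <- u + config$delta_cond * (cond == "hedonic")
    u_all[i] <- u; ustar_all[i] <- u_star

    age_all[i] <- min(80, max(18, round(rnorm(1, 41, 14))))
    gender_all[i] <- sample(c("female", "male", "other"), 1,
                            prob = c(0.58, 0.40, 0.02))
    edu_all[i] <- sample(c("secondary", "vocational", "bachelor", "master"),
                         1, prob = c(0.25, 0.25, 0.30, 0.20))
    e_explicit <- config$rho_explicit * u +
      sqrt(1 - config$rho_explicit^2) * rnorm(1)
    uti_all[i, ] <- pmin(7, pmax(1, round(4 + config$lambda * e_explicit +
                                            rnorm(3, 0, config$sigma_item))))
    dqs_target <- round(min(15, max(5, 10 - config$dqs_slope * u +
                                      rnorm(1, 0, config$sigma_dqs))))
    ffq_all[i, ] <- ffq_from_dqs(dqs_target, dqs_cfg)

    order_idx <- sample(rep(seq_len(nrow(stim)), config$repetitions))
    healthy <- stim$food_type[order_idx] == "healthy"
    p_tasty <- plogis(config$alpha0 +
                        config$alpha1 * (!healthy) -
                        config$alpha2 * max(u_star, 0) * healthy)
    tasty <- rbinom(n_trials, 1, p_tasty) == 1
    conflict <- softplus(config$kappa0 +
                           config$kappa1 * u_star * (healthy & tasty) +
                           config$kappa2 * (!tasty))

    starts <- cbind(config$start_px[1] + runif(n_trials, -5, 5),
                    config$start_px[2] + runif(n_trials, -5, 5))
    box_center <- rbind(config$left_box_px, config$right_box_px)
    chosen <- box_center[ifelse(tasty, 1, 2), , drop = FALSE]
    competing <- box_center[ifelse(tasty, 2, 1), , drop = FALSE]
    clicks <- cbind(chosen[, 1] + runif(n_trials, -40, 40),
                    chosen[, 2] + runif(n_trials, -15, 15))

    tt <- xx <- yy <- vector("list", n_trials)
    nlen <- integer(n_trials)
    for (j in seq_len(n_trials)) {
      tr <- simulate_trajectory(starts[j, ], clicks[j, ], competing[j, ],
                                conflict[j], config)
      tt[[j]] <- tr$t_ms; xx[[j]] <- tr$x_px; yy[[j]] <- tr$y_px
      nlen[j] <- length(tr$t_ms)
    }
    samp_t[[i]] <- tt; samp_x[[i]] <- xx; samp_y[[i]] <- yy
    samp_len[[i]] <- nlen
    trial_acc[[i]] <- list(
      stimulus_id = stim$stimulus_id[order_idx],
      food_type = stim$food_type[order_idx],
      tasty = tasty,
      starts = starts, clicks = clicks
    )
    truth_acc[[i]] <- list(conflict = conflict, p_tasty = p_tasty)
  }

  n_per <- vapply(samp_len, sum, numeric(1))
  samples <- tibble::tibble(
    participant_id = rep(pids, n_per),
    trial_id = rep(rep(t_ids, np), unlist(samp_len)),
    t_ms = unlist(samp_t),
    x_px = unlist(samp_x),
    y_px = unlist(samp_y)
  )
  get_tr <- function(field) lapply(trial_acc, `[[`, field)
  tasty_v <- unlist(get_tr("tasty"))
  starts_m <- do.call(rbind, get_tr("starts"))
  clicks_m <- do.call(rbind, get_tr("clicks"))
  trials <- tibble::tibble(
    participant_id = rep(pids, each = n_trials),
    trial_id = rep(t_ids, np),
    stimulus_id = unlist(get_tr("stimulus_id")),
    food_type = unlist(get_tr("food_type")),
    classification = ifelse(tasty_v, "tasty", "not_tasty"),
    response_side = ifelse(tasty_v, "left", "right"),
    presentation_index = rep(seq_len(n_trials), np),
    start_x_px = starts_m[, 1], start_y_px = starts_m[, 2],
    click_x_px = clicks_m[, 1], click_y_px = clicks_m[, 2]
  )
  participants <- tibble::tibble(
    participant_id = pids, age = age_all, gender = gender_all,
    education = edu_all, condition = conditions,
    uti_item_1 = uti_all[, 1], uti_item_2 = uti_all[, 2],
    uti_item_3 = uti_all[, 3]
  )
  for (kk in seq_len(n_items_ffq)) {
    participants[[paste0("ffq_", kk)]] <- ffq_all[, kk]
  }
  truth_trials <- tibble::tibble(
    participant_id = rep(pids, each = n_trials),
    trial_id = rep(t_ids, np),
    conflict = unlist(lapply(truth_acc, `[[`, "conflict")),
    p_tasty = unlist(lapply(truth_acc, `[[`, "p_tasty"))
  )

  structure(
    list(
      participants = participants,
      trials = trials,
      samples = samples,
      truth = list(
        agents = tibble::tibble(participant_id = pids, u = u_all,
                                u_star = ustar_all,
                                condition = conditions),
        trials = truth_trials
      ),
      config = config
    ),
    class = "uti_cohort"
  )
}

#' @export
print.uti_cohort <- function(x, ...) {
  cat(sprintf(
    "<uti_cohort: %d participants, %d trials, %d cursor samples (seed %d)>\n",
    nrow(x$participants), nrow(x$trials), nrow(x$samples),
    x$config$seed))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Emits `participants.csv`, `trials.csv`, `samples.csv`,
#' `truth_agents.csv`, `truth_trials.csv` and the configuration actually
#' used as `sim_config.json` into a directory.
#'
#' @param cohort A `uti_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "uti_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_participants(cohort$participants, file.path(dir, "participants.csv"))
  write_trials(cohort$trials, file.path(dir, "trials.csv"))
  write_samples(cohort$samples, file.path(dir, "samples.csv"))
  readr::write_csv(cohort$truth$agents, file.path(dir, "truth_agents.csv"),
                   progress = FALSE)
  readr::write_csv(cohort$truth$trials, file.path(dir, "truth_trials.csv"),
                   progress = FALSE)
  jsonlite::write_json(unclass(cohort$config),
                       file.path(dir, "sim_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
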