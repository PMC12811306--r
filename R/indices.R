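# Participant-level indices: outlier exclusion, difference scores,
# scale scoring, classification summaries.

#' Flag trial-level outliers by the k-SD rule
#'
#' Applies the preregistered-style exclusion rule: the grand mean and
#' standard deviation of each metric are computed once over all
#' non-degenerate trials (a single pass, pooled across participants) and
#' trials outside the resulting band are flagged. Reaction times are
#' excluded two-sided (both unusually slow and unusually fast responses);
#' the signed MAD is excluded in the upper tail only (trajectories more
#' extreme than mean + k SD toward the competing box). Flagged rows stay
#' in the table so exclusions can be audited.
#'
#' @param metrics Tibble from [compute_trial_metrics()].
#' @param k Number of standard deviations (default 3).
#' @param rt_two_sided,mad_two_sided Tail configuration for each metric.
#' @return A list with `metrics` (the table with `excluded_rt` /
#'   `excluded_mad` set) and `report`, a tibble of class
#'   `uti_exclusion_report` with one row per metric: mean, sd, bounds,
#'   `n_excluded`, `fraction_excluded`.
#' @export
exclude_outliers <- function(metrics, k = 3, rt_two_sided = TRUE,
                             mad_two_sided = FALSE) {
  ok <- !metrics$degenerate
  if (sum(ok) < 2) {
    stop("need at least 2 non-degenerate trials to estimate an SD",
         call. = FALSE)
  }
  flag_metric <- function(x, two_sided) {
    m <- mean(x[ok], na.rm = TRUE)
    s <- sd(x[ok], na.rm = TRUE)
    lo <- if (two_sided) m - k * s else -Inf
    hi <- m + k * s
    flags <- ok & !is.na(x) & (x < lo | x > hi)
    list(flags = flags, mean = m, sd = s, lower = lo, upper = hi)
  }
  rt <- flag_metric(metrics$rt_ms, rt_two_sided)
  mad <- flag_metric(metrics$mad_px, mad_two_sided)
  metrics$excluded_rt <- rt$flags
  metrics$excluded_mad <- mad$flags
  n_total <- sum(ok)
  report <- tibble::tibble(
    metric = c("rt_ms", "mad_px"),
    mean = c(rt$mean, mad$mean),
    sd = c(rt$sd, mad$sd),
    lower = c(rt$lower, mad$lower),
    upper = c(rt$upper, mad$upper),
    n_excluded = c(sum(rt$flags), sum(mad$flags)),
    n_total = n_total,
    fraction_excluded = c(sum(rt$flags), sum(mad$flags)) / n_total
  )
  class(report) <- c("uti_exclusion_report", class(report))
  list(metrics = metrics, report = report)
}

#' Healthy-minus-unhealthy difference scores per participant
#'
#' For each participant, the mean of a metric over retained healthy trials
#' minus the mean over retained unhealthy trials. Positive values mean
#' slower (`delta_rt_ms`) or more curved (`delta_mad_px`) responses to
#' healthy foods - the behavioral signature of the unhealthy = tasty
#' intuition. A delta is `NA` (with a warning) for participants with an
#' empty cell after exclusions.
#'
#' @param metrics Tibble from [compute_trial_metrics()], after
#'   [exclude_outliers()] has set the exclusion flags.
#' @param trials Trial table supplying `food_type` per trial.
#' @return A tibble: `participant_id, delta_rt_ms, delta_mad_px,
#'   n_healthy_rt, n_unhealthy_rt, n_healthy_mad, n_unhealthy_mad`.
#' @export
difference_scores <- function(metrics, trials) {
  dat <- dplyr::left_join(
    metrics,
    trials[, c("participant_id", "trial_id", "food_type")],
    by = c("participant_id", "trial_id")
  )
  if (anyNA(dat$food_type)) {
    stop("some metric rows have no matching trial row", call. = FALSE)
  }
  cell_mean <- function(x, use) if (any(use)) mean(x[use]) else NA_real_
  out <- dat |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      delta_rt_ms =
        cell_mean(.data$rt_ms, !.data$degenerate & !.data$excluded_rt &
                    .data$food_type == "healthy") -
        cell_mean(.data$rt_ms, !.data$degenerate & !.data$excluded_rt &
                    .data$food_type == "unhealthy"),
      delta_mad_px =
        cell_mean(.data$mad_px, !.data$degenerate & !.data$excluded_mad &
                    .data$food_type == "healthy") -
        cell_mean(.data$mad_px, !.data$degenerate & !.data$excluded_mad &
                    .data$food_type == "unhealthy"),
      n_healthy_rt = sum(!.data$degenerate & !.data$excluded_rt &
                           .data$food_type == "healthy"),
      n_unhealthy_rt = sum(!.data$degenerate & !.data$excluded_rt &
                             .data$food_type == "unhealthy"),
      n_healthy_mad = sum(!.data$degenerate & !.data$excluded_mad &
                            .data$food_type == "healthy"),
      n_unhealthy_mad = sum(!.data$degenerate & !.data$excluded_mad &
                              .data$food_type == "unhealthy"),
      .groups = "drop"
    )
  n_missing <- sum(is.na(out$delta_rt_ms) | is.na(out$delta_mad_px))
  if (n_missing > 0) {
    warning(sprintf(
      "%d participant(s) have an empty food-type cell after exclusions; their difference scores are NA",
      n_missing), call. = FALSE)
  }
  out
}

#' Score the explicit UTI scale
#'
#' Arithmetic mean of the three seven-point items ("healthy food is
#' usually less tasty" etc.). Higher scores indicate stronger endorsement
#' of the unhealthy = tasty belief.
#'
#' @param items Numeric vector of length 3 (or an n x 3 matrix /
#'   data frame for many participants), values in 1-7.
#' @return The item mean (a vector of row means for matrix input).
#' @export
score_uti_scale <- function(items) {
  m <- as.matrix(items)
  if (is.null(dim(items))) m <- matrix(as.numeric(items), nrow = 1)
  if (ncol(m) != 3) stop("the explicit UTI scale has 3 items", call. = FALSE)
  if (any(m < 1 | m > 7, na.rm = TRUE)) {
    stop("UTI items must lie in [1, 7]", call. = FALSE)
  }
  out <- rowMeans(m)
  if (is.null(dim(items))) out <- out[[1]]
  out
}

#' Cronbach's alpha internal consistency
#'
#' `alpha = k/(k-1) * (1 - sum of item variances / variance of total
#' scores)` for an n x k item matrix.
#'
#' @param items Numeric matrix or data frame, rows = respondents,
#'   columns = items (n >= 2, k >= 2).
#' @return Alpha, or `NA` when the total-score variance is zero
#'   (undefined).
#' @export
cronbach_alpha <- function(items) {
  m <- as.matrix(items)
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("need at least 2 respondents and 2 items",
                           call. = FALSE)
  total_var <- var(rowSums(m))
  if (total_var == 0) return(NA_real_)
  item_vars <- apply(m, 2, var)
  k / (k - 1) * (1 - sum(item_vars) / total_var)
}

#' Classification proportions by food type and group
#'
#' Empirical probability of a "tasty" classification in each food type
#' (optionally crossed with a participant grouping such as a median-split
#' UTI group or an experimental condition), with cell counts.
#'
#' @param trials Trial table.
#' @param grouping Optional named character vector or two-column data frame
#'   mapping `participant_id` to a group label; `NULL` for the full sample.
#' @return A tibble `group, food_type, n_trials, n_tasty, p_tasty`
#'   (`group = "all"` without a grouping). Empty cells are absent rather
#'   than zero-filled.
#' @export
classification_proportions <- function(trials, grouping = NULL) {
  dat <- trials[, c("participant_id", "food_type", "classification")]
  if (is.null(grouping)) {
    dat$group <- "all"
  } else {
    if (is.data.frame(grouping)) {
      g <- setNames(as.character(grouping[[2]]),
                    as.character(grouping[[1]]))
    } else {
      g <- grouping
    }
    dat$group <- unname(g[dat$participant_id])
  }
  dat |>
    dplyr::filter(!is.na(.data$group)) |>
    dplyr::group_by(.data$group, .data$food_type) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      n_tasty = sum(.data$classification == "tasty"),
      p_tasty = mean(.data$classification == "tasty"),
      .groups = "drop"
    )
}

#' Median split of a score
#'
#' Descriptive dichotomization: scores above the sample median are labeled
#' `"high"`, scores below `"low"`, and ties at the median go to `"low"`
#' (documented convention, so the split is deterministic).
#'
#' @param scores Numeric vector with at least 2 distinct values.
#' @return Character vector of `"low"` / `"high"` labels, same length.
#' @export
median_split <- function(scores) {
  if (length(unique(scores[!is.na(scores)])) < 2) {
    stop("median split needs at least 2 distinct values", call. = FALSE)
  }
  med <- median(scores, na.rm = TRUE)
  ifelse(is.na(scores), NA_character_,
         ifelse(scores > med, "high", "low"))
}

#' Assemble the participant-level index table
#'
#' One-stop aggregation: applies the k-SD exclusion rule to the trial
#' metrics, computes healthy-minus-unhealthy difference scores, scores the
#' explicit UTI scale and (when FFQ items are present) the diet quality
#' score, and adds the descriptive median-split group on the explicit
#' score.
#'
#' @param metrics Tibble from [compute_trial_metrics()].
#' @param trials,participants The corresponding tables.
#' @param k SD multiplier for [exclude_outliers()].
#' @param dqs_config DQS scoring configuration, see [dqs_default_config()];
#'   `NULL` skips DQS scoring.
#' @return A list with `indices` (tibble: `participant_id, uti_explicit,
#'   delta_rt_ms, delta_mad_px, dqs, condition, age, gender, education,
#'   median_split_group` plus retained-trial counts) and `exclusion_report`.
#' @export
participant_indices <- function(metrics, trials, participants, k = 3,
                                dqs_config = dqs_default_config()) {
  excl <- exclude_outliers(metrics, k = k)
  deltas <- difference_scores(excl$metrics, trials)
  uti <- score_uti_scale(
    participants[, paste0("uti_item_", 1:3)])
  ffq_cols <- grep("^ffq_[0-9]+$", names(participants), value = TRUE)
  dqs <- rep(NA_real_, nrow(participants))
  if (!is.null(dqs_config) && length(ffq_cols) > 0) {
    ffq <- as.matrix(participants[, ffq_cols])
    dqs <- apply(ffq, 1, score_dqs, config = dqs_config)
  }
  base <- tibble::tibble(
    participant_id = participants$participant_id,
    uti_explicit = uti,
    dqs = dqs,
    condition = participants$condition,
    age = participants$age,
    gender = participants$gender,
    education = participants$education
  )
  out <- dplyr::left_join(base, deltas, by = "participant_id")
  out$median_split_group <- median_split(out$uti_explicit)
  list(indices = out, exclusion_report = excl$report,
       metrics = excl$metrics)
}
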