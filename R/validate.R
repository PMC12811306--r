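# Cross-table invariant checks. Violations become report rows, never
# exceptions, so a whole dataset can be audited in one pass.

report_row <- function(code, location, message) {
  tibble::tibble(code = code, location = location, message = message)
}

empty_report <- function() {
  tibble::tibble(code = character(), location = character(),
                 message = character())
}

#' Validate a three-table dataset
#'
#' Checks every structural invariant the analysis relies on:
#' \itemize{
#'   \item within each trial, `t_ms` is strictly increasing and starts at 0;
#'   \item every sampled trial exists in the trial table and every trial has
#'     samples (no orphans on either side);
#'   \item every trial's participant exists in the participant table;
#'   \item `classification` agrees with `response_side` given which side
#'     holds the "tasty" box;
#'   \item each `stimulus_id` maps to exactly one `food_type`;
#'   \item UTI items lie in 1-7 and FFQ items in 1-8.
#' }
#' Inputs are never modified; calling twice yields identical reports.
#'
#' @param samples,trials,participants Tibbles from [read_samples()],
#'   [read_trials()], [read_participants()] (or [simulate_cohort()]).
#' @param tasty_side Which response box is the "tasty" one (`"left"` in the
#'   reference task layout, where tasty is the upper-left box).
#' @return An object of class `uti_validation`: a list with `errors` and
#'   `warnings` tibbles (`code`, `location`, `message`) and a `counts` list
#'   of rows per table. An empty error table means the dataset passes.
#' @export
validate_dataset <- function(samples, trials, participants,
                             tasty_side = c("left", "right")) {
  tasty_side <- match.arg(tasty_side)
  errors <- list()
  warnings <- list()

  key_s <- paste(samples$participant_id, samples$trial_id, sep = "\r")
  key_t <- paste(trials$participant_id, trials$trial_id, sep = "\r")

  # t_ms monotone increasing from 0 within each trial
  ord <- order(key_s)
  ks <- key_s[ord]
  ts <- samples$t_ms[ord]
  grp_start <- which(!duplicated(ks))
  grp_end <- c(grp_start[-1] - 1L, length(ks))
  for (g in seq_along(grp_start)) {
    i0 <- grp_start[g]; i1 <- grp_end[g]
    loc <- gsub("\r", "/", ks[i0])
    tt <- ts[i0:i1]
    if (tt[1] != 0) {
      errors[[length(errors) + 1L]] <- report_row(
        "t_not_rebased", loc,
        sprintf("first sample at t_ms=%g, expected 0", tt[1]))
    }
    if (length(tt) > 1 && any(diff(tt) <= 0)) {
      errors[[length(errors) + 1L]] <- report_row(
        "t_not_increasing", loc, "t_ms is not strictly increasing")
    }
  }

  # orphans in both directions
  orphan_samples <- unique(key_s[!(key_s %in% key_t)])
  for (k in orphan_samples) {
    errors[[length(errors) + 1L]] <- report_row(
      "orphan_samples", gsub("\r", "/", k),
      "samples present for a trial missing from the trial table")
  }
  orphan_trials <- unique(key_t[!(key_t %in% key_s)])
  for (k in orphan_trials) {
    errors[[length(errors) + 1L]] <- report_row(
      "orphan_trial", gsub("\r", "/", k),
      "trial has no cursor samples")
  }

  # duplicated trial keys
  dup <- unique(key_t[duplicated(key_t)])
  for (k in dup) {
    errors[[length(errors) + 1L]] <- report_row(
      "duplicate_trial", gsub("\r", "/", k), "duplicated trial row")
  }

  # participants referenced by trials must exist
  missing_p <- setdiff(unique(trials$participant_id),
                       participants$participant_id)
  for (p in missing_p) {
    errors[[length(errors) + 1L]] <- report_row(
      "unknown_participant", p,
      "trial references a participant missing from the participant table")
  }

  # classification <-> response side consistency
  expected_side <- ifelse(trials$classification == "tasty",
                          tasty_side, setdiff(RESPONSE_SIDES, tasty_side))
  bad <- which(trials$response_side != expected_side)
  for (i in bad) {
    errors[[length(errors) + 1L]] <- report_row(
      "side_mismatch", paste(trials$participant_id[i], trials$trial_id[i],
                             sep = "/"),
      sprintf("classification '%s' inconsistent with response_side '%s'",
              trials$classification[i], trials$response_side[i]))
  }

  # one food type per stimulus
  map <- unique(trials[, c("stimulus_id", "food_type")])
  multi <- unique(map$stimulus_id[duplicated(map$stimulus_id)])
  for (s in multi) {
    errors[[length(errors) + 1L]] <- report_row(
      "stimulus_food_type", s,
      "stimulus mapped to more than one food_type")
  }

  # questionnaire ranges
  for (col in paste0("uti_item_", 1:3)) {
    bad <- which(!is.na(participants[[col]]) &
                   (participants[[col]] < 1 | participants[[col]] > 7))
    for (i in bad) {
      errors[[length(errors) + 1L]] <- report_row(
        "out_of_range", paste0(participants$participant_id[i], ":", col),
        sprintf("%s = %g outside [1, 7]", col, participants[[col]][i]))
    }
  }
  for (col in grep("^ffq_[0-9]+$", names(participants), value = TRUE)) {
    bad <- which(!is.na(participants[[col]]) &
                   (participants[[col]] < 1 | participants[[col]] > 8))
    for (i in bad) {
      errors[[length(errors) + 1L]] <- report_row(
        "out_of_range", paste0(participants$participant_id[i], ":", col),
        sprintf("%s = %g outside [1, 8]", col, participants[[col]][i]))
    }
  }

  structure(
    list(
      errors = if (length(errors)) dplyr::bind_rows(errors) else empty_report(),
      warnings = if (length(warnings)) dplyr::bind_rows(warnings) else empty_report(),
      counts = list(samples = nrow(samples), trials = nrow(trials),
                    participants = nrow(participants))
    ),
    class = "uti_validation"
  )
}

#' @export
print.uti_validation <- function(x, ...) {
  cat(sprintf(
    "Dataset validation: %d samples, %d trials, %d participants\n",
    x$counts$samples, x$counts$trials, x$counts$participants))
  cat(sprintf("  errors: %d, warnings: %d\n",
              nrow(x$errors), nrow(x$warnings)))
  if (nrow(x$errors) > 0) {
    print(utils::head(x$errors, 10))
  }
  invisible(x)
}
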