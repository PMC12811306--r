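# End-to-end convenience wrappers chaining preprocessing, metrics,
# indices and the standard inferential set.

#' Run the full analysis pipeline on a dataset
#'
#' Chains [compute_trial_metrics()], [participant_indices()] and the
#' standard validity statistics: Pearson correlations of the explicit UTI
#' score with the two difference scores (and with DQS when present), and
#' optionally the trial-level mixed models with their simple-slope
#' contrasts.
#'
#' @param samples,trials,participants The three tables (tibbles from the
#'   readers or a [simulate_cohort()] result).
#' @param k SD multiplier for the outlier rule.
#' @param sampen Compute sample entropy per trial (costliest metric)?
#' @param models Fit the trial-level mixed models (`fit_lmm()` for RT and
#'   MAD plus simple slopes)? Default FALSE: the correlations are cheap,
#'   the models are not.
#' @param dqs_config DQS scoring configuration (`NULL` to skip).
#' @return A list of class `uti_analysis`: `metrics` (flagged trial
#'   metrics), `indices`, `exclusion_report`, `correlations` (tibble),
#'   `classification` (proportions by food type), and - when requested -
#'   `lmm_rt`, `lmm_mad`, `slopes_rt`, `slopes_mad`.
#' @export
analyze_dataset <- function(samples, trials, participants, k = 3,
                            sampen = FALSE, models = FALSE,
                            dqs_config = dqs_default_config()) {
  metrics <- compute_trial_metrics(samples, trials, sampen = sampen)
  agg <- participant_indices(metrics, trials, participants, k = k,
                             dqs_config = dqs_config)
  idx <- agg$indices
  cors <- list(
    uti_delta_rt = pearson_r(idx$uti_explicit, idx$delta_rt_ms),
    uti_delta_mad = pearson_r(idx$uti_explicit, idx$delta_mad_px)
  )
  if (any(!is.na(idx$dqs)) && sd(idx$dqs, na.rm = TRUE) > 0) {
    cors$uti_dqs <- pearson_r(idx$uti_explicit, idx$dqs)
    cors$delta_rt_dqs <- pearson_r(idx$delta_rt_ms, idx$dqs)
    cors$delta_mad_dqs <- pearson_r(idx$delta_mad_px, idx$dqs)
  }
  correlations <- dplyr::bind_rows(lapply(names(cors), function(nm) {
    tibble::tibble(pair = nm, r = cors[[nm]]$r, p = cors[[nm]]$p,
                   n = cors[[nm]]$n)
  }))
  out <- list(
    metrics = agg$metrics,
    indices = idx,
    exclusion_report = agg$exclusion_report,
    correlations = correlations,
    classification = classification_proportions(trials)
  )
  if (models) {
    dat <- prepare_trial_data(agg$metrics, trials, participants)
    out$lmm_rt <- fit_lmm(dat, "rt_ms")
    out$lmm_mad <- fit_lmm(dat, "mad_px")
    out$slopes_rt <- simple_slopes(out$lmm_rt)
    out$slopes_mad <- simple_slopes(out$lmm_mad)
  }
  class(out) <- "uti_analysis"
  out
}

#' @export
print.uti_analysis <- function(x, ...) {
  cat("UTI classification-task analysis\n")
  cat(sprintf("  trials: %d (%d participants)\n", nrow(x$metrics),
              nrow(x$indices)))
  cat("  exclusions:\n")
  for (i in seq_len(nrow(x$exclusion_report))) {
    cat(sprintf("    %s: %d/%d trials (%.1f%%) outside [%.1f, %.1f]\n",
                x$exclusion_report$metric[i], x$exclusion_report$n_excluded[i],
                x$exclusion_report$n_total[i],
                100 * x$exclusion_report$fraction_excluded[i],
                x$exclusion_report$lower[i], x$exclusion_report$upper[i]))
  }
  cat("  validity correlations:\n")
  for (i in seq_len(nrow(x$correlations))) {
    cat(sprintf("    %s: r = %.3f (p = %.4g, n = %d)\n",
                x$correlations$pair[i], x$correlations$r[i],
                x$correlations$p[i], x$correlations$n[i]))
  }
  invisible(x)
}
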