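# Inferential harness: validity correlations, group contrasts, crossed
# random-intercept mixed models, simple-slope contrasts, incremental
# validity, and the Fisher-z power analysis.

#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation on pairwise-complete observations, with the
#' two-sided p-value from `t = r * sqrt((n-2)/(1-r^2))` on `n - 2` degrees
#' of freedom.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A list `r, p, n`.
#' @export
pearson_r <- function(x, y) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("correlation undefined: zero variance", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom, the
#' default two-group contrast (group sizes and variances are rarely equal
#' in between-subject conditions).
#'
#' @param group_a,group_b Numeric vectors (each n >= 2), NAs dropped.
#' @return A list `t, df, p, mean_a, mean_b, sd_a, sd_b, n_a, n_b`.
#' @export
welch_t <- function(group_a, group_b) {
  a <- group_a[!is.na(group_a)]
  b <- group_b[!is.na(group_b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  if (sd(a) == 0 && sd(b) == 0) {
    stop("Welch test undefined: zero variance in both groups", call. = FALSE)
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(
    t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
    mean_a = mean(a), mean_b = mean(b), sd_a = sd(a), sd_b = sd(b),
    n_a = length(a), n_b = length(b)
  )
}

#' Cohen's d with a normal-approximation confidence interval
#'
#' Standardized mean difference `(mean_a - mean_b) / pooled SD`, with the
#' large-sample CI `d +/- z * SE`,
#' `SE = sqrt((n_a + n_b)/(n_a * n_b) + d^2 / (2 (n_a + n_b)))`.
#'
#' @param group_a,group_b Numeric vectors (each n >= 2), NAs dropped.
#' @param level Confidence level (default 0.95).
#' @return A list `d, lo, hi, se`.
#' @export
cohens_d_ci <- function(group_a, group_b, level = 0.95) {
  a <- group_a[!is.na(group_a)]
  b <- group_b[!is.na(group_b)]
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  sp <- sqrt(((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2))
  if (sp == 0) stop("Cohen's d undefined: zero pooled variance", call. = FALSE)
  d <- (mean(a) - mean(b)) / sp
  se <- sqrt((na + nb) / (na * nb) + d^2 / (2 * (na + nb)))
  z <- qnorm(1 - (1 - level) / 2)
  list(d = d, lo = d - z * se, hi = d + z * se, se = se)
}

#' Assemble the trial-level analysis table
#'
#' Joins trial metrics, trial design variables and participant covariates
#' into the flat table the mixed models consume. Factor codings follow the
#' analysis conventions: `food_type` with reference `healthy`,
#' `classification` with reference `tasty`, gender and education
#' indicator-coded with the most frequent level as reference, and `uti_z`
#' the explicit UTI score standardized (mean 0, SD 1) over the
#' participants present in the table.
#'
#' @param metrics Trial metrics (after [exclude_outliers()] if exclusion
#'   flags should be honored downstream).
#' @param trials,participants The corresponding tables.
#' @return A tibble with one row per metric row and columns
#'   `rt_ms, mad_px, sample_entropy, excluded_rt, excluded_mad, degenerate,
#'   food_type, classification, tasty, stimulus_id, uti_explicit, uti_z,
#'   age, gender, education, condition, participant_id, trial_id`.
#' @export
prepare_trial_data <- function(metrics, trials, participants) {
  uti <- tibble::tibble(
    participant_id = participants$participant_id,
    uti_explicit = score_uti_scale(participants[, paste0("uti_item_", 1:3)]),
    age = participants$age,
    gender = participants$gender,
    education = participants$education,
    condition = participants$condition
  )
  dat <- metrics |>
    dplyr::left_join(
      trials[, c("participant_id", "trial_id", "stimulus_id", "food_type",
                 "classification")],
      by = c("participant_id", "trial_id")) |>
    dplyr::left_join(uti, by = "participant_id")
  mode_level <- function(x) names(sort(table(x), decreasing = TRUE))[1]
  dat$food_type <- factor(dat$food_type, levels = c("healthy", "unhealthy"))
  dat$classification <- factor(dat$classification,
                               levels = c("tasty", "not_tasty"))
  dat$tasty <- as.integer(dat$classification == "tasty")
  dat$gender <- stats::relevel(factor(dat$gender), ref = mode_level(dat$gender))
  dat$education <- stats::relevel(factor(dat$education),
                                  ref = mode_level(dat$education))
  dat$condition <- factor(dat$condition,
                          levels = intersect(CONDITIONS,
                                             unique(dat$condition)))
  mu <- mean(dat$uti_explicit[!duplicated(dat$participant_id)])
  s <- sd(dat$uti_explicit[!duplicated(dat$participant_id)])
  dat$uti_z <- (dat$uti_explicit - mu) / s
  dat
}

new_model_fit <- function(coefficients, varcomp, n_obs, converged,
                          family, fit = NULL, note = NA_character_) {
  structure(
    list(coefficients = coefficients, varcomp = varcomp, n_obs = n_obs,
         converged = converged, family = family, fit = fit, note = note),
    class = "uti_model_fit"
  )
}

#' @export
print.uti_model_fit <- function(x, ...) {
  cat(sprintf("<uti_model_fit: %s, n_obs=%d, converged=%s%s>\n",
              x$family, x$n_obs, x$converged,
              if (!is.na(x$note)) paste0(", ", x$note) else ""))
  print(x$coefficients, n = Inf)
  invisible(x)
}

lme4_converged <- function(fit) {
  msgs <- fit@optinfo$conv$lme4$messages
  # a boundary (singular) fit is converged - a variance component is just 0
  msgs <- msgs[!grepl("boundary \\(singular\\)", msgs)]
  isTRUE(fit@optinfo$conv$opt == 0) && length(msgs) == 0
}

coef_table_from_lme4 <- function(fit) {
  sm <- summary(fit)$coefficients
  est <- sm[, "Estimate"]
  se <- sm[, "Std. Error"]
  z <- est / se
  tibble::tibble(
    term = rownames(sm), estimate = unname(est), se = unname(se),
    z = unname(z), p = 2 * pnorm(-abs(unname(z)))
  )
}

varcomp_from_lme4 <- function(fit) {
  vc <- as.data.frame(lme4::VarCorr(fit))
  tibble::tibble(group = vc$grp, variance = vc$vcov, sd = vc$sdcor)
}

#' Fit the trial-level linear mixed model
#'
#' REML fit of a conflict metric on food type, classification, the
#' standardized explicit UTI score and all their interactions, with age,
#' gender and education as covariates and crossed random intercepts for
#' participant and stimulus. Coefficient p-values use the normal
#' approximation for z = estimate/SE (no degrees-of-freedom correction),
#' the convention documented for this toolkit.
#'
#' The key term is `food_typeunhealthy:uti_z`: with reference levels
#' `healthy`/`tasty`, a negative estimate means the positive UTI slope is
#' concentrated on healthy trials.
#'
#' @param data Tibble from [prepare_trial_data()].
#' @param outcome Column name of the outcome (`"rt_ms"` or `"mad_px"`).
#' @param use_exclusions Drop rows flagged by [exclude_outliers()] for this
#'   outcome (default TRUE; degenerate trials are always dropped).
#' @param covariates Character vector of covariate columns to include when
#'   they vary (default age, gender, education).
#' @return A `uti_model_fit`: coefficient table (estimate, SE, z, p),
#'   variance components, `n_obs`, honest `converged` flag, and the
#'   underlying `lme4` fit.
#' @export
fit_lmm <- function(data, outcome = c("rt_ms", "mad_px", "sample_entropy"),
                    use_exclusions = TRUE,
                    covariates = c("age", "gender", "education")) {
  outcome <- match.arg(outcome)
  keep <- !data$degenerate & !is.na(data[[outcome]])
  if (use_exclusions) {
    flag_col <- switch(outcome, rt_ms = "excluded_rt",
                       mad_px = "excluded_mad", NULL)
    if (!is.null(flag_col)) keep <- keep & !data[[flag_col]]
  }
  dat <- data[keep, ]
  covariates <- covariates[vapply(covariates, function(v) {
    length(unique(dat[[v]])) > 1
  }, logical(1))]
  rhs <- paste(c("food_type * classification * uti_z", covariates,
                 "(1 | participant_id)", "(1 | stimulus_id)"),
               collapse = " + ")
  form <- stats::as.formula(paste(outcome, "~", rhs))
  if (var(dat[[outcome]]) == 0) {
    # constant outcome: the ML solution is exact and trivial
    terms <- colnames(stats::model.matrix(lme4::nobars(form), dat))
    coefs <- tibble::tibble(
      term = terms,
      estimate = c(dat[[outcome]][1], rep(0, length(terms) - 1)),
      se = NA_real_, z = NA_real_, p = NA_real_)
    return(new_model_fit(coefs,
                         tibble::tibble(group = c("participant_id",
                                                  "stimulus_id", "Residual"),
                                        variance = 0, sd = 0),
                         nrow(dat), TRUE, "gaussian",
                         note = "constant outcome"))
  }
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(form, data = dat, REML = TRUE,
               control = lme4::lmerControl(calc.derivs = FALSE))))
  new_model_fit(coef_table_from_lme4(fit), varcomp_from_lme4(fit),
                nrow(dat), lme4_converged(fit), "gaussian", fit = fit)
}

#' Fit the classification-choice generalized linear mixed model
#'
#' Logistic mixed model of the binary classification (1 = "tasty",
#' 0 = "not tasty") on experimental condition, food type and their
#' interaction, with demographic covariates and crossed random intercepts
#' for participant and stimulus. The condition x food-type interaction
#' captures whether a manipulation (e.g., a hedonic goal prime) shifts
#' tasty judgments specifically for healthy foods.
#'
#' @param data Tibble from [prepare_trial_data()]; must contain at least
#'   two condition levels.
#' @param predictors Right-hand-side fixed-effect specification (default
#'   `condition * food_type`).
#' @param covariates Covariates to include when they vary.
#' @return A `uti_model_fit` (binomial-logit family). A single-level
#'   outcome yields a flagged degenerate fit rather than an error, and
#'   non-convergence (including separation symptoms) is reported in the
#'   `converged` flag.
#' @export
fit_glmm_choice <- function(data, predictors = "condition * food_type",
                            covariates = c("age", "gender", "education")) {
  dat <- data[!data$degenerate, ]
  if (length(unique(dat$tasty)) < 2) {
    return(new_model_fit(
      tibble::tibble(term = character(), estimate = numeric(),
                     se = numeric(), z = numeric(), p = numeric()),
      tibble::tibble(group = character(), variance = numeric(),
                     sd = numeric()),
      nrow(dat), FALSE, "binomial-logit",
      note = "degenerate: outcome has a single level"))
  }
  covariates <- covariates[vapply(covariates, function(v) {
    length(unique(dat[[v]])) > 1
  }, logical(1))]
  rhs <- paste(c(predictors, covariates,
                 "(1 | participant_id)", "(1 | stimulus_id)"),
               collapse = " + ")
  form <- stats::as.formula(paste("tasty ~", rhs))
  fit <- suppressMessages(suppressWarnings(
    lme4::glmer(form, data = dat, family = stats::binomial("logit"),
                nAGQ = 0L)))
  coefs <- coef_table_from_lme4(fit)
  converged <- lme4_converged(fit) && all(is.finite(coefs$se)) &&
    all(abs(coefs$estimate) < 15)   # huge logits flag separation
  new_model_fit(coefs, varcomp_from_lme4(fit), nrow(dat), converged,
                "binomial-logit", fit = fit)
}

find_term <- function(terms, parts) {
  hit <- which(vapply(terms, function(tm) {
    bits <- strsplit(tm, ":", fixed = TRUE)[[1]]
    setequal(bits, parts)
  }, logical(1)))
  if (length(hit) != 1) {
    stop(sprintf("term '%s' absent from the model", paste(parts, collapse = ":")),
         call. = FALSE)
  }
  hit
}

#' Simple slopes of UTI within food-type x classification cells
#'
#' From a trial-level mixed model containing `uti_z` and its interactions
#' with food type and classification, computes the UTI slope within each
#' of the four cells and the healthy-minus-unhealthy slope difference
#' within each classification, as linear combinations `L'beta` of the
#' fixed effects with `SE = sqrt(L' V L)` from the coefficient covariance
#' and a normal z-test.
#'
#' @param fit A `uti_model_fit` from [fit_lmm()] carrying its `lme4` fit.
#' @return A list with `slopes` (tibble: food_type, classification,
#'   slope, se, z, p) and `contrasts` (tibble: classification, estimate =
#'   healthy - unhealthy slope difference, se, z, p).
#' @export
simple_slopes <- function(fit) {
  stopifnot(inherits(fit, "uti_model_fit"))
  if (is.null(fit$fit)) {
    stop("simple_slopes() needs the underlying lme4 fit", call. = FALSE)
  }
  beta <- lme4::fixef(fit$fit)
  V <- as.matrix(vcov(fit$fit))
  terms <- names(beta)
  i_uti <- find_term(terms, "uti_z")
  i_uf <- find_term(terms, c("uti_z", "food_typeunhealthy"))
  i_uc <- find_term(terms, c("uti_z", "classificationnot_tasty"))
  i_ufc <- find_term(terms, c("uti_z", "food_typeunhealthy",
                              "classificationnot_tasty"))
  cell_L <- function(unhealthy, not_tasty) {
    L <- numeric(length(beta))
    L[i_uti] <- 1
    if (unhealthy) L[i_uf] <- 1
    if (not_tasty) L[i_uc] <- 1
    if (unhealthy && not_tasty) L[i_ufc] <- 1
    L
  }
  lincomb <- function(L) {
    est <- sum(L * beta)
    se <- sqrt(drop(t(L) %*% V %*% L))
    z <- est / se
    c(est = est, se = se, z = z, p = 2 * pnorm(-abs(z)))
  }
  grid <- expand.grid(food_type = c("healthy", "unhealthy"),
                      classification = c("tasty", "not_tasty"),
                      stringsAsFactors = FALSE)
  slopes <- t(apply(grid, 1, function(row) {
    lincomb(cell_L(row[["food_type"]] == "unhealthy",
                   row[["classification"]] == "not_tasty"))
  }))
  slopes_tb <- tibble::tibble(
    food_type = grid$food_type, classification = grid$classification,
    slope = slopes[, "est"], se = slopes[, "se"], z = slopes[, "z"],
    p = slopes[, "p"]
  )
  contrasts_tb <- dplyr::bind_rows(lapply(c("tasty", "not_tasty"), function(cl) {
    nt <- cl == "not_tasty"
    L <- cell_L(FALSE, nt) - cell_L(TRUE, nt)
    v <- lincomb(L)
    tibble::tibble(classification = cl, estimate = v[["est"]],
                   se = v[["se"]], z = v[["z"]], p = v[["p"]])
  }))
  list(slopes = slopes_tb, contrasts = contrasts_tb)
}

#' Incremental validity of a behavioral index over the explicit scale
#'
#' Nested OLS model comparison: does adding a mouse-tracking difference
#' score improve prediction of the diet quality score beyond the explicit
#' UTI score and demographic covariates? Reports the F-change
#' `((RSS_r - RSS_f)/1) / (RSS_f / df_f)` on (1, df_f) degrees of freedom.
#'
#' @param indices Participant index table (from [participant_indices()]):
#'   needs `dqs`, `uti_explicit`, the added column, and the covariates.
#' @param added Name of the added predictor (`"delta_mad_px"` or
#'   `"delta_rt_ms"`).
#' @param covariates Covariates in both models (kept only when they vary).
#' @return A list `f_change, df1, df2, p, singular, coefficients`
#'   (full-model OLS coefficient table). `singular = TRUE` (with `NA`
#'   statistics) when the added predictor is collinear with the base
#'   model.
#' @export
incremental_validity <- function(indices, added = "delta_mad_px",
                                 covariates = c("age", "gender", "education")) {
  need <- c("dqs", "uti_explicit", added, covariates)
  dat <- indices[complete.cases(indices[, need]), ]
  covariates <- covariates[vapply(covariates, function(v) {
    length(unique(dat[[v]])) > 1
  }, logical(1))]
  base_rhs <- paste(c(covariates, "uti_explicit"), collapse = " + ")
  f_r <- stats::as.formula(paste("dqs ~", base_rhs))
  f_f <- stats::as.formula(paste("dqs ~", base_rhs, "+", added))
  m_r <- lm(f_r, data = dat)
  m_f <- lm(f_f, data = dat)
  if (anyNA(coef(m_f))) {
    return(list(f_change = NA_real_, df1 = NA_integer_, df2 = NA_integer_,
                p = NA_real_, singular = TRUE, coefficients = NULL))
  }
  rss_r <- sum(stats::residuals(m_r)^2)
  rss_f <- sum(stats::residuals(m_f)^2)
  df_f <- m_f$df.residual
  f_change <- (rss_r - rss_f) / (rss_f / df_f)
  sm <- summary(m_f)$coefficients
  list(
    f_change = f_change, df1 = 1L, df2 = df_f,
    p = stats::pf(f_change, 1, df_f, lower.tail = FALSE),
    singular = FALSE,
    coefficients = tibble::tibble(
      term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
      t = sm[, 3], p = sm[, 4])
  )
}

#' Minimum sample size for detecting a correlation (Fisher z)
#'
#' Closed-form power analysis for a product-moment correlation via the
#' Fisher z transformation:
#' `n = ceiling(((z_{1-alpha/tails} + z_{power}) / atanh(|r|))^2 + 3)`.
#'
#' @param r Expected correlation, 0 < |r| < 1.
#' @param alpha Significance level (default 0.05).
#' @param power Target power (default 0.90); must exceed `alpha`.
#' @param tails 1 or 2 (default 2).
#' @return Integer minimum n.
#' @examples
#' power_n_for_r(0.21, alpha = 0.05, power = 0.90, tails = 2)  # 235
#' @export
power_n_for_r <- function(r, alpha = 0.05, power = 0.90, tails = 2) {
  if (!is.finite(r) || abs(r) <= 0 || abs(r) >= 1) {
    stop("r must satisfy 0 < |r| < 1", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1 || power <= alpha || power >= 1) {
    stop("need 0 < alpha < power < 1", call. = FALSE)
  }
  if (!tails %in% c(1, 2)) stop("tails must be 1 or 2", call. = FALSE)
  za <- qnorm(1 - alpha / tails)
  zb <- qnorm(power)
  as.integer(ceiling(((za + zb) / atanh(abs(r)))^2 + 3))
}
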