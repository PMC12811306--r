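test_that("pearson_r matches the computational-formula oracle", {
  expect_equal(pearson_r(1:10, 2 * (1:10) + 1)$r, 1)
  expect_equal(pearson_r(1:10, -(1:10))$r, -1)
  set.seed(31)
  for (i in 1:20) {
    x <- rnorm(25); y <- 0.4 * x + rnorm(25)
    got <- pearson_r(x, y)
    want <- oracle_pearson(x, y)
    expect_equal(got$r, want$r, tolerance = 1e-12)
    expect_equal(got$p, want$p, tolerance = 1e-12)
  }
  expect_error(pearson_r(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(pearson_r(1:2, 2:1), "at least 3")
})

test_that("welch_t matches the textbook formula and its equal-variance limit", {
  same <- c(1, 2, 3, 4)
  expect_equal(welch_t(same, same)$t, 0)
  # equal variances, equal n: Satterthwaite df collapses to n_a + n_b - 2
  a <- c(1, 2, 3, 4, 5); b <- c(11, 12, 13, 14, 15)
  expect_equal(welch_t(a, b)$df, 8)
  set.seed(32)
  for (i in 1:20) {
    x <- rnorm(12, 0, 1); y <- rnorm(17, 0.5, 2)
    got <- welch_t(x, y)
    want <- oracle_welch(x, y)
    expect_equal(got$t, want$t, tolerance = 1e-12)
    expect_equal(got$df, want$df, tolerance = 1e-12)
    expect_equal(got$p, want$p, tolerance = 1e-12)
  }
  expect_error(welch_t(rep(1, 3), rep(1, 4)), "zero variance")
})

test_that("cohens_d_ci recovers known effect sizes with sane intervals", {
  x <- c(1, 2, 3, 4, 5)
  same <- cohens_d_ci(x, x)
  expect_equal(same$d, 0)
  expect_equal(same$lo, -same$hi)

  set.seed(33)
  a <- rnorm(10000)
  b <- rnorm(10000)
  sp <- sqrt((var(a) + var(b)) / 2)
  res <- cohens_d_ci(a + sp, b)
  expect_equal(res$d, 1, tolerance = 0.05)
  expect_true(res$lo < res$d && res$d < res$hi)

  # same effect, doubled data: the interval tightens
  small <- cohens_d_ci(a[1:20] + 1, b[1:20])
  big <- cohens_d_ci(rep(a[1:20], 10) + 1, rep(b[1:20], 10))
  expect_lt(big$hi - big$lo, small$hi - small$lo)

  # hand-check d and the normal-approximation CI against the formulas
  na <- 14; nb <- 19
  xa <- rnorm(na, 1, 2); xb <- rnorm(nb)
  got <- cohens_d_ci(xa, xb)
  d <- (mean(xa) - mean(xb)) /
    sqrt(((na - 1) * var(xa) + (nb - 1) * var(xb)) / (na + nb - 2))
  se <- sqrt((na + nb) / (na * nb) + d^2 / (2 * (na + nb)))
  expect_equal(got$d, d, tolerance = 1e-12)
  expect_equal(got$lo, d - qnorm(0.975) * se, tolerance = 1e-12)
})

test_that("power_n_for_r reproduces the Fisher-z closed form and monotonicity", {
  expect_identical(power_n_for_r(0.21, 0.05, 0.90, 2), 235L)
  # direct evaluation at extreme r
  r <- 0.9999
  expect_identical(power_n_for_r(r),
                   as.integer(ceiling(((qnorm(0.975) + qnorm(0.9)) /
                                         atanh(r))^2 + 3)))
  ns <- vapply(seq(0.1, 0.9, by = 0.1), power_n_for_r, integer(1))
  expect_true(all(diff(ns) < 0))
  expect_error(power_n_for_r(0), "0 < \\|r\\| < 1")
  expect_error(power_n_for_r(0.3, alpha = 0.5, power = 0.4), "alpha")
  expect_error(power_n_for_r(0.3, tails = 3), "tails")
})

# Simulate trial-level data straight from the crossed random-intercept
# model with known coefficients (independent of the cohort generator).
simulate_lmm_data <- function(n_part = 50, n_stim = 20, beta, sd_part = 30,
                              sd_stim = 15, sd_res = 80) {
  grid <- expand.grid(participant_id = sprintf("p%02d", 1:n_part),
                      stimulus_id = sprintf("s%02d", 1:n_stim),
                      stringsAsFactors = FALSE)
  grid$food_type <- factor(ifelse(as.integer(sub("s", "", grid$stimulus_id))
                                  <= n_stim / 2, "healthy", "unhealthy"),
                           levels = c("healthy", "unhealthy"))
  grid$classification <- factor(sample(c("tasty", "not_tasty"),
                                       nrow(grid), TRUE, c(0.75, 0.25)),
                                levels = c("tasty", "not_tasty"))
  uti <- setNames(rnorm(n_part), unique(grid$participant_id))
  grid$uti_z <- unname(uti[grid$participant_id])
  re_p <- setNames(rnorm(n_part, 0, sd_part), unique(grid$participant_id))
  re_s <- setNames(rnorm(n_stim, 0, sd_stim), unique(grid$stimulus_id))
  X <- model.matrix(~ food_type * classification * uti_z, grid)
  grid$rt_ms <- drop(X %*% beta) + re_p[grid$participant_id] +
    re_s[grid$stimulus_id] + rnorm(nrow(grid), 0, sd_res)
  grid$mad_px <- grid$rt_ms
  grid$sample_entropy <- NA_real_
  grid$degenerate <- FALSE
  grid$excluded_rt <- FALSE
  grid$excluded_mad <- FALSE
  grid$trial_id <- sprintf("t%04d", seq_len(nrow(grid)))
  grid$age <- 40
  grid$gender <- "female"
  grid$education <- "bachelor"
  tibble::as_tibble(grid)
}

beta_true <- c(900, 40, 150, 30, 20, -25, -15, 20)

test_that("fit_lmm recovers known fixed effects from crossed-design data", {
  set.seed(41)
  hits <- 0; total <- 0
  for (rep in 1:10) {
    dat <- simulate_lmm_data(beta = beta_true)
    fit <- fit_lmm(dat, "rt_ms")
    expect_s3_class(fit, "uti_model_fit")
    ct <- fit$coefficients
    ix <- match(colnames(model.matrix(~ food_type * classification * uti_z,
                                      dat)), ct$term)
    expect_false(anyNA(ix))
    hits <- hits + sum(abs(ct$estimate[ix] - beta_true) <= 2 * ct$se[ix])
    total <- total + length(beta_true)
  }
  expect_gte(hits / total, 0.9)
})

test_that("fit_lmm on a constant outcome returns the trivial exact fit", {
  set.seed(42)
  dat <- simulate_lmm_data(n_part = 10, n_stim = 6, beta = rep(0, 8))
  dat$rt_ms <- 500
  fit <- fit_lmm(dat, "rt_ms")
  expect_true(fit$converged)
  expect_equal(fit$coefficients$estimate[1], 500)
  expect_true(all(fit$coefficients$estimate[-1] == 0))
  expect_true(all(fit$varcomp$variance == 0))
})

test_that("simple slopes match prediction-difference and quadratic-form oracles", {
  set.seed(43)
  dat <- simulate_lmm_data(beta = beta_true)
  fit <- fit_lmm(dat, "rt_ms")
  ss <- simple_slopes(fit)

  # estimate oracle: slope = prediction at uti_z=1 minus at uti_z=0
  nd <- expand.grid(food_type = factor(c("healthy", "unhealthy"),
                                       levels = c("healthy", "unhealthy")),
                    classification = factor(c("tasty", "not_tasty"),
                                            levels = c("tasty", "not_tasty")))
  p1 <- predict(fit$fit, cbind(nd, uti_z = 1), re.form = NA)
  p0 <- predict(fit$fit, cbind(nd, uti_z = 0), re.form = NA)
  slopes_oracle <- p1 - p0
  key <- paste(ss$slopes$food_type, ss$slopes$classification)
  want <- slopes_oracle[match(key, paste(nd$food_type, nd$classification))]
  expect_equal(ss$slopes$slope, unname(want), tolerance = 1e-10)

  # SE oracle: L from model-matrix differences, SE^2 = L' V L
  V <- as.matrix(vcov(fit$fit))
  mmrow <- function(ft, cl, u) {
    model.matrix(~ food_type * classification * uti_z,
                 data.frame(food_type = factor(ft, levels = levels(nd$food_type)),
                            classification = factor(cl, levels = levels(nd$classification)),
                            uti_z = u))[1, ]
  }
  for (cl in c("tasty", "not_tasty")) {
    L <- (mmrow("healthy", cl, 1) - mmrow("healthy", cl, 0)) -
      (mmrow("unhealthy", cl, 1) - mmrow("unhealthy", cl, 0))
    est <- sum(L * lme4::fixef(fit$fit))
    se <- sqrt(drop(t(L) %*% V %*% L))
    row <- ss$contrasts[ss$contrasts$classification == cl, ]
    expect_equal(row$estimate, est, tolerance = 1e-10)
    expect_equal(row$se, se, tolerance = 1e-10)
    expect_equal(row$z, est / se, tolerance = 1e-10)
  }
})

test_that("simple slope contrasts vanish when interaction terms are zero", {
  set.seed(44)
  beta0 <- c(900, 40, 150, 30, 0, 0, 0, 0)   # no interactions at all
  zs <- vapply(1:5, function(i) {
    dat <- simulate_lmm_data(beta = beta0)
    ss <- simple_slopes(fit_lmm(dat, "rt_ms"))
    max(abs(ss$contrasts$z))
  }, numeric(1))
  # both contrasts are null quantities: |z| beyond 3 would be surprising
  expect_lt(max(zs), 3.5)
  expect_gt(mean(zs < 1.96), 0.5)
})

test_that("a tasty-only conflict effect shows up only within tasty responses", {
  set.seed(45)
  sig <- matrix(NA, 8, 2)
  for (i in 1:8) {
    co <- simulate_cohort(sim_config(n_participants = 120, seed = 500 + i))
    m <- compute_trial_metrics(co$samples, co$trials, sampen = FALSE)
    excl <- exclude_outliers(m)
    dat <- prepare_trial_data(excl$metrics, co$trials, co$participants)
    ss <- simple_slopes(fit_lmm(dat, "rt_ms"))
    sig[i, ] <- ss$contrasts$p < 0.05
    # contrast within tasty is healthy > unhealthy UTI slope (negative
    # healthy-minus... positive: slope_healthy - slope_unhealthy > 0)
  }
  # conflict enters healthy x tasty only: the tasty contrast should fire
  # in the majority of runs, the not-tasty contrast should mostly not
  expect_gte(sum(sig[, 1]), 5)
  expect_lte(sum(sig[, 2]), 3)
})

test_that("choice GLMM recovers the condition x food-type shift and flags degenerate input", {
  set.seed(46)
  signs <- vapply(1:10, function(i) {
    co <- simulate_cohort(sim_config(n_participants = 80, seed = 600 + i,
                                     delta_cond = 0.8),
                          conditions = rep(c("utilitarian", "hedonic"),
                                           length.out = 80))
    m <- compute_trial_metrics(co$samples, co$trials, sampen = FALSE)
    dat <- prepare_trial_data(m, co$trials, co$participants)
    fit <- fit_glmm_choice(dat)
    ct <- fit$coefficients
    term <- grep("conditionhedonic.*food_typeunhealthy|food_typeunhealthy.*conditionhedonic",
                 ct$term)
    # hedonic lowers tasty for healthy only: positive interaction on the
    # unhealthy dummy under treatment coding
    ct$estimate[term] > 0
  }, logical(1))
  expect_gte(sum(signs), 9)

  d <- tiny_dataset()
  d$trials$classification <- "tasty"
  d$trials$response_side <- "left"
  m <- compute_trial_metrics(d$samples, d$trials, sampen = FALSE)
  dat <- prepare_trial_data(m, d$trials, d$participants)
  fit <- fit_glmm_choice(dat)
  expect_false(fit$converged)
  expect_match(fit$note, "degenerate")
})

test_that("choice GLMM interaction is calibrated under a null generator", {
  set.seed(47)
  zs <- vapply(1:25, function(i) {
    co <- simulate_cohort(sim_config(n_participants = 40, seed = 700 + i,
                                     repetitions = 1, delta_cond = 0),
                          conditions = rep(c("utilitarian", "hedonic"),
                                           length.out = 40))
    m <- compute_trial_metrics(co$samples, co$trials, sampen = FALSE)
    dat <- prepare_trial_data(m, co$trials, co$participants)
    ct <- fit_glmm_choice(dat)$coefficients
    term <- grep("conditionhedonic.*food_typeunhealthy|food_typeunhealthy.*conditionhedonic",
                 ct$term)
    abs(ct$z[term])
  }, numeric(1))
  # ~95% of null runs should stay under 1.96; allow binomial slack
  expect_gte(mean(zs < 1.96), 0.8)
})

test_that("incremental validity: F-change oracle, singularity, null rate, recovery", {
  set.seed(48)
  n <- 120
  idx <- tibble::tibble(
    participant_id = sprintf("p%03d", 1:n),
    age = round(runif(n, 18, 70)),
    gender = sample(c("female", "male"), n, TRUE),
    education = sample(c("secondary", "bachelor"), n, TRUE),
    uti_explicit = runif(n, 1, 7))
  idx$delta_mad_px <- 10 - 2 * idx$uti_explicit + rnorm(n, 0, 5)
  idx$dqs <- 14 - 0.5 * idx$uti_explicit - 0.1 * idx$delta_mad_px +
    rnorm(n, 0, 1.5)

  res <- incremental_validity(idx, "delta_mad_px")
  X_r <- model.matrix(~ age + gender + education + uti_explicit, idx)
  X_f <- cbind(X_r, idx$delta_mad_px)
  want <- oracle_f_change(idx$dqs, X_r, X_f)
  expect_equal(res$f_change, want$f, tolerance = 1e-10)
  expect_equal(res$df2, want$df2)
  expect_equal(res$p, want$p, tolerance = 1e-10)

  # duplicated predictor: flagged singular, no statistics invented
  idx$dup <- idx$uti_explicit
  expect_true(incremental_validity(idx, "dup")$singular)

  # null: an added variable unrelated to the residual rarely "improves"
  rejections <- vapply(1:200, function(i) {
    idx$noise <- rnorm(n)
    incremental_validity(idx, "noise")$p < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.005)
  expect_lte(mean(rejections), 0.10)
})

test_that("behavioral indices add predictive validity for diet quality in the generator", {
  hits <- vapply(1:8, function(i) {
    co <- simulate_cohort(sim_config(n_participants = 150, seed = 800 + i))
    m <- compute_trial_metrics(co$samples, co$trials, sampen = FALSE)
    agg <- participant_indices(m, co$trials, co$participants)
    incremental_validity(agg$indices, "delta_mad_px")$p < 0.05
  }, logical(1))
  expect_gt(sum(hits), 4)
})
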