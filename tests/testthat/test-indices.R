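make_metrics <- function(rt, mad = rep(0, length(rt)),
                         pid = rep("p1", length(rt))) {
  tibble::tibble(
    participant_id = pid,
    trial_id = sprintf("t%03d", seq_along(rt)),
    rt_ms = rt, mad_px = mad, mad_unit = mad / 1000,
    sample_entropy = NA_real_, degenerate = FALSE,
    excluded_rt = FALSE, excluded_mad = FALSE)
}

test_that("a single gross RT outlier is the only trial flagged", {
  rt <- c(rep(500, 100), 10000)
  m <- make_metrics(rt)
  res <- exclude_outliers(m, k = 3)
  expect_equal(which(res$metrics$excluded_rt), 101L)
  expect_equal(sum(res$metrics$excluded_rt), 1L)
  # report numbers recomputed directly, outlier included in mean/SD
  expect_equal(res$report$mean[1], mean(rt))
  expect_equal(res$report$sd[1], sd(rt))
  expect_equal(res$report$fraction_excluded[1], 1 / 101)
})

test_that("identical values yield zero exclusions and tails are configurable", {
  m <- make_metrics(rep(700, 10), mad = rep(3, 10))
  res <- exclude_outliers(m)
  expect_equal(sum(res$metrics$excluded_rt), 0L)
  expect_equal(sum(res$metrics$excluded_mad), 0L)

  # MAD rule is upper-tail only by default: a low outlier survives
  m2 <- make_metrics(rep(700, 30), mad = c(rep(10, 29), -200))
  res2 <- exclude_outliers(m2)
  expect_equal(sum(res2$metrics$excluded_mad), 0L)
  res3 <- exclude_outliers(m2, mad_two_sided = TRUE)
  expect_equal(which(res3$metrics$excluded_mad), 30L)

  expect_error(exclude_outliers(make_metrics(c(1))), "at least 2")
})

test_that("exclusion flags are order-independent", {
  set.seed(8)
  m <- make_metrics(rnorm(60, 800, 300), mad = rnorm(60, 50, 40),
                    pid = rep(c("a", "b"), 30))
  perm <- sample(nrow(m))
  f1 <- exclude_outliers(m)$metrics
  f2 <- exclude_outliers(m[perm, ])$metrics
  f2 <- f2[order(match(f2$trial_id, f1$trial_id)), ]
  expect_equal(f1$excluded_rt, f2$excluded_rt)
  expect_equal(f1$excluded_mad, f2$excluded_mad)
})

test_that("difference scores are healthy-minus-unhealthy cell means", {
  d <- tiny_dataset()
  m <- compute_trial_metrics(d$samples, d$trials, sampen = FALSE)
  # make the healthy trials of p01 exactly 50 ms slower on average
  m$rt_ms <- rep(750, nrow(m))
  hp <- m$participant_id == "p01" &
    m$trial_id %in% d$trials$trial_id[d$trials$food_type == "healthy"]
  m$rt_ms[m$participant_id == "p01"] <- ifelse(hp[m$participant_id == "p01"],
                                               800, 750)
  ds <- difference_scores(m, d$trials)
  expect_equal(ds$delta_rt_ms[ds$participant_id == "p01"], 50)
  expect_equal(ds$delta_rt_ms[ds$participant_id == "p02"], 0)

  # swapping food-type labels negates both deltas exactly
  tr2 <- d$trials
  tr2$food_type <- ifelse(tr2$food_type == "healthy", "unhealthy", "healthy")
  ds2 <- difference_scores(m, tr2)
  expect_equal(ds2$delta_rt_ms, -ds$delta_rt_ms)
  expect_equal(ds2$delta_mad_px, -ds$delta_mad_px)
})

test_that("an empty cell leaves the delta missing with a warning", {
  d <- tiny_dataset()
  m <- compute_trial_metrics(d$samples, d$trials, sampen = FALSE)
  m$excluded_rt[m$participant_id == "p02" &
                  m$trial_id %in% c("t1", "t3")] <- TRUE
  m$excluded_mad[m$participant_id == "p02" &
                   m$trial_id %in% c("t1", "t3")] <- TRUE
  expect_warning(ds <- difference_scores(m, d$trials), "empty")
  expect_true(is.na(ds$delta_rt_ms[ds$participant_id == "p02"]))
  expect_false(is.na(ds$delta_rt_ms[ds$participant_id == "p01"]))
})

test_that("explicit UTI scale scoring is the item mean with range checks", {
  expect_equal(score_uti_scale(c(7, 7, 7)), 7)
  expect_equal(score_uti_scale(c(1, 4, 7)), 4)
  set.seed(4)
  m <- matrix(sample(1:7, 30, replace = TRUE), ncol = 3)
  expect_equal(score_uti_scale(m), rowMeans(m))
  expect_error(score_uti_scale(c(0, 4, 4)), "\\[1, 7\\]")
})

test_that("Cronbach's alpha matches the covariance-matrix oracle", {
  m <- matrix(rep(c(2, 5, 3, 7), 3), ncol = 3)    # identical columns
  expect_equal(cronbach_alpha(m), 1)
  set.seed(14)
  r <- matrix(rnorm(30), ncol = 3)
  expect_equal(cronbach_alpha(r), oracle_alpha(r), tolerance = 1e-12)
  expect_true(is.na(cronbach_alpha(matrix(c(1, 1, 2, 2), 2))))
})

test_that("simulated explicit items are internally consistent", {
  co <- simulate_cohort(sim_config(n_participants = 200, seed = 2))
  a <- cronbach_alpha(co$participants[, paste0("uti_item_", 1:3)])
  expect_gt(a, 0.8)
})

test_that("classification proportions count cells correctly", {
  d <- tiny_dataset()
  cp <- classification_proportions(d$trials)
  # fixture: per participant, healthy trials t1 (tasty) and t3 (not), so 0.5
  expect_equal(cp$p_tasty, c(0.5, 0.5))
  all_tasty <- d$trials
  all_tasty$classification <- "tasty"
  expect_equal(classification_proportions(all_tasty)$p_tasty, c(1, 1))

  grp <- classification_proportions(
    d$trials, grouping = data.frame(participant_id = c("p01", "p02"),
                                    g = c("low", "high")))
  expect_equal(nrow(grp), 4)
  expect_equal(sort(unique(grp$group)), c("high", "low"))
})

test_that("high-UTI agents classify fewer healthy foods as tasty", {
  signs <- vapply(1:10, function(seed) {
    co <- simulate_cohort(sim_config(n_participants = 80, seed = seed))
    uti <- score_uti_scale(co$participants[, paste0("uti_item_", 1:3)])
    grp <- tibble::tibble(participant_id = co$participants$participant_id,
                          g = median_split(uti))
    cp <- classification_proportions(co$trials, grouping = grp)
    ph <- function(g) cp$p_tasty[cp$group == g & cp$food_type == "healthy"]
    ph("high") < ph("low")
  }, logical(1))
  expect_gte(sum(signs), 9)
})

test_that("median split ties go low and group sizes stay balanced", {
  expect_equal(median_split(1:10), rep(c("low", "high"), each = 5))
  # odd n: the median observation is labeled low
  expect_equal(median_split(c(1, 2, 3)), c("low", "low", "high"))
  set.seed(6)
  x <- sample(1:7, 51, replace = TRUE)
  g <- median_split(x)
  n_ties <- sum(x == median(x))
  # ties all go low, so the imbalance is bounded by twice the tie count
  expect_lte(abs(sum(g == "low") - sum(g == "high")), 2 * n_ties)
  expect_error(median_split(rep(4, 5)), "distinct")
})

test_that("difference scores under a null generator are centered at zero", {
  deltas <- vapply(1:30, function(seed) {
    # all conflict effects off, including the not-tasty bump: with kappa2
    # active, the food types' different tasty rates would shift the cell
    # means apart even without any trait effect
    co <- simulate_cohort(sim_config(n_participants = 12, seed = 400 + seed,
                                     repetitions = 1, kappa1 = 0, kappa2 = 0,
                                     alpha2 = 0, delta_cond = 0))
    m <- compute_trial_metrics(co$samples, co$trials, sampen = FALSE)
    mean(difference_scores(m, co$trials)$delta_mad_px, na.rm = TRUE)
  }, numeric(1))
  expect_lt(abs(mean(deltas)), 2 * sd(deltas) / sqrt(length(deltas)))
})
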