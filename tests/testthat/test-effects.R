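two_level_cohort <- function(n1_pos, n1_tot, n2_pos, n2_tot) {
  n <- n1_tot + n2_tot
  eln <- rep(c(1L, 2L), c(n1_tot, n2_tot))
  pos <- c(rep(c(1L, 0L), c(n1_pos, n1_tot - n1_pos)),
           rep(c(1L, 0L), c(n2_pos, n2_tot - n2_pos)))
  as_cohort(data.frame(
    patient_id = sprintf("X%04d", 1:n), age = 65,
    sex = "male", histology = "adenocarcinoma", t_stage = "T1",
    tumor_location = "upper_lobe", operation_type = "lobectomy",
    eln_count = eln, positive_count = pos * eln,
    n_stage = ifelse(pos > 0, "node_positive", "node_negative"),
    time = 1, event = 0, stringsAsFactors = FALSE))
}

test_that("unadjusted two-level logistic fit equals the cross-product odds ratio", {
  co <- two_level_cohort(30, 100, 50, 100)
  fit <- fit_stage_migration(co, adjusters = character(0))
  eff <- eln_effect(fit)
  expect_equal(eff$effect, (50 / 50) / (30 / 70), tolerance = 1e-6)
})

test_that("unadjusted two-group Cox fit matches the exponential rate ratio", {
  set.seed(51)
  n <- 800
  eln <- rep(c(1L, 2L), each = n)
  tt <- c(rexp(n, 0.25), rexp(n, 0.15))
  co <- as_cohort(data.frame(
    patient_id = sprintf("C%04d", 1:(2 * n)), age = 65, sex = "male",
    histology = "adenocarcinoma", t_stage = "T1",
    tumor_location = "upper_lobe", operation_type = "lobectomy",
    eln_count = eln, positive_count = 0L, n_stage = "node_negative",
    time = tt, event = 1L, stringsAsFactors = FALSE))
  fit <- fit_survival_model(co, subset = "all", adjusters = character(0))
  closed_form <- (sum(eln == 2) / sum(tt[eln == 2])) /
                 (sum(eln == 1) / sum(tt[eln == 1]))
  expect_equal(eln_effect(fit)$effect, closed_form, tolerance = 0.02)
})

test_that("model fits are invariant to row order and patient relabeling", {
  co <- generate_cohort(generator_config(n_patients = 4000, seed = 52))
  perm <- sample(nrow(co))
  shuffled <- as.data.frame(co)[perm, ]
  shuffled$patient_id <- sprintf("Z%05d", seq_len(nrow(shuffled)))
  a <- eln_effect(fit_stage_migration(co))
  b <- eln_effect(fit_stage_migration(as_cohort(shuffled)))
  expect_equal(a$estimate, b$estimate, tolerance = 1e-9)
  a2 <- eln_effect(fit_survival_model(co, "node_negative"))
  b2 <- eln_effect(fit_survival_model(as_cohort(shuffled), "node_negative"))
  expect_equal(a2$estimate, b2$estimate, tolerance = 1e-9)
})

test_that("adding an unrelated covariate barely moves the ELN estimate", {
  co <- generate_cohort(generator_config(n_patients = 20000, seed = 53))
  base <- eln_effect(fit_survival_model(co, "node_negative"))
  set.seed(99)
  df <- as.data.frame(co)
  df$noise <- rnorm(nrow(df))
  aug <- eln_effect(fit_survival_model(
    as_cohort(df), "node_negative",
    adjusters = c("sex", "age", "histology", "t_stage", "operation_type",
                  "noise")))
  expect_lt(abs(aug$estimate - base$estimate), 0.5 * base$se)
})

test_that("effect series has a zero reference, pooled sparse levels and enough levels", {
  co <- generate_cohort(generator_config(n_patients = 20000, seed = 54))
  ser <- eln_effect_series(co, "survival", "node_negative")
  expect_equal(ser$estimate[1], 0)
  expect_equal(ser$se[1], 0)
  expect_true(all(ser$n >= 20))
  expect_true(attr(ser, "reference_is_one"))
  map <- attr(ser, "pooling_map")
  expect_equal(sum(map$n), sum(co$n_stage == "node_negative"))

  tiny <- generate_cohort(generator_config(n_patients = 120, seed = 55))
  expect_error(eln_effect_series(tiny, "survival", "node_negative",
                                 sparsity_floor = 40), "at least 5")
})

test_that("null generator yields a flat series; benefit generator a decreasing one", {
  null_co <- simulate_glm_cohort(30000, 0, 0, seed = 56)
  ser0 <- eln_effect_series(null_co, "survival", "all")
  z <- abs(ser0$estimate[-1] / ser0$se[-1])
  expect_lt(mean(z > 1.96), 0.2)

  ben <- generate_cohort(generator_config(n_patients = 50000, seed = 57))
  ser1 <- eln_effect_series(ben, "survival", "node_negative")
  ct <- suppressWarnings(
    stats::cor.test(ser1$eln, ser1$estimate, method = "spearman"))
  expect_lt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.05)
})

test_that("interaction test is calibrated under the null and powered under effect", {
  set.seed(58)
  base <- generator_config(n_patients = 2000)
  pvals <- replicate(100, {
    co <- simulate_glm_cohort(2000, eln_logodds = 0.03, config = base)
    interaction_test(co, "stage_migration")$p_value
  })
  rej <- mean(pvals < 0.05)
  expect_gt(rej, 0.004)
  expect_lt(rej, 0.13)

  # effect confined to one histology: strong interaction signal
  set.seed(59)
  n <- 30000
  hist <- sample(c("adenocarcinoma", "squamous"), n, replace = TRUE)
  eln <- sample(1:30, n, replace = TRUE)
  lp <- -1.5 + 0.06 * eln * (hist == "adenocarcinoma")
  pos <- rbinom(n, 1, stats::plogis(lp))
  co <- as_cohort(data.frame(
    patient_id = sprintf("I%05d", 1:n), age = 65,
    sex = sample(c("male", "female"), n, replace = TRUE),
    histology = hist,
    t_stage = sample(c("T1", "T2"), n, replace = TRUE),
    tumor_location = sample(c("upper_lobe", "lower_lobe"), n, replace = TRUE),
    operation_type = sample(c("lobectomy", "sublobar"), n, replace = TRUE),
    eln_count = eln, positive_count = pos,
    n_stage = ifelse(pos > 0, "node_positive", "node_negative"),
    time = 1, event = 0, stringsAsFactors = FALSE))
  expect_lt(interaction_test(co, "stage_migration")$p_value, 1e-6)

  # coarse partition pooling bronchoalveolar with large-cell carcinoma
  co2 <- generate_cohort(generator_config(n_patients = 8000, seed = 60))
  grp <- list(low_eln_sensitivity = c("bronchoalveolar", "large_cell"),
              rest = c("adenocarcinoma", "squamous", "other"))
  res <- interaction_test(co2, "survival", grouping = grp)
  expect_true(res$p_value >= 0 && res$p_value <= 1)
  expect_equal(res$df, 1)

  single <- as.data.frame(co2)
  single$histology <- "adenocarcinoma"
  expect_error(interaction_test(as_cohort(single), "stage_migration"),
               "at least two histology groups")
})

test_that("mean positive series equals direct tabulation", {
  co <- toy_cohort()
  ser <- mean_positive_series(co, sparsity_floor = 1)
  direct <- tapply(co$positive_count, co$eln_count, mean)
  expect_equal(ser$mean_positive, as.numeric(direct))
  expect_equal(ser$eln, as.numeric(names(direct)))

  big <- generate_cohort(generator_config(n_patients = 10000, seed = 61))
  ser2 <- mean_positive_series(big)
  map <- attr(ser2, "pooling_map")
  pool <- elncut:::pool_eln_levels(big$eln_count, 20)
  direct2 <- tapply(big$positive_count, pool$assignment, mean)
  expect_equal(ser2$mean_positive, as.numeric(direct2), tolerance = 1e-12)
})

test_that("all-negative cohorts give an all-zero mean positive series", {
  co <- generate_cohort(generator_config(n_patients = 2000, seed = 62,
                                         positivity_logodds = list(intercept = -Inf)))
  ser <- mean_positive_series(co)
  expect_true(all(ser$mean_positive == 0))
})

test_that("positive-vs-examined regression recovers exact and degenerate cases", {
  # exactly proportional: mean positives = 0.1 * eln
  n_per <- 10
  lv <- c(10L, 20L, 30L, 40L, 50L)
  co <- as_cohort(data.frame(
    patient_id = sprintf("R%03d", 1:(5 * n_per)), age = 65, sex = "male",
    histology = "adenocarcinoma", t_stage = "T1",
    tumor_location = "upper_lobe", operation_type = "lobectomy",
    eln_count = rep(lv, each = n_per),
    positive_count = rep(lv / 10, each = n_per),
    n_stage = "node_positive", time = 1, event = 0,
    stringsAsFactors = FALSE))
  res <- positive_vs_examined_regression(co, sparsity_floor = 1)
  expect_equal(res$r_squared, 1, tolerance = 1e-12)
  expect_equal(res$slope, 0.1, tolerance = 1e-12)

  flat <- co
  flat$positive_count <- 2L
  res0 <- positive_vs_examined_regression(as_cohort(flat), sparsity_floor = 1)
  expect_true(is.na(res0$r_squared))
  expect_match(res0$note, "constant")
})

test_that("regression R-squared matches an independent least-squares computation", {
  co <- generate_cohort(generator_config(n_patients = 20000, seed = 63))
  res <- positive_vs_examined_regression(co)
  x <- res$series$eln; y <- res$series$mean_positive
  bhat <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  ahat <- mean(y) - bhat * mean(x)
  r2 <- 1 - sum((y - ahat - bhat * x)^2) / sum((y - mean(y))^2)
  expect_equal(res$slope, bhat, tolerance = 1e-10)
  expect_equal(res$r_squared, r2, tolerance = 1e-10)
})
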