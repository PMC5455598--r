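# Adjuster sets for the two outcome models: stage migration is adjusted for
# tumor/operative factors associated with nodal yield; survival for the
# prognostic factors.
migration_adjusters <- c("histology", "t_stage", "tumor_location", "operation_type")
survival_adjusters  <- c("sex", "age", "histology", "t_stage", "operation_type")

take_subset <- function(cohort, subset = c("all", "node_negative", "node_positive")) {
  subset <- match.arg(subset)
  out <- switch(subset,
    all = cohort,
    node_negative = cohort[cohort$n_stage == "node_negative", , drop = FALSE],
    node_positive = cohort[cohort$n_stage == "node_positive", , drop = FALSE])
  attr(out, "subset") <- subset
  out
}

model_frame <- function(cohort, vars) {
  df <- as.data.frame(cohort)[, unique(vars), drop = FALSE]
  for (nm in names(df)) if (is.factor(df[[nm]])) df[[nm]] <- droplevels(df[[nm]])
  df
}

new_model_fit <- function(fit, outcome, adjusters, n_used, eln_term = "eln_count") {
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  keep <- !is.na(est)
  est <- est[keep]; se <- se[names(est)]
  z <- est / se
  tab <- data.frame(
    term = names(est),
    estimate = unname(est),
    se = unname(se),
    ci_lower = unname(est - qnorm(0.975) * se),
    ci_upper = unname(est + qnorm(0.975) * se),
    p_value = unname(2 * stats::pnorm(-abs(z))),
    row.names = NULL
  )
  structure(list(outcome = outcome, coefficients = tab, n_used = n_used,
                 adjusters = adjusters, eln_term = eln_term, fit = fit),
            class = "eln_model_fit")
}

#' Extract the per-ELN effect from a fitted model
#' @param fit an `eln_model_fit`.
#' @return one-row data frame with the log-scale estimate, its exponentiated
#'   value (OR or HR per additional examined node), CI and p-value.
#' @export
eln_effect <- function(fit) {
  stopifnot(inherits(fit, "eln_model_fit"))
  row <- fit$coefficients[fit$coefficients$term == fit$eln_term, , drop = FALSE]
  if (nrow(row) == 0) stop("model has no ELN term", call. = FALSE)
  row$effect <- exp(row$estimate)
  row$effect_ci_lower <- exp(row$ci_lower)
  row$effect_ci_upper <- exp(row$ci_upper)
  row$outcome <- fit$outcome
  row
}

#' @export
print.eln_model_fit <- function(x, ...) {
  eff <- eln_effect(x)
  lab <- if (x$outcome == "stage_migration") "OR" else "HR"
  cat(sprintf("%s model (n = %d; adjusted for %s)\n", x$outcome, x$n_used,
              paste(x$adjusters, collapse = ", ")))
  cat(sprintf("  per-ELN %s = %.3f (95%% CI %.3f-%.3f), p = %.3g\n", lab,
              eff$effect, eff$effect_ci_lower, eff$effect_ci_upper, eff$p_value))
  invisible(x)
}

#' Adjusted logistic model of stage migration
#'
#' Binary logistic regression of declared node positivity on the ELN count
#' (continuous), adjusted for histology, T stage, tumor location and
#' operation type. The exponentiated ELN coefficient is the odds ratio of
#' being staged node-positive per additional examined node — the population
#' stage-migration effect.
#'
#' @param cohort an `eln_cohort`.
#' @param adjusters covariates to adjust for.
#' @return an `eln_model_fit` with outcome `"stage_migration"`.
#' @export
fit_stage_migration <- function(cohort, adjusters = migration_adjusters) {
  cohort <- as_cohort(cohort)
  if (length(unique(cohort$n_stage)) < 2) {
    stop("both node-stage categories must be present to model stage migration",
         call. = FALSE)
  }
  df <- model_frame(cohort, c("n_stage", "eln_count", adjusters))
  df$node_positive <- as.integer(df$n_stage == "node_positive")
  fml <- as.formula(paste("node_positive ~",
                          paste(c("eln_count", adjusters), collapse = " + ")))
  fit <- glm(fml, data = df, family = binomial())
  if (!fit$converged) {
    stop("logistic model did not converge (possible complete separation)",
         call. = FALSE)
  }
  new_model_fit(fit, "stage_migration", adjusters, nrow(df))
}

#' Adjusted Cox model of overall survival
#'
#' Cox proportional hazards regression of survival on the ELN count
#' (continuous), adjusted for sex, age, histology, T stage and operation
#' type, with the Efron approximation for tied event times. The
#' exponentiated ELN coefficient is the hazard ratio per additional
#' examined node. With `include_positive_count = TRUE` the number of
#' positive nodes enters as an additional covariate, which asks whether the
#' examined count is prognostic beyond the positive count it uncovers.
#'
#' @param cohort an `eln_cohort`.
#' @param subset `"all"`, `"node_negative"` or `"node_positive"`.
#' @param include_positive_count add `positive_count` as a covariate.
#' @param adjusters covariates to adjust for.
#' @return an `eln_model_fit` with outcome `"survival"`.
#' @export
fit_survival_model <- function(cohort,
                               subset = c("all", "node_negative", "node_positive"),
                               include_positive_count = FALSE,
                               adjusters = survival_adjusters) {
  cohort <- take_subset(as_cohort(cohort), subset)
  if (nrow(cohort) == 0) stop("survival subset is empty", call. = FALSE)
  if (sum(cohort$event) < 1) {
    stop("survival subset contains no events", call. = FALSE)
  }
  vars <- c("time", "event", "eln_count", adjusters,
            if (include_positive_count) "positive_count")
  df <- model_frame(cohort, vars)
  rhs <- c("eln_count", adjusters,
           if (include_positive_count) "positive_count")
  fml <- as.formula(paste("Surv(time, event) ~", paste(rhs, collapse = " + ")))
  fit <- coxph(fml, data = df, ties = "efron")
  out <- new_model_fit(fit, "survival", adjusters, nrow(df))
  out$subset <- attr(cohort, "subset")
  out$include_positive_count <- include_positive_count
  out
}

# Pool sparse ELN levels: levels above the terminal quantile form one tail
# bin, then any level with fewer patients than the floor is merged with its
# nearest retained neighbor until every bin clears the floor.
pool_eln_levels <- function(eln, sparsity_floor = 20, terminal_quantile = 0.99) {
  q_hi <- as.numeric(quantile(eln, terminal_quantile, type = 1))
  lvls <- sort(unique(eln))
  groups <- lapply(lvls[lvls <= q_hi], function(l) l)
  tail_lvls <- lvls[lvls > q_hi]
  if (length(tail_lvls) > 0) groups <- c(groups, list(tail_lvls))

  counts <- vapply(groups, function(g) sum(eln %in% g), numeric(1))
  while (length(groups) > 1 && min(counts) < sparsity_floor) {
    i <- which.min(counts)
    j <- if (i == 1) 2L
         else if (i == length(groups)) i - 1L
         else if (counts[i - 1] <= counts[i + 1]) i - 1L else i + 1L
    a <- min(i, j); b <- max(i, j)
    groups[[a]] <- c(groups[[a]], groups[[b]])
    groups[[b]] <- NULL
    counts <- vapply(groups, function(g) sum(eln %in% g), numeric(1))
  }

  x <- vapply(groups, function(g) {
    w <- vapply(g, function(l) sum(eln == l), numeric(1))
    sum(g * w) / sum(w)
  }, numeric(1))
  assignment <- integer(length(eln))
  for (gi in seq_along(groups)) assignment[eln %in% groups[[gi]]] <- gi
  map <- data.frame(group = seq_along(groups), x = x, n = counts)
  map$raw_levels <- vapply(groups, function(g) paste(sort(g), collapse = ","),
                           character(1))
  list(assignment = assignment, map = map)
}

#' Per-ELN-count effect series against a reference of one examined node
#'
#' The ELN count enters the adjusted logistic (stage migration) or Cox
#' (survival) model as a categorical factor; the coefficient of each level
#' is the log OR or log HR of that examined-node count relative to the
#' reference count of one node (or the smallest observed count, recorded in
#' the output). Raw counts with fewer than `sparsity_floor` patients are
#' pooled with their nearest neighbor, and counts above the 99th percentile
#' form a terminal bin; the pooling map is returned. This series is the
#' input to LOWESS smoothing and the structural-break scan.
#'
#' @param cohort an `eln_cohort`.
#' @param outcome `"stage_migration"` or `"survival"`.
#' @param subset survival subset (ignored for stage migration).
#' @param sparsity_floor minimum patients per retained ELN level.
#' @return an `eln_effect_series`: data frame with columns `eln` (the
#'   patient-weighted mean examined count of the bin), `estimate` (log
#'   scale, 0 at the reference), `se`, `n`; attributes carry the outcome,
#'   adjusters, reference level and pooling map.
#' @export
eln_effect_series <- function(cohort,
                              outcome = c("stage_migration", "survival"),
                              subset = c("all", "node_negative", "node_positive"),
                              sparsity_floor = 20) {
  outcome <- match.arg(outcome)
  cohort <- as_cohort(cohort)
  if (outcome == "survival") cohort <- take_subset(cohort, subset)

  pool <- pool_eln_levels(cohort$eln_count, sparsity_floor)
  if (nrow(pool$map) < 5) {
    stop(sprintf("only %d distinct ELN levels after pooling; at least 5 needed to scan",
                 nrow(pool$map)), call. = FALSE)
  }
  g <- factor(pool$assignment, levels = pool$map$group)

  if (outcome == "stage_migration") {
    adjusters <- migration_adjusters
    df <- model_frame(cohort, c("n_stage", adjusters))
    df$node_positive <- as.integer(df$n_stage == "node_positive")
    df$eln_bin <- g
    fml <- as.formula(paste("node_positive ~",
                            paste(c("eln_bin", adjusters), collapse = " + ")))
    fit <- glm(fml, data = df, family = binomial())
  } else {
    adjusters <- survival_adjusters
    if (sum(cohort$event) < 1) stop("no events in survival subset", call. = FALSE)
    df <- model_frame(cohort, c("time", "event", adjusters))
    df$eln_bin <- g
    fml <- as.formula(paste("Surv(time, event) ~",
                            paste(c("eln_bin", adjusters), collapse = " + ")))
    fit <- coxph(fml, data = df, ties = "efron")
  }

  est <- coef(fit); se <- sqrt(diag(vcov(fit)))
  series <- data.frame(eln = pool$map$x, estimate = 0, se = 0, n = pool$map$n)
  for (gi in pool$map$group[-1]) {
    term <- paste0("eln_bin", gi)
    row <- which(pool$map$group == gi)
    series$estimate[row] <- unname(est[term])
    series$se[row] <- unname(se[term])
  }
  ref_level <- min(cohort$eln_count)
  structure(series,
            class = c("eln_effect_series", "data.frame"),
            outcome = outcome,
            subset = if (outcome == "survival") attr(cohort, "subset") else "all",
            adjusters = adjusters,
            reference_eln = ref_level,
            reference_is_one = ref_level == 1L,
            pooling_map = pool$map)
}

#' Test whether the ELN effect differs across histologic subgroups
#'
#' Adds the product of the histology grouping and the ELN count to the
#' adjusted stage-migration (logistic) or survival (Cox) model and performs
#' a joint Wald test of the product terms. The grouping may be the full
#' histology factor or a coarser partition, for example bronchoalveolar and
#' large-cell carcinoma pooled against the remaining types.
#'
#' @param cohort an `eln_cohort`.
#' @param outcome which model to embed the interaction in.
#' @param grouping `"histology"` for the full factor, or a named list of
#'   character vectors partitioning the histology categories.
#' @param subset survival subset (survival outcome only).
#' @return list with `statistic` (Wald chi-square), `df` and `p_value`.
#' @export
interaction_test <- function(cohort,
                             outcome = c("stage_migration", "survival"),
                             grouping = "histology",
                             subset = c("all", "node_negative", "node_positive")) {
  outcome <- match.arg(outcome)
  cohort <- as_cohort(cohort)
  if (outcome == "survival") cohort <- take_subset(cohort, subset)

  if (identical(grouping, "histology")) {
    grp <- droplevels(cohort$histology)
  } else {
    stopifnot(is.list(grouping), !is.null(names(grouping)))
    all_lv <- unlist(grouping)
    if (!setequal(all_lv, levels(droplevels(cohort$histology)))) {
      stop("grouping must partition the observed histology categories",
           call. = FALSE)
    }
    key <- rep(names(grouping), lengths(grouping))
    names(key) <- all_lv
    grp <- factor(key[as.character(cohort$histology)], levels = names(grouping))
  }
  tab <- table(grp)
  if (sum(tab > 0) < 2) {
    stop("interaction test needs at least two histology groups; only '",
         names(tab)[tab > 0][1], "' is present", call. = FALSE)
  }
  if (any(tab == 0)) grp <- droplevels(grp)

  if (outcome == "stage_migration") {
    adjusters <- setdiff(migration_adjusters, "histology")
    df <- model_frame(cohort, c("n_stage", "eln_count", adjusters))
    df$node_positive <- as.integer(df$n_stage == "node_positive")
    df$grp <- grp
    fml <- as.formula(paste("node_positive ~ eln_count * grp +",
                            paste(adjusters, collapse = " + ")))
    fit <- glm(fml, data = df, family = binomial())
  } else {
    adjusters <- setdiff(survival_adjusters, "histology")
    by_grp <- tapply(cohort$event, grp, sum)
    if (any(by_grp == 0)) {
      stop("histology group '", names(by_grp)[by_grp == 0][1],
           "' has no events", call. = FALSE)
    }
    df <- model_frame(cohort, c("time", "event", "eln_count", adjusters))
    df$grp <- grp
    fml <- as.formula(paste("Surv(time, event) ~ eln_count * grp +",
                            paste(adjusters, collapse = " + ")))
    fit <- coxph(fml, data = df, ties = "efron")
  }

  est <- coef(fit)
  prod_terms <- grep("^eln_count:grp", names(est), value = TRUE)
  prod_terms <- prod_terms[!is.na(est[prod_terms])]
  if (length(prod_terms) == 0) {
    stop("no estimable product terms (degenerate grouping)", call. = FALSE)
  }
  b <- est[prod_terms]
  V <- vcov(fit)[prod_terms, prod_terms, drop = FALSE]
  W <- drop(t(b) %*% solve(V, b))
  list(statistic = W, df = length(b),
       p_value = pchisq(W, df = length(b), lower.tail = FALSE))
}

#' Mean positive-node count per examined-node count
#'
#' Arithmetic mean of the observed positive-node count at each retained ELN
#' level, under the same sparsity pooling as [eln_effect_series]. This is
#' one of the series smoothed and scanned for a structural break.
#'
#' @param cohort an `eln_cohort`.
#' @param sparsity_floor minimum patients per retained level.
#' @return data frame with `eln`, `mean_positive`, `n`, plus the pooling map
#'   as an attribute.
#' @export
mean_positive_series <- function(cohort, sparsity_floor = 20) {
  cohort <- as_cohort(cohort)
  pool <- pool_eln_levels(cohort$eln_count, sparsity_floor)
  mp <- vapply(pool$map$group, function(gi) {
    mean(cohort$positive_count[pool$assignment == gi])
  }, numeric(1))
  structure(data.frame(eln = pool$map$x, mean_positive = mp, n = pool$map$n),
            pooling_map = pool$map)
}

#' Linear regression of positive-node count on examined-node count
#'
#' Ordinary least squares of the per-ELN-level mean positive-node count on
#' the ELN level, quantifying how strongly more examination uncovers more
#' positive nodes.
#'
#' @param cohort an `eln_cohort`.
#' @param subset `"all"` or `"node_positive"`.
#' @param sparsity_floor minimum patients per retained level.
#' @return list with `slope`, `r_squared` (NA with a note for a constant
#'   series), `n_levels` and the underlying `series`.
#' @export
positive_vs_examined_regression <- function(cohort,
                                            subset = c("all", "node_positive"),
                                            sparsity_floor = 20) {
  subset <- match.arg(subset)
  cohort <- as_cohort(cohort)
  if (subset == "node_positive") {
    cohort <- take_subset(cohort, "node_positive")
    if (nrow(cohort) == 0) stop("no node-positive patients", call. = FALSE)
  }
  ser <- mean_positive_series(cohort, sparsity_floor)
  if (nrow(ser) < 5) {
    stop("fewer than 5 distinct ELN levels; regression not meaningful",
         call. = FALSE)
  }
  if (stats::var(ser$mean_positive) == 0) {
    return(list(slope = 0, r_squared = NA_real_,
                note = "constant series: R^2 undefined",
                n_levels = nrow(ser), series = ser))
  }
  fit <- lm(mean_positive ~ eln, data = ser)
  rss <- sum(fit$residuals^2)
  tss <- sum((ser$mean_positive - mean(ser$mean_positive))^2)
  list(slope = unname(coef(fit)["eln"]),
       r_squared = 1 - rss / tss,
       n_levels = nrow(ser), series = ser)
}
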