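#' Adjusted hazard ratio for examination at or above an ELN threshold
#'
#' Dichotomizes the cohort at `eln_count >= threshold` and fits a Cox
#' proportional hazards model of the indicator adjusted for sex, age,
#' T stage, histology and operation type, by default on the declared
#' node-negative subset (where thorough examination both corrects the stage
#' and removes occult disease). A hazard ratio below 1 with its whole
#' confidence interval below 1 indicates reduced all-cause mortality for
#' patients with at least `threshold` nodes examined.
#'
#' @param cohort an `eln_cohort`.
#' @param threshold ELN count defining adequate examination (default 16).
#' @param subset `"node_negative"` (default), `"node_positive"` or `"all"`.
#' @param endpoint label carried into the result (e.g. `"overall_survival"`,
#'   `"disease_free_survival"`); the time/event columns are used either way.
#' @param adjusters covariates to adjust for.
#' @return a `cutpoint_validation`: threshold, `hr`, `ci` (95%), `p_value`,
#'   arm sizes and event counts, endpoint label, fitted model.
#' @export
dichotomize_and_fit <- function(cohort, threshold = 16,
                                subset = c("node_negative", "node_positive", "all"),
                                endpoint = "overall_survival",
                                adjusters = survival_adjusters) {
  subset <- match.arg(subset)
  cohort <- take_subset(as_cohort(cohort), subset)
  above <- cohort$eln_count >= threshold
  n_above <- sum(above); n_below <- sum(!above)
  if (n_above == 0 || n_below == 0) {
    stop(sprintf("threshold %d leaves an empty arm (%d above, %d below)",
                 threshold, n_above, n_below), call. = FALSE)
  }
  ev_above <- sum(cohort$event[above]); ev_below <- sum(cohort$event[!above])
  if (ev_above == 0 || ev_below == 0) {
    stop(sprintf("threshold %d leaves an arm with no events (%d above, %d below)",
                 threshold, ev_above, ev_below), call. = FALSE)
  }
  df <- model_frame(cohort, c("time", "event", adjusters))
  df$adequate <- as.integer(above)
  fml <- as.formula(paste("Surv(time, event) ~",
                          paste(c("adequate", adjusters), collapse = " + ")))
  fit <- coxph(fml, data = df, ties = "efron")
  b <- coef(fit)[["adequate"]]
  se <- sqrt(vcov(fit)["adequate", "adequate"])
  structure(list(
    threshold = as.integer(threshold),
    hr = exp(b),
    ci = exp(b + c(-1, 1) * qnorm(0.975) * se),
    p_value = 2 * stats::pnorm(-abs(b / se)),
    log_hr = b, se = se,
    n_above = n_above, n_below = n_below,
    events_above = ev_above, events_below = ev_below,
    subset = subset, endpoint = endpoint,
    adjusters = adjusters, fit = fit,
    provenance = cohort_provenance(cohort)
  ), class = "cutpoint_validation")
}

#' @export
print.cutpoint_validation <- function(x, ...) {
  cat(sprintf("ELN >= %d vs < %d (%s, %s subset)\n", x$threshold, x$threshold,
              x$endpoint, x$subset))
  cat(sprintf("  adjusted HR = %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
              x$hr, x$ci[1], x$ci[2], x$p_value))
  cat(sprintf("  arms: %d at/above (%d events), %d below (%d events)\n",
              x$n_above, x$events_above, x$n_below, x$events_below))
  invisible(x)
}

#' Covariate-adjusted survival curves for the two threshold arms
#'
#' Predicted survival from the dichotomized Cox model of
#' [dichotomize_and_fit], evaluated for each arm at a single reference
#' covariate profile (mean age, modal category of each factor) so the
#' curves differ only through the threshold indicator.
#'
#' @param cohort an `eln_cohort`.
#' @param threshold ELN threshold.
#' @param subset passed to [dichotomize_and_fit].
#' @param times optional time grid; defaults to the fitted model's event
#'   times.
#' @return data frame with columns `time`, `surv`, `arm`
#'   (`"below"`/`"above"`), plus the reference profile as an attribute.
#' @export
adjusted_survival_curves <- function(cohort, threshold = 16,
                                     subset = c("node_negative", "node_positive", "all"),
                                     times = NULL) {
  val <- dichotomize_and_fit(cohort, threshold, subset)
  fit <- val$fit
  mf <- stats::model.frame(fit)
  ref <- list(adequate = c(0L, 1L))
  for (nm in val$adjusters) {
    v <- mf[[nm]]
    ref[[nm]] <- if (is.numeric(v)) rep(mean(v), 2)
                 else rep(names(which.max(table(v))), 2)
  }
  newdata <- as.data.frame(ref, stringsAsFactors = FALSE)
  sf <- survfit(fit, newdata = newdata)
  tgrid <- if (is.null(times)) sf$time else times
  sm <- summary(sf, times = tgrid, extend = TRUE)
  surv <- sm$surv
  if (is.null(dim(surv))) surv <- matrix(surv, ncol = 2)
  out <- data.frame(
    time = rep(sm$time, 2),
    surv = c(surv[, 1], surv[, 2]),
    arm = rep(c("below", "above"), each = length(sm$time))
  )
  attr(out, "reference_profile") <- newdata[1, val$adjusters, drop = FALSE]
  attr(out, "threshold") <- threshold
  out
}

#' Validate an ELN threshold on an independent cohort
#'
#' Refits the dichotomized adjusted Cox model on a validation cohort. When
#' the two cohorts share provenance (same generator configuration hash or
#' file path) a warning flags that the validation may not be independent.
#'
#' @param validation_cohort an `eln_cohort` independent of the derivation
#'   cohort.
#' @param threshold ELN threshold to validate.
#' @param endpoint endpoint label (`"overall_survival"` or
#'   `"disease_free_survival"`); the cohort's time/event columns are taken
#'   to measure it.
#' @param derivation_cohort optional derivation cohort, used only for the
#'   provenance-independence check.
#' @param subset passed to [dichotomize_and_fit].
#' @return a `cutpoint_validation`.
#' @export
validate_on_cohort <- function(validation_cohort, threshold = 16,
                               endpoint = "overall_survival",
                               derivation_cohort = NULL,
                               subset = "node_negative") {
  if (!is.null(derivation_cohort)) {
    pv <- cohort_provenance(as_cohort(validation_cohort))
    pd <- cohort_provenance(as_cohort(derivation_cohort))
    same <- !is.null(pv$config_hash) && identical(pv$config_hash, pd$config_hash) ||
      !is.null(pv$path) && identical(pv$path, pd$path)
    if (isTRUE(same)) {
      warning("validation cohort shares provenance with the derivation cohort; validation may not be independent")
    }
  }
  dichotomize_and_fit(validation_cohort, threshold, subset = subset,
                      endpoint = endpoint)
}
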