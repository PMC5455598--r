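cohort_columns <- c("patient_id", "age", "sex", "histology", "t_stage",
                    "tumor_location", "operation_type", "eln_count",
                    "positive_count", "n_stage", "time", "event")
latent_columns <- c("latent_true_positive", "latent_m_total")

# polynomial rolling hash of the JSON rendering of a config; enough to tag
# provenance (not cryptographic)
config_hash <- function(cfg) {
  txt <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                          null = "null")
  h <- 0
  for (b in utf8ToInt(as.character(txt))) {
    h <- (h * 131 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

new_cohort <- function(df, provenance) {
  structure(df, class = c("eln_cohort", "data.frame"), provenance = provenance)
}

#' Cohort provenance metadata
#' @param cohort an `eln_cohort`.
#' @return list with at least `source` and either `config_hash` or `path`.
#' @export
cohort_provenance <- function(cohort) attr(cohort, "provenance")

#' @export
print.eln_cohort <- function(x, ...) {
  prov <- cohort_provenance(x)
  cat(sprintf("ELN cohort: %d patients (%s)\n", nrow(x),
              if (is.null(prov)) "unknown provenance" else prov$source))
  cat(sprintf("  ELN count: median %s [IQR %s-%s]; node-positive: %.1f%%; deaths: %d\n",
              median(x$eln_count), quantile(x$eln_count, 0.25),
              quantile(x$eln_count, 0.75),
              100 * mean(x$n_stage == "node_positive"), sum(x$event)))
  NextMethod()
}

rtruncnorm_3090 <- function(n, mean, sd) {
  lo <- stats::pnorm(30, mean, sd)
  hi <- stats::pnorm(90, mean, sd)
  stats::qnorm(runif(n, lo, hi), mean, sd)
}

# zero-truncated negative binomial via inverse CDF, then capped at m_total
r_eln <- function(n, mu, size, m_total) {
  p0 <- stats::pnbinom(0, mu = mu, size = size)
  x <- stats::qnbinom(runif(n, p0, 1), mu = mu, size = size)
  pmin(pmax(x, 1L), m_total)
}

draw_covariates <- function(n, cfg) {
  out <- list(age = round(rtruncnorm_3090(n, cfg$age_mean, cfg$age_sd), 1))
  for (nm in names(eln_categories)) {
    f <- cfg$covariate_freqs[[nm]]
    out[[nm]] <- factor(sample(names(f), n, replace = TRUE, prob = f),
                        levels = eln_categories[[nm]])
  }
  out
}

category_effect <- function(values, effects) {
  if (is.null(effects)) return(rep(0, length(values)))
  eff <- effects[as.character(values)]
  eff[is.na(eff)] <- 0
  as.numeric(eff)
}

survival_linear_predictor <- function(cov, eln, undetected, cfg) {
  lh <- cfg$covariate_log_hazards
  lp <- lh$age_per_year * (cov$age - 65) +
    category_effect(cov$sex, lh$sex) +
    category_effect(cov$histology, lh$histology) +
    category_effect(cov$t_stage, lh$t_stage) +
    category_effect(cov$operation_type, lh$operation_type) +
    cfg$eln_log_hazard * eln
  # occult penalty attenuated by dissection-template completeness: zero at
  # and above the template size, sliding to full strength at one node
  shortfall <- pmax(0, (cfg$hazard_break_eln - eln) / cfg$hazard_break_eln)
  lp + cfg$occult_log_hazard * undetected * shortfall^cfg$occult_shape
}

apply_censoring <- function(n, t_event, cfg) {
  cens <- if (cfg$censor_rate > 0) rexp(n, cfg$censor_rate) else rep(Inf, n)
  cens <- pmin(cens, cfg$max_followup)
  list(time = pmax(pmin(t_event, cens), 1e-6),
       event = as.integer(t_event <= cens))
}

#' Generate a synthetic registry cohort from the mechanistic nodal model
#'
#' Each patient receives a latent nodal population of `m_total` nodes, of
#' which a latent number are truly positive (Bernoulli chance of any
#' positivity from the covariate-dependent logistic model, then a
#' zero-truncated geometric count). Pathology examines `eln_count` nodes
#' drawn without replacement, so the observed positive count is a
#' hypergeometric sample of the latent truth and the declared N stage is
#' node-negative exactly when no positive node was found. Survival follows
#' an exponential proportional-hazards model whose linear predictor includes
#' the clinical covariates plus an occult-disease penalty of
#' `occult_log_hazard` per truly positive node left undetected (dropped once
#' `eln_count >= hazard_break_eln`, the mechanism that creates a survival
#' break at that threshold). Independent exponential censoring is capped by
#' administrative end of follow-up.
#'
#' @param config a [generator_config].
#' @return An `eln_cohort` data frame with the standard registry columns plus
#'   the latent truth columns `latent_true_positive` and `latent_m_total`.
#' @examples
#' cohort <- generate_cohort(generator_config(n_patients = 200, seed = 7))
#' table(cohort$n_stage)
#' @export
generate_cohort <- function(config) {
  validate_generator_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_patients

  cov <- draw_covariates(n, config)
  eln <- r_eln(n, config$eln_mu, config$eln_size, config$m_total)

  po <- config$positivity_logodds
  lo <- po$intercept +
    category_effect(cov$t_stage, po$t_stage) +
    category_effect(cov$histology, po$histology) +
    config$eln_logodds * eln
  any_pos <- rbinom(n, 1, stats::plogis(lo))
  true_pos <- any_pos * pmin(1L + rgeom(n, config$ztgeom_p), config$m_total)

  k <- rhyper(n, m = true_pos, n = config$m_total - true_pos, k = eln)
  undetected <- true_pos - k

  rate <- config$baseline_hazard *
    exp(survival_linear_predictor(cov, eln, undetected, config))
  fu <- apply_censoring(n, rexp(n, rate), config)

  df <- data.frame(
    patient_id = sprintf("P%06d", seq_len(n)),
    age = cov$age, sex = cov$sex, histology = cov$histology,
    t_stage = cov$t_stage, tumor_location = cov$tumor_location,
    operation_type = cov$operation_type,
    eln_count = as.integer(eln), positive_count = as.integer(k),
    n_stage = factor(ifelse(k > 0, "node_positive", "node_negative"),
                     levels = c("node_negative", "node_positive")),
    time = fu$time, event = fu$event,
    latent_true_positive = as.integer(true_pos),
    latent_m_total = as.integer(config$m_total),
    stringsAsFactors = FALSE
  )
  new_cohort(df, list(source = "simulated", config_hash = config_hash(config),
                      cohort_style = config$cohort_style,
                      seed = config$seed))
}

#' Generate a cohort with known direct ELN effects (calibration generator)
#'
#' Unlike [generate_cohort], where node status arises from hypergeometric
#' detection of a latent truth, this generator writes the ELN effects
#' directly into the observable model: declared node positivity is Bernoulli
#' with conditional log-odds `eln_logodds` per examined node given the
#' covariates, and the death rate carries a log hazard ratio `eln_log_hazard`
#' per examined node. The true coefficient of the correctly specified
#' logistic or Cox model is therefore known exactly, which is what coverage
#' and null-calibration studies need. Setting both effects to 0 gives the
#' null generator (node status and survival independent of ELN given
#' covariates).
#'
#' @param n_patients cohort size.
#' @param eln_logodds true conditional log-odds of node positivity per
#'   examined node.
#' @param eln_log_hazard true conditional log hazard ratio per examined node.
#' @param config a [generator_config] supplying the covariate distributions,
#'   ELN distribution, baseline hazard and censoring; its mechanistic fields
#'   (latent model, occult penalty) are ignored.
#' @param seed RNG seed; `NULL` leaves the RNG state alone.
#' @return an `eln_cohort` without latent columns.
#' @export
simulate_glm_cohort <- function(n_patients,
                                eln_logodds = 0,
                                eln_log_hazard = 0,
                                config = generator_config(n_patients = n_patients),
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- n_patients
  cov <- draw_covariates(n, config)
  eln <- r_eln(n, config$eln_mu, config$eln_size, config$m_total)

  po <- config$positivity_logodds
  lo <- po$intercept +
    category_effect(cov$t_stage, po$t_stage) +
    category_effect(cov$histology, po$histology) +
    eln_logodds * eln
  node_pos <- rbinom(n, 1, stats::plogis(lo))
  k <- node_pos * pmin(1L + rgeom(n, config$ztgeom_p), eln)

  cfg2 <- config
  cfg2$eln_log_hazard <- eln_log_hazard
  cfg2$occult_log_hazard <- 0
  rate <- config$baseline_hazard *
    exp(survival_linear_predictor(cov, eln, rep(0, n), cfg2))
  fu <- apply_censoring(n, rexp(n, rate), config)

  df <- data.frame(
    patient_id = sprintf("P%06d", seq_len(n)),
    age = cov$age, sex = cov$sex, histology = cov$histology,
    t_stage = cov$t_stage, tumor_location = cov$tumor_location,
    operation_type = cov$operation_type,
    eln_count = as.integer(eln), positive_count = as.integer(k),
    n_stage = factor(ifelse(k > 0, "node_positive", "node_negative"),
                     levels = c("node_negative", "node_positive")),
    time = fu$time, event = fu$event,
    stringsAsFactors = FALSE
  )
  new_cohort(df, list(source = "simulated_glm",
                      eln_logodds = eln_logodds,
                      eln_log_hazard = eln_log_hazard,
                      seed = seed))
}
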