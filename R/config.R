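#' Covariate categories used throughout the package
#'
#' Fixed category sets for the clinical covariates a resected-NSCLC registry
#' carries. The first element of each is the generator's reference level.
#'
#' @format A named list of character vectors.
#' @export
eln_categories <- list(
  sex            = c("male", "female"),
  histology      = c("adenocarcinoma", "squamous", "bronchoalveolar",
                     "large_cell", "other"),
  t_stage        = c("T1", "T2", "T3", "T4"),
  tumor_location = c("upper_lobe", "middle_lobe", "lower_lobe", "main_bronchus"),
  operation_type = c("lobectomy", "sublobar", "pneumonectomy")
)

#' Cohort-style presets for the ELN-count distribution
#'
#' Negative-binomial (mean, dispersion) pairs calibrated so that the
#' zero-truncated draw reproduces the two registry shapes the package
#' emulates: a low-yield style (median 7 ELNs, interquartile range about
#' 4 to 13) and a high-yield style (median 15, interquartile range 10 to 22).
#'
#' @param style `"SEER"` (low yield) or `"China"` (high yield).
#' @return list with `eln_mu` and `eln_size`.
#' @export
cohort_style_preset <- function(style = c("SEER", "China")) {
  style <- match.arg(style)
  switch(style,
    SEER  = list(eln_mu = 8.8,  eln_size = 1.35),
    China = list(eln_mu = 16.9, eln_size = 3.4)
  )
}

default_covariate_freqs <- function() {
  list(
    sex            = c(male = 0.55, female = 0.45),
    histology      = c(adenocarcinoma = 0.50, squamous = 0.30,
                       bronchoalveolar = 0.05, large_cell = 0.05, other = 0.10),
    t_stage        = c(T1 = 0.30, T2 = 0.45, T3 = 0.15, T4 = 0.10),
    tumor_location = c(upper_lobe = 0.55, middle_lobe = 0.07,
                       lower_lobe = 0.33, main_bronchus = 0.05),
    operation_type = c(lobectomy = 0.75, sublobar = 0.15, pneumonectomy = 0.10)
  )
}

default_positivity_logodds <- function() {
  # log-odds contributions to P(>= 1 truly positive node); intercept gives
  # roughly 35% latent node-positive prevalence at the reference profile
  list(
    intercept = -1.1,
    t_stage   = c(T1 = 0, T2 = 0.5, T3 = 1.0, T4 = 1.3),
    histology = c(adenocarcinoma = 0, squamous = 0.1, bronchoalveolar = -0.8,
                  large_cell = 0.2, other = 0)
  )
}

default_covariate_log_hazards <- function() {
  list(
    age_per_year   = 0.03,     # centered at 65 years
    sex            = c(male = 0, female = -0.25),
    histology      = c(adenocarcinoma = 0, squamous = 0.10,
                       bronchoalveolar = -0.40, large_cell = 0.25, other = 0.10),
    t_stage        = c(T1 = 0, T2 = 0.35, T3 = 0.70, T4 = 1.00),
    operation_type = c(lobectomy = 0, sublobar = 0.20, pneumonectomy = 0.30)
  )
}

#' Configuration for the synthetic registry generator
#'
#' Bundles and validates every knob of the mechanistic cohort generator.
#' Defaults describe a low-yield registry: zero-truncated negative-binomial
#' ELN counts with median 7, a latent nodal population of 40 nodes per
#' patient, roughly 35% latent node-positive prevalence with a zero-truncated
#' geometric positive-node count, exponential baseline survival under
#' proportional hazards, and an occult-disease mortality penalty per
#' undetected positive node that is attenuated by the completeness of the
#' nodal dissection and vanishes once at least `hazard_break_eln` nodes were
#' examined (a complete dissection template is assumed to clear residual
#' occult disease), which is what induces a survival break at that ELN
#' count.
#'
#' @param n_patients number of patients to simulate.
#' @param cohort_style `"SEER"` or `"China"`; sets `eln_mu`/`eln_size` unless
#'   both are supplied explicitly.
#' @param eln_mu,eln_size negative-binomial mean and dispersion of the ELN
#'   count before zero truncation and capping at `m_total`.
#' @param m_total latent nodal population size per patient (every drawn ELN
#'   count is capped at this).
#' @param positivity_logodds list with `intercept` and optional per-category
#'   log-odds vectors (named by covariate) for harboring at least one truly
#'   positive node.
#' @param eln_logodds additional log-odds of latent node positivity per
#'   examined node (0 in the mechanistic model; nonzero values let the
#'   generator realize a known logistic ELN effect for calibration studies).
#' @param ztgeom_p success parameter of the zero-truncated geometric
#'   distribution of the positive-node count given at least one.
#' @param covariate_freqs named list of category frequency vectors; see
#'   [eln_categories].
#' @param age_mean,age_sd mean and SD of age, truncated to \[30, 90\] years.
#' @param baseline_hazard exponential death rate per year at the reference
#'   covariate profile.
#' @param covariate_log_hazards list of log hazard ratios (`age_per_year`
#'   plus per-category vectors).
#' @param occult_log_hazard extra log hazard per undetected truly positive
#'   node, at maximal attenuation shortfall (one examined node).
#' @param hazard_break_eln size of the complete dissection template: the ELN
#'   count at and above which residual occult disease is taken as cleared, so
#'   the occult penalty vanishes. Below it the per-node penalty is scaled by
#'   `((hazard_break_eln - eln)/hazard_break_eln)^occult_shape`. This is the
#'   mechanism that places a survival break at the configured count. `Inf`
#'   disables the break (full-strength penalty at any yield).
#' @param occult_shape shape exponent of the attenuation factor; the default
#'   0.3 makes the induced adjusted log-hazard series decline approximately
#'   linearly in the ELN count below the template size and stay flat above
#'   it (the kinked shape the break-scan procedure targets).
#' @param eln_log_hazard direct log hazard ratio per examined node (0 in the
#'   mechanistic model; for calibration studies).
#' @param censor_rate administrative censoring rate per year.
#' @param max_followup administrative end of follow-up, years.
#' @param seed integer RNG seed; `NULL` leaves the RNG state alone.
#' @return An object of class `generator_config` (a validated list).
#' @examples
#' cfg <- generator_config(n_patients = 500, seed = 1)
#' cohort <- generate_cohort(cfg)
#' @export
generator_config <- function(n_patients = 10000,
                             cohort_style = c("SEER", "China"),
                             eln_mu = NULL, eln_size = NULL,
                             m_total = 40,
                             positivity_logodds = default_positivity_logodds(),
                             eln_logodds = 0,
                             ztgeom_p = 0.45,
                             covariate_freqs = default_covariate_freqs(),
                             age_mean = 65, age_sd = 10,
                             baseline_hazard = 0.08,
                             covariate_log_hazards = default_covariate_log_hazards(),
                             occult_log_hazard = 0.3,
                             hazard_break_eln = 16,
                             occult_shape = 0.3,
                             eln_log_hazard = 0,
                             censor_rate = 0.08,
                             max_followup = 8,
                             seed = NULL) {
  cohort_style <- match.arg(cohort_style)
  preset <- cohort_style_preset(cohort_style)
  if (is.null(eln_mu)) eln_mu <- preset$eln_mu
  if (is.null(eln_size)) eln_size <- preset$eln_size

  cfg <- structure(list(
    n_patients = n_patients, cohort_style = cohort_style,
    eln_mu = eln_mu, eln_size = eln_size, m_total = m_total,
    positivity_logodds = positivity_logodds, eln_logodds = eln_logodds,
    ztgeom_p = ztgeom_p, covariate_freqs = covariate_freqs,
    age_mean = age_mean, age_sd = age_sd,
    baseline_hazard = baseline_hazard,
    covariate_log_hazards = covariate_log_hazards,
    occult_log_hazard = occult_log_hazard,
    hazard_break_eln = hazard_break_eln,
    occult_shape = occult_shape,
    eln_log_hazard = eln_log_hazard,
    censor_rate = censor_rate, max_followup = max_followup,
    seed = seed
  ), class = "generator_config")
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  chk <- function(ok, field, why) {
    if (!ok) stop(sprintf("invalid generator_config: field '%s' %s", field, why),
                  call. = FALSE)
  }
  chk(is.numeric(cfg$n_patients) && length(cfg$n_patients) == 1 &&
        cfg$n_patients >= 1 && cfg$n_patients == floor(cfg$n_patients),
      "n_patients", "must be a positive integer")
  chk(is.numeric(cfg$eln_mu) && cfg$eln_mu > 0, "eln_mu", "must be > 0")
  chk(is.numeric(cfg$eln_size) && cfg$eln_size > 0, "eln_size", "must be > 0")
  chk(is.numeric(cfg$m_total) && cfg$m_total >= 1 &&
        cfg$m_total == floor(cfg$m_total),
      "m_total", "must be a positive integer")
  chk(is.numeric(cfg$ztgeom_p) && cfg$ztgeom_p > 0 && cfg$ztgeom_p <= 1,
      "ztgeom_p", "must be in (0, 1]")
  chk(is.numeric(cfg$baseline_hazard) && cfg$baseline_hazard > 0,
      "baseline_hazard", "must be > 0")
  chk(is.numeric(cfg$censor_rate) && cfg$censor_rate >= 0,
      "censor_rate", "must be >= 0")
  chk(is.numeric(cfg$max_followup) && cfg$max_followup > 0,
      "max_followup", "must be > 0")
  chk(is.numeric(cfg$hazard_break_eln) && cfg$hazard_break_eln >= 1,
      "hazard_break_eln", "must be >= 1 (use Inf to disable)")
  chk(is.numeric(cfg$occult_shape) && cfg$occult_shape > 0,
      "occult_shape", "must be > 0")
  chk(is.list(cfg$covariate_freqs), "covariate_freqs", "must be a list")
  for (nm in names(eln_categories)) {
    f <- cfg$covariate_freqs[[nm]]
    chk(!is.null(f), "covariate_freqs", paste("is missing", nm))
    chk(all(f >= 0) && abs(sum(f) - 1) < 1e-8,
        paste0("covariate_freqs$", nm), "must be non-negative and sum to 1")
    chk(all(names(f) %in% eln_categories[[nm]]),
        paste0("covariate_freqs$", nm),
        paste("has unknown categories; allowed:",
              paste(eln_categories[[nm]], collapse = ", ")))
  }
  chk(is.numeric(cfg$positivity_logodds$intercept),
      "positivity_logodds", "must contain a numeric intercept")
  invisible(cfg)
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic registry generator configuration\n")
  cat(sprintf("  patients: %d (%s-style ELN distribution: NB mu=%.1f, size=%.2f, capped at M=%d)\n",
              x$n_patients, x$cohort_style, x$eln_mu, x$eln_size, x$m_total))
  cat(sprintf("  positivity: intercept %.2f (log-odds), positive count ~ zt-geometric(p=%.2f)\n",
              x$positivity_logodds$intercept, x$ztgeom_p))
  cat(sprintf("  survival: exponential baseline %.3f/yr, occult penalty %.2f/node below ELN %s\n",
              x$baseline_hazard, x$occult_log_hazard,
              format(x$hazard_break_eln)))
  cat(sprintf("  censoring: %.3f/yr, administrative cap %.1f yr; seed: %s\n",
              x$censor_rate, x$max_followup,
              if (is.null(x$seed)) "none" else format(x$seed)))
  invisible(x)
}
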