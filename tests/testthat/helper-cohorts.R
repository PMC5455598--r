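# Small hand-built cohort with known values, used across files.
toy_cohort <- function() {
  as_cohort(data.frame(
    patient_id = sprintf("T%02d", 1:10),
    age = c(60, 65, 70, 55, 62, 68, 71, 59, 64, 66),
    sex = rep(c("male", "female"), 5),
    histology = rep(c("adenocarcinoma", "squamous"), 5),
    t_stage = rep(c("T1", "T2"), 5),
    tumor_location = rep("upper_lobe", 10),
    operation_type = rep("lobectomy", 10),
    eln_count = c(2, 2, 2, 5, 5, 5, 10, 10, 10, 10),
    positive_count = c(0, 1, 0, 0, 2, 1, 0, 0, 3, 1),
    n_stage = c("node_negative", "node_positive", "node_negative",
                "node_negative", "node_positive", "node_positive",
                "node_negative", "node_negative", "node_positive",
                "node_positive"),
    time = c(5, 2, 6, 4, 1.5, 3, 7, 6.5, 1, 2.5),
    event = c(0, 1, 0, 1, 1, 0, 0, 0, 1, 1),
    stringsAsFactors = FALSE
  ))
}

# Generator config with every covariate and occult effect switched off:
# constant hazard, no ELN-survival link, positivity independent of ELN.
flat_config <- function(n, seed, ...) {
  zero_lh <- list(
    age_per_year = 0,
    sex = c(male = 0, female = 0),
    histology = c(adenocarcinoma = 0, squamous = 0, bronchoalveolar = 0,
                  large_cell = 0, other = 0),
    t_stage = c(T1 = 0, T2 = 0, T3 = 0, T4 = 0),
    operation_type = c(lobectomy = 0, sublobar = 0, pneumonectomy = 0)
  )
  generator_config(
    n_patients = n,
    positivity_logodds = list(intercept = -0.6),
    covariate_log_hazards = zero_lh,
    occult_log_hazard = 0,
    seed = seed, ...)
}
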