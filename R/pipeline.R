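log_msg <- function(level, verbosity, ...) {
  levels <- c(debug = 1, info = 2, warn = 3)
  if (levels[[level]] >= levels[[verbosity]]) {
    message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"),
                    toupper(level), paste0(...)))
  }
}

#' Configuration for the full ELN cut-point pipeline
#'
#' Exactly one input mode is active: `"simulate"` draws a derivation cohort
#' (and, unless disabled, an independent validation cohort) from the
#' mechanistic generator; `"file"` reads cohorts written by [write_cohort].
#'
#' @param mode `"simulate"` or `"file"`.
#' @param generator a [generator_config] (simulate mode). Its seed is
#'   superseded by `seed`.
#' @param derivation_path,validation_path cohort CSV paths (file mode;
#'   `validation_path` optional).
#' @param validation_n validation-cohort size in simulate mode (0 skips
#'   validation).
#' @param m_total nodal population size for the occult-probability model;
#'   defaults to the generator's value in simulate mode and must be given
#'   in file mode.
#' @param sparsity_floor minimum patients per ELN level in the effect
#'   series.
#' @param bandwidth LOWESS bandwidth.
#' @param candidate_range optional length-2 numeric restricting Chow-scan
#'   candidates.
#' @param threshold_override use this threshold instead of the scanned
#'   survival break (NULL scans).
#' @param out_dir directory for persisted artifacts (created if absent).
#' @param seed integer seed driving every random draw of the run.
#' @param log_level `"debug"`, `"info"` or `"warn"`.
#' @return a validated `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("simulate", "file"),
                            generator = generator_config(),
                            derivation_path = NULL, validation_path = NULL,
                            validation_n = 10000,
                            m_total = NULL,
                            sparsity_floor = 20,
                            bandwidth = 2/3,
                            candidate_range = NULL,
                            threshold_override = NULL,
                            out_dir = tempfile("elncut_run_"),
                            seed = 1,
                            log_level = c("info", "debug", "warn")) {
  mode <- match.arg(mode)
  log_level <- match.arg(log_level)
  if (mode == "file") {
    if (is.null(derivation_path)) {
      stop("file mode requires derivation_path", call. = FALSE)
    }
    if (is.null(m_total)) {
      stop("file mode requires m_total (latent nodal population size)",
           call. = FALSE)
    }
  } else {
    validate_generator_config(generator)
    if (is.null(m_total)) m_total <- generator$m_total
  }
  if (bandwidth <= 0 || bandwidth > 1) {
    stop("bandwidth must be in (0, 1]", call. = FALSE)
  }
  structure(list(mode = mode, generator = generator,
                 derivation_path = derivation_path,
                 validation_path = validation_path,
                 validation_n = validation_n, m_total = m_total,
                 sparsity_floor = sparsity_floor, bandwidth = bandwidth,
                 candidate_range = candidate_range,
                 threshold_override = threshold_override,
                 out_dir = out_dir, seed = seed, log_level = log_level),
            class = "pipeline_config")
}

#' Summary statistics of a cohort
#'
#' The descriptive block every report leads with: cohort size, deaths,
#' censoring fraction, median follow-up, ELN median and interquartile
#' range, and declared N-stage proportions.
#'
#' @param cohort an `eln_cohort`.
#' @return a named list.
#' @export
summarize_cohort <- function(cohort) {
  cohort <- as_cohort(cohort)
  iqr <- quantile(cohort$eln_count, c(0.25, 0.75), type = 1)
  list(
    n = nrow(cohort),
    deaths = sum(cohort$event),
    censored_fraction = mean(cohort$event == 0),
    median_followup = median(cohort$time),
    eln_median = as.numeric(median(cohort$eln_count)),
    eln_iqr = as.numeric(iqr),
    node_negative_fraction = mean(cohort$n_stage == "node_negative"),
    node_positive_fraction = mean(cohort$n_stage == "node_positive")
  )
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

run_stage <- function(name, verbosity, expr) {
  log_msg("info", verbosity, "stage: ", name)
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full ELN cut-point analysis
#'
#' Executes the stages in order — cohort acquisition, descriptive
#' summaries, continuous adjusted models, the occult-probability table, the
#' per-ELN effect series, LOWESS smoothing, Chow structural-break scans,
#' cut-point selection, and dichotomized validation on the derivation and
#' validation cohorts — persisting every intermediate artifact as a flat
#' TSV/CSV/JSON file under `config$out_dir` and writing a machine-readable
#' `report.json`. Given a fixed seed the run is fully reproducible.
#'
#' @param config a [pipeline_config].
#' @return the report, invisibly, as an `eln_report` list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  v <- config$log_level
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  cohorts <- run_stage("cohorts", v, {
    if (config$mode == "simulate") {
      gen <- config$generator
      gen$seed <- config$seed
      der <- generate_cohort(gen)
      val <- NULL
      if (config$validation_n > 0) {
        gv <- gen
        gv$n_patients <- config$validation_n
        gv$seed <- config$seed + 1000003L
        val <- generate_cohort(gv)
      }
      list(derivation = der, validation = val)
    } else {
      der <- read_cohort(config$derivation_path)
      val <- if (!is.null(config$validation_path)) {
        read_cohort(config$validation_path)
      }
      list(derivation = der, validation = val)
    }
  })
  der <- cohorts$derivation
  write_cohort(der, file.path(config$out_dir, "derivation_cohort.csv"))
  if (!is.null(cohorts$validation)) {
    write_cohort(cohorts$validation,
                 file.path(config$out_dir, "validation_cohort.csv"))
  }

  summaries <- run_stage("summaries", v, {
    s <- list(derivation = summarize_cohort(der))
    if (!is.null(cohorts$validation)) {
      s$validation <- summarize_cohort(cohorts$validation)
    }
    s
  })

  models <- run_stage("continuous_models", v, {
    mig <- fit_stage_migration(der)
    os_n0 <- fit_survival_model(der, subset = "node_negative")
    os_np <- fit_survival_model(der, subset = "node_positive")
    os_np_adj <- fit_survival_model(der, subset = "node_positive",
                                    include_positive_count = TRUE)
    list(stage_migration = eln_effect(mig),
         survival_node_negative = eln_effect(os_n0),
         survival_node_positive = eln_effect(os_np),
         survival_node_positive_adj_pos_count = eln_effect(os_np_adj))
  })

  pos_reg <- run_stage("positive_vs_examined", v, {
    all <- positive_vs_examined_regression(der, "all", config$sparsity_floor)
    npos <- tryCatch(
      positive_vs_examined_regression(der, "node_positive", config$sparsity_floor),
      error = function(e) NULL)
    list(all = list(slope = all$slope, r_squared = all$r_squared),
         node_positive = if (!is.null(npos)) {
           list(slope = npos$slope, r_squared = npos$r_squared)
         })
  })

  occult <- run_stage("occult_table", v, {
    prior <- estimate_prior(der)
    tab <- occult_table(prior, config$m_total)
    write_tsv(tab, file.path(config$out_dir, "occult_table.tsv"))
    list(prior = prior, table = tab)
  })

  series <- run_stage("effect_series", v, {
    sv <- eln_effect_series(der, "survival", "node_negative",
                            config$sparsity_floor)
    mg <- eln_effect_series(der, "stage_migration",
                            sparsity_floor = config$sparsity_floor)
    mp <- mean_positive_series(der, config$sparsity_floor)
    oc <- occult$table[!is.na(occult$table$p_occult_given_k0),
                       c("n", "p_occult_given_k0")]
    write_tsv(as.data.frame(sv), file.path(config$out_dir, "series_survival.tsv"))
    write_tsv(as.data.frame(mg), file.path(config$out_dir, "series_migration.tsv"))
    write_tsv(mp, file.path(config$out_dir, "series_mean_positive.tsv"))
    inv_var <- function(se) 1 / pmax(se, min(se[se > 0]))^2
    list(survival = list(x = sv$eln, y = sv$estimate, w = inv_var(sv$se)),
         migration = list(x = mg$eln, y = mg$estimate, w = inv_var(mg$se)),
         mean_positive = list(x = mp$eln, y = mp$mean_positive, w = NULL),
         occult = list(x = oc$n, y = oc$p_occult_given_k0, w = NULL))
  })

  breaks <- run_stage("breakpoints", v, {
    out <- list()
    for (nm in names(series)) {
      sm <- lowess_fit(series[[nm]]$x, series[[nm]]$y,
                       bandwidth = config$bandwidth,
                       weights = series[[nm]]$w)
      w_ord <- series[[nm]]$w[order(series[[nm]]$x)]
      sc <- chow_scan(sm, candidate_range = config$candidate_range,
                      weights = w_ord)
      sc_raw <- chow_scan(sm, candidate_range = config$candidate_range,
                          on = "raw", weights = w_ord)
      write_tsv(sc$scan,
                file.path(config$out_dir, sprintf("chow_scan_%s.tsv", nm)))
      out[[nm]] <- list(smoothed = sc, raw = sc_raw)
    }
    out
  })

  selection <- run_stage("cutpoint_selection", v, {
    select_cutpoint(lapply(breaks, `[[`, "smoothed"))
  })
  threshold <- if (!is.null(config$threshold_override)) {
    as.integer(config$threshold_override)
  } else {
    selection$cutpoint
  }

  validation <- run_stage("threshold_validation", v, {
    derv <- dichotomize_and_fit(der, threshold, subset = "node_negative")
    curves <- adjusted_survival_curves(der, threshold, subset = "node_negative")
    write_tsv(curves, file.path(config$out_dir, "adjusted_curves.tsv"))
    valv <- if (!is.null(cohorts$validation)) {
      validate_on_cohort(cohorts$validation, threshold,
                         derivation_cohort = der)
    }
    list(derivation = derv, validation = valv)
  })

  strip_fit <- function(cv) {
    if (is.null(cv)) return(NULL)
    cv[c("threshold", "hr", "ci", "p_value", "n_above", "n_below",
         "events_above", "events_below", "subset", "endpoint")]
  }
  report <- structure(list(
    software = list(package = "elncut",
                    version = as.character(utils::packageVersion("elncut"))),
    config = list(
      mode = config$mode, seed = config$seed, m_total = config$m_total,
      sparsity_floor = config$sparsity_floor, bandwidth = config$bandwidth,
      threshold_override = config$threshold_override,
      generator = if (config$mode == "simulate") unclass(config$generator)
    ),
    cohorts = summaries,
    continuous_models = lapply(models, function(m) {
      list(effect = m$effect, ci = c(m$effect_ci_lower, m$effect_ci_upper),
           p_value = m$p_value, outcome = m$outcome)
    }),
    positive_vs_examined = pos_reg,
    breakpoints = lapply(breaks, function(b) {
      list(smoothed = b$smoothed$selected_break,
           raw = b$raw$selected_break,
           f = b$smoothed$f_at_break, p = b$smoothed$p_at_break)
    }),
    cutpoint = list(selected = selection$cutpoint,
                    threshold_used = threshold,
                    breaks = as.list(selection$breaks),
                    spread = selection$spread,
                    concordant = selection$concordant),
    validation = lapply(validation, strip_fit),
    artifacts = list(
      out_dir = config$out_dir,
      files = sort(setdiff(list.files(config$out_dir), "report.json"))
    )
  ), class = "eln_report")

  jsonlite::write_json(unclass(report), file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  log_msg("info", v, "done: report at ",
          file.path(config$out_dir, "report.json"))
  invisible(report)
}

#' @export
print.eln_report <- function(x, ...) {
  cat("ELN cut-point analysis report\n")
  s <- x$cohorts$derivation
  cat(sprintf("  derivation cohort: n=%d, deaths=%d, ELN median %g [IQR %g-%g]\n",
              s$n, s$deaths, s$eln_median, s$eln_iqr[1], s$eln_iqr[2]))
  m <- x$continuous_models
  cat(sprintf("  per-ELN OR (stage migration) = %.3f; HR (N0 survival) = %.3f\n",
              m$stage_migration$effect, m$survival_node_negative$effect))
  cat(sprintf("  selected cut point: %d (series breaks: %s)\n",
              x$cutpoint$selected,
              paste(sprintf("%s=%.3g", names(x$cutpoint$breaks),
                            unlist(x$cutpoint$breaks)), collapse = ", ")))
  dv <- x$validation$derivation
  cat(sprintf("  dichotomized HR at %d (derivation): %.3f (95%% CI %.3f-%.3f)\n",
              dv$threshold, dv$hr, dv$ci[1], dv$ci[2]))
  if (!is.null(x$validation$validation)) {
    vv <- x$validation$validation
    cat(sprintf("  dichotomized HR at %d (validation): %.3f (95%% CI %.3f-%.3f)\n",
                vv$threshold, vv$hr, vv$ci[1], vv$ci[2]))
  }
  invisible(x)
}

#' Check a pipeline report against the shipped schema
#'
#' A structural check of `report.json` against the JSON schema at
#' `system.file("extdata", "report-schema.json", package = "elncut")`:
#' required top-level blocks present, numeric fields numeric, cut point an
#' integer.
#'
#' @param report an `eln_report` or a path to a `report.json`.
#' @return `TRUE` invisibly; stops with the first violation otherwise.
#' @export
validate_report <- function(report) {
  if (is.character(report)) report <- jsonlite::read_json(report)
  schema <- jsonlite::read_json(system.file("extdata", "report-schema.json",
                                            package = "elncut"))
  need <- names(schema$properties)
  miss <- setdiff(need, names(report))
  if (length(miss) > 0) {
    stop("report is missing block(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  sel <- report$cutpoint$selected
  if (!is.numeric(sel) || sel != round(sel)) {
    stop("cutpoint$selected must be an integer", call. = FALSE)
  }
  for (m in report$continuous_models) {
    if (!is.numeric(m$effect)) stop("model effect must be numeric", call. = FALSE)
  }
  invisible(TRUE)
}
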