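#' Coerce and validate a patient table as an ELN cohort
#'
#' Checks column completeness and the structural invariants every analysis
#' in the package relies on: ELN count a positive integer, positive count
#' within `[0, eln_count]`, declared N stage consistent with the positive
#' count, positive follow-up time, a 0/1 event indicator, and covariate
#' categories drawn from [eln_categories]. Violations are reported with the
#' offending row numbers.
#'
#' @param df a data frame with the standard registry columns.
#' @param provenance optional provenance list (kept if `df` already carries
#'   one).
#' @return an `eln_cohort`.
#' @export
as_cohort <- function(df, provenance = NULL) {
  missing_cols <- setdiff(cohort_columns, names(df))
  if (length(missing_cols) > 0) {
    stop("cohort is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0) stop("cohort is empty", call. = FALSE)

  bad_rows <- function(cond, what) {
    rows <- which(cond)
    if (length(rows) > 0) {
      stop(sprintf("invalid cohort: %s on row(s) %s", what,
                   paste(head(rows, 10), collapse = ", ")), call. = FALSE)
    }
  }
  num_ok <- function(x) is.numeric(x) & !is.na(x)

  eln <- suppressWarnings(as.numeric(df$eln_count))
  bad_rows(is.na(eln) | eln < 1 | eln != floor(eln),
           "eln_count must be an integer >= 1")
  pos <- suppressWarnings(as.numeric(df$positive_count))
  bad_rows(is.na(pos) | pos < 0 | pos != floor(pos),
           "positive_count must be a non-negative integer")
  bad_rows(pos > eln, "positive_count > eln_count")
  tm <- suppressWarnings(as.numeric(df$time))
  bad_rows(!num_ok(tm) | tm <= 0, "time must be > 0")
  bad_rows(!(df$event %in% c(0, 1)), "event must be 0 or 1")
  age <- suppressWarnings(as.numeric(df$age))
  bad_rows(!num_ok(age), "age must be numeric and non-missing")

  n_stage <- as.character(df$n_stage)
  bad_rows(!(n_stage %in% c("node_negative", "node_positive")),
           "n_stage must be 'node_negative' or 'node_positive'")
  bad_rows(n_stage == "node_negative" & pos > 0,
           "declared node_negative but positive_count > 0")
  bad_rows(n_stage == "node_positive" & pos == 0,
           "declared node_positive but positive_count == 0")

  for (nm in names(eln_categories)) {
    vals <- as.character(df[[nm]])
    unknown <- !(vals %in% eln_categories[[nm]])
    if (any(unknown)) {
      stop(sprintf(
        "invalid cohort: unknown %s '%s' on row(s) %s; allowed categories: %s",
        nm, vals[which(unknown)[1]],
        paste(head(which(unknown), 10), collapse = ", "),
        paste(eln_categories[[nm]], collapse = ", ")), call. = FALSE)
    }
    df[[nm]] <- factor(vals, levels = eln_categories[[nm]])
  }

  if ("latent_true_positive" %in% names(df) &&
      !all(is.na(df$latent_true_positive))) {
    bad_rows(pos > df$latent_true_positive,
             "positive_count exceeds latent_true_positive")
  }

  df$eln_count <- as.integer(eln)
  df$positive_count <- as.integer(pos)
  df$n_stage <- factor(n_stage, levels = c("node_negative", "node_positive"))
  df$event <- as.integer(df$event)
  df$time <- tm
  df$age <- age

  if (is.null(provenance)) provenance <- attr(df, "provenance")
  if (is.null(provenance)) provenance <- list(source = "unknown")
  new_cohort(as.data.frame(df), provenance)
}

#' Write a cohort to a comma-delimited file
#'
#' UTF-8 CSV with a fixed header (`patient_id, age, sex, histology, t_stage,
#' tumor_location, operation_type, eln_count, positive_count, n_stage, time,
#' event`). Latent truth columns are withheld unless requested, so a written
#' file looks exactly like a registry extract.
#'
#' @param cohort an `eln_cohort`.
#' @param path output path.
#' @param include_latent also write `latent_true_positive` and
#'   `latent_m_total` when present.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, include_latent = FALSE) {
  cols <- cohort_columns
  if (include_latent) cols <- c(cols, intersect(latent_columns, names(cohort)))
  df <- as.data.frame(cohort)[, cols]
  write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a cohort from a comma-delimited file
#'
#' Reads a CSV written by [write_cohort] (or any registry extract with the
#' same header) and validates it with [as_cohort]; malformed files are
#' rejected with the offending column or row.
#'
#' @param path CSV path.
#' @return an `eln_cohort` whose provenance records the source path.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  as_cohort(df, provenance = list(source = "file", path = path))
}
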