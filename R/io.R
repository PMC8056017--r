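# Cohort tables travel as three CSVs: patients, assessments, samples.

required_columns <- list(
  patients = c("patient_id", "age_at_sampling", "gender", "phenotype", "ftd",
               "umn_regions", "lmn_regions", "survival_months", "event"),
  assessments = c("patient_id", "t_months", "alsfrs_r"),
  samples = c("patient_id", "group", "nfl_pg_ml", "laboratory")
)

read_table_checked <- function(path, what) {
  if (!file.exists(path))
    stop_d50("d50als_schema_error", sprintf("File not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required_columns[[what]], names(df))
  if (length(missing))
    stop_d50("d50als_missing_column",
             sprintf("%s: missing column(s) %s", basename(path),
                     paste(missing, collapse = ", ")))
  num_cols <- intersect(names(df), c("t_months", "alsfrs_r", "nfl_pg_ml",
                                     "age_at_sampling", "survival_months",
                                     "umn_regions", "lmn_regions",
                                     "t_sampling_months", "log10_nfl"))
  for (nm in num_cols) {
    v <- suppressWarnings(as.numeric(df[[nm]]))
    bad <- which(is.na(v) & !is.na(df[[nm]]) & df[[nm]] != "")
    if (length(bad))
      stop_d50("d50als_schema_error",
               sprintf("%s: non-numeric '%s' at data row(s) %s",
                       basename(path), nm,
                       paste(utils::head(bad, 5), collapse = ", ")))
    df[[nm]] <- v
  }
  if (what == "assessments" && nrow(df) &&
      any(df$alsfrs_r < 0 | df$alsfrs_r > 48, na.rm = TRUE))
    stop_d50("d50als_schema_error",
             sprintf("%s: ALSFRS-R outside [0, 48]", basename(path)))
  df
}

#' Read a cohort from its three CSV files
#'
#' @param patients,assessments,samples Paths to the three CSVs (schemas as
#'   written by [write_cohort]). Malformed files raise classed schema errors
#'   naming the offending column or row.
#' @return List with elements `patients`, `assessments`, `samples`.
#' @export
read_cohort <- function(patients, assessments, samples) {
  list(patients = read_table_checked(patients, "patients"),
       assessments = read_table_checked(assessments, "assessments"),
       samples = read_table_checked(samples, "samples"))
}

#' Write a cohort to CSV files plus a JSON config sidecar
#'
#' @param cohort A `synthetic_cohort` from [build_cohort] (or a compatible
#'   list of tables).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (`patients.csv`, `assessments.csv`,
#'   `samples.csv`, and `config.json` when a config is present).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(patients = file.path(dir, "patients.csv"),
             assessments = file.path(dir, "assessments.csv"),
             samples = file.path(dir, "samples.csv"))
  utils::write.csv(cohort$patients, paths["patients"], row.names = FALSE)
  utils::write.csv(cohort$assessments, paths["assessments"], row.names = FALSE)
  utils::write.csv(cohort$samples, paths["samples"], row.names = FALSE)
  if (!is.null(cohort$config)) {
    cfgp <- file.path(dir, "config.json")
    jsonlite::write_json(unclass(cohort$config), cfgp, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    paths <- c(paths, config = cfgp)
  }
  invisible(paths)
}

#' Serialize a study report
#'
#' Writes the full report as JSON and, alongside it, a human-readable text
#' rendering.
#'
#' @param report A `d50_study_report` from [run_study].
#' @param path Output path for the JSON file; the text rendering goes to the
#'   same path with extension `.txt`.
#' @return Invisibly, the JSON path.
#' @export
write_report <- function(report, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  ser <- serialize_report(report)
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE, na = "null")
  txt <- sub("\\.json$", ".txt", path)
  if (identical(txt, path)) txt <- paste0(path, ".txt")
  writeLines(utils::capture.output(print(report)), txt)
  invisible(path)
}

# strip model objects etc. so the JSON is plain data
serialize_report <- function(x) {
  scrub <- function(v) {
    if (inherits(v, "lm")) return(NULL)
    if (is.function(v)) return(NULL)
    if (is.factor(v)) return(as.character(v))
    if (is.data.frame(v)) {
      v[] <- lapply(v, function(col) if (is.factor(col)) as.character(col)
                    else col)
      return(v)
    }
    if (is.list(v)) {
      out <- lapply(v, scrub)
      return(out[!vapply(out, is.null, logical(1))])
    }
    v
  }
  scrub(unclass_deep(x))
}

unclass_deep <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x)) {
    x <- unclass(x)
    return(lapply(x, unclass_deep))
  }
  x
}
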