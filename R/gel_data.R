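#' Default column schema for gel-assay CSV files
#'
#' Maps the package's canonical field names to CSV column names. Override any
#' entry to read files with different headers, e.g.
#' `gel_schema(b16_measured = "recovered")`.
#'
#' Canonical fields: `dataset` (small integer label), `experiment` (small
#' integer label), `replicate` (integer), `b16_desired` (desired B16 tumor
#' concentration, cell/mL), `otl_conc` (OT1 CTL concentration, cell/mL),
#' `time_h` (hours since inoculation), `b16_measured` (recovered B16
#' concentration, cell/mL; zero allowed).
#'
#' @param ... Named overrides, `canonical = "csv_column"`.
#' @return Named character vector mapping canonical names to column names.
#' @export
gel_schema <- function(...) {
  schema <- c(
    dataset = "dataset", experiment = "experiment", replicate = "replicate",
    b16_desired = "b16_desired", otl_conc = "otl_conc",
    time_h = "time_h", b16_measured = "b16_measured"
  )
  dots <- c(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(schema))
    if (length(bad)) stop("unknown schema field(s): ", paste(bad, collapse = ", "))
    schema[names(dots)] <- dots
  }
  schema
}

gel_fields <- function() names(gel_schema())

#' Validate a data frame of gel measurements
#'
#' Checks the invariants of a gel measurement record: desired tumor
#' concentration positive, CTL concentration, time and measured concentration
#' non-negative, no missing values. Rows are reported by number on failure.
#'
#' @param df Data frame with the canonical columns (see [gel_schema()]).
#' @return The validated data frame with class `gel_data`.
#' @export
as_gel_data <- function(df) {
  missing_cols <- setdiff(gel_fields(), names(df))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[gel_fields()]
  num_fields <- c("b16_desired", "otl_conc", "time_h", "b16_measured")
  for (f in num_fields) df[[f]] <- as.numeric(df[[f]])
  bad_row <- function(ok, what) {
    if (!all(ok)) {
      stop("invalid ", what, " in row(s): ",
           paste(which(!ok), collapse = ", "), call. = FALSE)
    }
  }
  bad_row(complete.cases(df), "missing value")
  bad_row(df$b16_desired > 0, "b16_desired (must be > 0)")
  bad_row(df$otl_conc >= 0, "otl_conc (must be >= 0)")
  bad_row(df$time_h >= 0, "time_h (must be >= 0)")
  bad_row(df$b16_measured >= 0, "b16_measured (must be >= 0)")
  class(df) <- c("gel_data", "data.frame")
  df
}

#' Read gel-assay measurements from CSV
#'
#' Reads a plain UTF-8 CSV with a header row into a validated `gel_data`
#' frame. Units are taken as cell/mL for concentrations and hours for time.
#'
#' @param path Path to the CSV file.
#' @param schema Column-name mapping from [gel_schema()].
#' @return A `gel_data` data frame.
#' @export
read_gel_csv <- function(path, schema = gel_schema()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(unname(schema), names(raw))
  if (length(missing_cols)) {
    stop("schema error: column(s) not in file: ",
         paste(missing_cols, collapse = ", "))
  }
  df <- raw[unname(schema)]
  names(df) <- names(schema)
  as_gel_data(df)
}

#' Write gel-assay measurements to CSV
#'
#' Inverse of [read_gel_csv()]; the round trip preserves every field.
#'
#' @param data A `gel_data` data frame.
#' @param path Output path.
#' @param schema Column-name mapping from [gel_schema()].
#' @return `path`, invisibly.
#' @export
write_gel_csv <- function(data, path, schema = gel_schema()) {
  data <- as_gel_data(data)
  out <- data[names(schema)]
  names(out) <- unname(schema)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Filter specification for gel measurements
#'
#' Declarative record selection and zero-count handling, so limit-of-detection
#' sensitivity analyses are re-runs with a different policy rather than
#' different files. Zero-count gels stay in storage and are only excluded (or
#' imputed at the LOD) at analysis time.
#'
#' @param max_ctl_conc Keep records with CTL concentration `<=` this value
#'   (cell/mL); `Inf` for unbounded.
#' @param datasets,desired_concs,experiments Optional vectors restricting the
#'   corresponding fields; `NULL` keeps all.
#' @param excluded_conditions Optional data frame with columns `dataset`,
#'   `b16_desired`, `otl_conc`; matching records are dropped.
#' @param zero_policy `"exclude"` drops gels with zero measured cells;
#'   `"impute_lod"` replaces zero with `lod_value`.
#' @param lod_value Limit of detection in cell/mL, required (and only used)
#'   when `zero_policy = "impute_lod"`; must lie in `[2, 10]`.
#' @return An object of class `gel_filter`.
#' @export
gel_filter <- function(max_ctl_conc = Inf, datasets = NULL,
                       desired_concs = NULL, experiments = NULL,
                       excluded_conditions = NULL,
                       zero_policy = c("exclude", "impute_lod"),
                       lod_value = NULL) {
  zero_policy <- match.arg(zero_policy)
  if (zero_policy == "impute_lod") {
    if (is.null(lod_value)) stop("zero_policy = 'impute_lod' requires lod_value")
    if (lod_value < 2 || lod_value > 10) {
      stop("lod_value must be in [2, 10] cell/mL")
    }
  }
  if (!is.null(excluded_conditions)) {
    need <- c("dataset", "b16_desired", "otl_conc")
    if (!all(need %in% names(excluded_conditions))) {
      stop("excluded_conditions needs columns: ", paste(need, collapse = ", "))
    }
  }
  structure(
    list(max_ctl_conc = max_ctl_conc, datasets = datasets,
         desired_concs = desired_concs, experiments = experiments,
         excluded_conditions = excluded_conditions,
         zero_policy = zero_policy, lod_value = lod_value),
    class = "gel_filter"
  )
}

#' Apply a filter to gel measurements
#'
#' Removes records violating any criterion of the [gel_filter()]; zero-count
#' gels are excluded or imputed at the LOD according to the filter's policy.
#' The per-rule removal/imputation tally is attached as attribute
#' `"filter_report"` and shown by the print method.
#'
#' @param data A `gel_data` data frame.
#' @param spec A `gel_filter`.
#' @return Filtered `gel_data` with a `filter_report` attribute.
#' @export
apply_filter <- function(data, spec) {
  data <- as_gel_data(data)
  stopifnot(inherits(spec, "gel_filter"))
  report <- c()
  drop_rule <- function(df, keep, rule) {
    report[[rule]] <<- sum(!keep)
    df[keep, , drop = FALSE]
  }
  data <- drop_rule(data, data$otl_conc <= spec$max_ctl_conc, "max_ctl_conc")
  if (!is.null(spec$datasets)) {
    data <- drop_rule(data, data$dataset %in% spec$datasets, "datasets")
  }
  if (!is.null(spec$desired_concs)) {
    data <- drop_rule(data, data$b16_desired %in% spec$desired_concs,
                      "desired_concs")
  }
  if (!is.null(spec$experiments)) {
    data <- drop_rule(data, data$experiment %in% spec$experiments,
                      "experiments")
  }
  if (!is.null(spec$excluded_conditions)) {
    ex <- spec$excluded_conditions
    key <- function(d, ta, e) paste(d, signif(ta, 12), signif(e, 12))
    hit <- key(data$dataset, data$b16_desired, data$otl_conc) %in%
      key(ex$dataset, ex$b16_desired, ex$otl_conc)
    data <- drop_rule(data, !hit, "excluded_conditions")
  }
  zero <- data$b16_measured == 0
  if (spec$zero_policy == "exclude") {
    data <- drop_rule(data, !zero, "zero_excluded")
  } else {
    data$b16_measured[zero] <- spec$lod_value
    report[["zero_imputed"]] <- sum(zero)
  }
  if (nrow(data) == 0) warning("filter removed every record")
  rownames(data) <- NULL
  attr(data, "filter_report") <- report
  class(data) <- c("gel_data", "data.frame")
  data
}

#' @export
print.gel_data <- function(x, ...) {
  cat("Gel measurements: ", nrow(x), " records, ",
      length(unique(x$dataset)), " dataset(s)\n", sep = "")
  rep_tab <- attr(x, "filter_report")
  if (!is.null(rep_tab) && length(rep_tab)) {
    cat("Filter report (records removed/imputed per rule):\n")
    for (nm in names(rep_tab)) cat("  ", nm, ": ", rep_tab[[nm]], "\n", sep = "")
  }
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("... and", nrow(x) - 10, "more rows\n")
  invisible(x)
}
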