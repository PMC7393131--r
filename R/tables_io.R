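#' @title Schema-validated table I/O and run configuration
#' @description Readers and writers for all tabular inputs and outputs.  Every
#'   table is long-format CSV/TSV with a declared schema (required columns, key
#'   columns, numeric columns); wide matrices exist only as in-memory views.
#'   Missing values are written as empty fields; "NA" is accepted on read but
#'   never written.
#' @name tables_io
NULL

# Registry of table schemas: required columns, primary-key columns, numeric
# columns.  growth accepts either a volume_mm3 or a flux measurement column.
.schemas <- list(
  metabolite_panel = list(
    required = c("metabolite", "sample", "cell_line", "condition", "replicate", "area"),
    key = c("metabolite", "sample"),
    numeric = "area"),
  pathway_map = list(
    required = c("metabolite", "pathway"),
    key = "metabolite",
    numeric = character(0)),
  clonogenic = list(
    required = c("cell_line", "treatment", "dose_gy", "cells_plated", "colonies", "replicate"),
    key = c("cell_line", "treatment", "dose_gy", "replicate"),
    numeric = c("dose_gy", "cells_plated", "colonies")),
  viability = list(
    required = c("cell_line", "treatment", "dose_gy", "viability", "replicate"),
    key = c("cell_line", "treatment", "dose_gy", "replicate"),
    numeric = c("dose_gy", "viability")),
  growth = list(
    required = c("animal", "arm", "day"),
    one_of = c("volume_mm3", "flux"),
    key = c("animal", "day"),
    numeric = c("day", "volume_mm3", "flux")),
  survival = list(
    required = c("subject", "group", "time_days", "event"),
    key = "subject",
    numeric = c("time_days", "event")),
  expression_survival = list(
    required = c("patient", "gene", "expression", "os_days", "os_event"),
    key = c("patient", "gene"),
    numeric = c("expression", "os_days", "os_event")),
  isotopologue = list(
    required = c("metabolite", "isotopologue", "area"),
    key = c("metabolite", "isotopologue"),
    numeric = c("isotopologue", "area")),
  resistance = list(
    required = c("cell_line", "dmid"),
    key = "cell_line",
    numeric = "dmid"),
  pathway_scores = list(
    required = c("pathway", "cell_line", "down_score", "up_score", "n_measured"),
    key = c("pathway", "cell_line"),
    numeric = c("down_score", "up_score", "n_measured")),
  pathway_correlations = list(
    required = c("pathway", "direction", "n", "r", "p", "q", "significant"),
    key = c("pathway", "direction"),
    numeric = c("n", "r", "p", "q")),
  qc_report = list(
    required = c("metabolite", "cell_line", "condition", "action", "reason"),
    key = character(0),
    numeric = character(0)),
  lq_fits = list(
    required = c("cell_line", "treatment", "alpha", "beta", "dmid"),
    key = c("cell_line", "treatment"),
    numeric = c("alpha", "beta", "dmid")),
  enhancement = list(
    required = c("cell_line", "comparison", "er", "basis"),
    key = c("cell_line", "comparison"),
    numeric = "er"),
  tripling = list(
    required = c("animal", "arm", "tripling_day", "censored", "last_day"),
    key = "animal",
    numeric = c("tripling_day", "last_day")),
  endpoint_summary = list(
    required = c("arm", "n", "events", "median"),
    key = "arm",
    numeric = c("n", "events", "median")),
  pairwise_tests = list(
    required = c("comparison", "statistic", "df_or_n", "p"),
    key = "comparison",
    numeric = c("statistic", "df_or_n", "p"))
)

#' List the table schemas the package validates
#'
#' @return named list; each element has `required`, `key`, and `numeric`
#'   column sets (and `one_of` for schemas accepting alternative measurement
#'   columns).
#' @export
table_schemas <- function() .schemas

.get_schema <- function(schema_name) {
  sc <- .schemas[[schema_name]]
  if (is.null(sc)) stop(sprintf("unknown schema '%s'", schema_name))
  sc
}

.sniff_sep <- function(path) {
  line <- readLines(path, n = 1L, warn = FALSE)
  if (length(line) == 0) return("\t")
  if (grepl("\t", line)) "\t" else ","
}

#' Read and validate a long-format table
#'
#' Reads a CSV or TSV file (delimiter sniffed from the header line) and
#' validates it against a named schema: all required columns present, no
#' duplicate primary-key tuples, numeric columns parse as finite numbers or
#' missing.  Empty fields and the literal "NA" are read as missing.
#'
#' @param path file path.
#' @param schema_name one of `names(table_schemas())`.
#' @return validated data.frame with attributes `schema_name` and `source`.
#' @export
read_long_table <- function(path, schema_name) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (file.size(path) == 0) stop(sprintf("schema error: empty file %s", path))
  sep <- .sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character",
                          na.strings = c("", "NA"),
                          check.names = FALSE, quote = "\"",
                          stringsAsFactors = FALSE)
  validate_table(df, schema_name, source = path)
}

#' Validate an in-memory table against a schema
#'
#' @param df data.frame.
#' @param schema_name schema identifier.
#' @param source provenance label recorded on the result.
#' @return the validated data.frame (numeric columns coerced), with
#'   attributes `schema_name` and `source`.
#' @export
validate_table <- function(df, schema_name, source = "in-memory") {
  sc <- .get_schema(schema_name)
  missing_cols <- setdiff(sc$required, names(df))
  if (length(missing_cols)) {
    stop(sprintf("schema error [%s]: missing required column(s): %s",
                 schema_name, paste(missing_cols, collapse = ", ")))
  }
  if (!is.null(sc$one_of) && !any(sc$one_of %in% names(df))) {
    stop(sprintf("schema error [%s]: need one of column(s): %s",
                 schema_name, paste(sc$one_of, collapse = ", ")))
  }
  if (nrow(df) == 0) stop(sprintf("schema error [%s]: table has no rows", schema_name))
  for (col in intersect(sc$numeric, names(df))) {
    if (is.numeric(df[[col]])) next
    raw <- as.character(df[[col]])
    suppressWarnings(num <- as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(num))
    if (length(bad)) {
      stop(sprintf("parse error [%s]: column '%s' not numeric at row %d (value '%s')",
                   schema_name, col, bad[1], raw[bad[1]]))
    }
    if (any(is.infinite(num))) {
      stop(sprintf("parse error [%s]: column '%s' contains non-finite values",
                   schema_name, col))
    }
    df[[col]] <- num
  }
  keys <- intersect(sc$key, names(df))
  if (length(keys)) {
    keytup <- do.call(paste, c(df[keys], sep = "\r"))
    if (anyDuplicated(keytup)) {
      dup <- keytup[duplicated(keytup)][1]
      stop(sprintf("integrity error [%s]: duplicate key (%s) = (%s)",
                   schema_name, paste(keys, collapse = ", "),
                   gsub("\r", ", ", dup)))
    }
  }
  attr(df, "schema_name") <- schema_name
  attr(df, "source") <- source
  df
}

#' Write a table as TSV with reproducible formatting
#'
#' Integers are written exactly; floating-point values with 6 significant
#' digits; missing values as empty fields.  Two writes of the same table are
#' byte-identical, and a round trip through [read_long_table()] returns an
#' equal table.
#'
#' @param table data.frame.
#' @param path output path (.tsv).
#' @export
write_table <- function(table, path) {
  fmt_col <- function(v) {
    if (is.logical(v)) return(ifelse(is.na(v), "", ifelse(v, "TRUE", "FALSE")))
    if (is.numeric(v)) {
      out <- vapply(v, function(x) {
        if (is.na(x)) return("")
        if (is.finite(x) && x == round(x) && abs(x) < 1e15) {
          return(format(x, scientific = FALSE, trim = TRUE))
        }
        formatC(x, digits = 6, format = "g")
      }, character(1))
      return(out)
    }
    ifelse(is.na(v), "", as.character(v))
  }
  header <- paste(names(table), collapse = "\t")
  if (nrow(table) == 0L) {
    lines <- header
  } else {
    mat <- vapply(table, fmt_col, character(nrow(table)))
    if (nrow(table) == 1L) mat <- matrix(mat, nrow = 1L)
    lines <- c(header, apply(mat, 1L, paste, collapse = "\t"))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con = con, sep = "\n")
  invisible(path)
}

#' Construct a validated run configuration
#'
#' Central container for the analysis thresholds: regulation-call z cutoffs
#' (default -1 / +1), the ion-count detection threshold (default 3000 counts)
#' and replicate coefficient-of-variation cutoff (default 0.5), the FDR
#' threshold for pathway significance (default 0.1), the Dmid integration
#' range (default 8 Gy, the maximum assayed dose), the random seed, and the
#' unit of analysis for post-irradiation fold-change correlations.
#'
#' @param z_lower,z_upper regulation thresholds (dimensionless).
#' @param min_ion_area ion-count detection threshold.
#' @param max_cv maximum replicate coefficient of variation.
#' @param fdr_threshold Benjamini-Hochberg significance cutoff, in (0, 1).
#' @param dose_max upper limit (Gy) of the Dmid integral.
#' @param seed integer random seed.
#' @param unit_of_analysis `"cell_line_mean"` or `"replicate"`.
#' @param max_missing_frac drop a metabolite missing in more than this
#'   fraction of replicate groups after QC.
#' @param normalization sample-normalization method recorded for the run.
#' @return list of class `run_config`.
#' @export
run_config <- function(z_lower = -1, z_upper = 1,
                       min_ion_area = 3000, max_cv = 0.5,
                       fdr_threshold = 0.1, dose_max = 8,
                       seed = 1L,
                       unit_of_analysis = c("cell_line_mean", "replicate"),
                       max_missing_frac = 0.5,
                       normalization = "none") {
  unit_of_analysis <- match.arg(unit_of_analysis)
  if (!(z_lower < z_upper)) stop("run_config: z_lower must be < z_upper")
  if (!(max_cv > 0)) stop("run_config: max_cv must be > 0")
  if (!(fdr_threshold > 0 && fdr_threshold < 1)) {
    stop("run_config: fdr_threshold must be in (0, 1)")
  }
  if (!(dose_max > 0)) stop("run_config: dose_max must be > 0")
  if (!(min_ion_area >= 0)) stop("run_config: min_ion_area must be >= 0")
  if (!(max_missing_frac >= 0 && max_missing_frac <= 1)) {
    stop("run_config: max_missing_frac must be in [0, 1]")
  }
  structure(list(z_lower = z_lower, z_upper = z_upper,
                 min_ion_area = min_ion_area, max_cv = max_cv,
                 fdr_threshold = fdr_threshold, dose_max = dose_max,
                 seed = as.integer(seed),
                 unit_of_analysis = unit_of_analysis,
                 max_missing_frac = max_missing_frac,
                 normalization = normalization),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Unspecified fields take the package defaults; the full effective set is
#' embedded in the run manifest so defaults changing in future versions cannot
#' silently alter results.
#'
#' @param path .yaml/.yml or .json file.
#' @return `run_config` object.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop(sprintf("configuration error: unknown field(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  do.call(run_config, vals)
}
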