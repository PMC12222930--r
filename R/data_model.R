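#' shrubmeta: meta-analysis of shrubland vegetation responses
#'
#' Random-effects meta-analysis of multi-site shrubland manipulation
#' experiments: log response-ratio effect sizes, REML/DL pooling with
#' Wald z tests and bias-corrected bootstrap intervals, Egger/PEESE
#' publication-bias handling, duration subgrouping, and climate-moderator
#' meta-regression of driver-standardised sensitivities.
#'
#' @keywords internal
#' @aliases shrubmeta-package
"_PACKAGE"

#' Vegetation metrics recognised by the pipeline
#'
#' Aboveground biomass (AGB), aboveground net primary production (ANPP),
#' vegetation cover (COV), plant density (DEN), species richness (SP),
#' Shannon diversity (H) and the shrub proportion of the community
#' (Ratio_S).
#' @export
METRICS <- c("AGB", "ANPP", "COV", "DEN", "SP", "H", "Ratio_S")

#' Treatments recognised by the pipeline
#'
#' Four single-driver treatments and the two driver combinations.
#' Sensitivities are only defined for single-driver treatments.
#' @export
TREATMENTS <- c("warming", "increased_precipitation", "drought",
                "nitrogen", "warming_nitrogen", "precipitation_nitrogen")

#' Single-driver treatments (sensitivity is defined for these only)
#' @export
SINGLE_DRIVER_TREATMENTS <- c("warming", "increased_precipitation",
                              "drought", "nitrogen")

.record_columns <- c("site_id", "metric", "treatment",
                     "mean_treat", "mean_ctrl", "sd_treat", "sd_ctrl",
                     "n_treat", "n_ctrl", "driver_magnitude",
                     "driver_window", "duration_yr", "mat_c",
                     "aridity_index")

.numeric_columns <- c("mean_treat", "mean_ctrl", "sd_treat", "sd_ctrl",
                      "n_treat", "n_ctrl", "driver_magnitude",
                      "duration_yr", "mat_c", "aridity_index")

#' Construct a study set
#'
#' A study set is the container passed between pipeline stages: a
#' data.frame of experiment records (one treatment-control contrast per
#' vegetation metric per site) plus a provenance tag.
#'
#' @param records data.frame with the experiment-record columns (see
#'   [read_records()] for the schema).
#' @param provenance free-text source tag.
#' @param n_dropped number of rows removed during validation.
#' @return an object of class `study_set`.
#' @export
study_set <- function(records, provenance = "unknown", n_dropped = 0L) {
  stopifnot(is.data.frame(records))
  rownames(records) <- NULL
  structure(list(records = records, provenance = provenance,
                 n_dropped = as.integer(n_dropped)),
            class = "study_set")
}

#' @export
print.study_set <- function(x, ...) {
  cat("<study_set> ", nrow(x$records), " records from '", x$provenance,
      "'", sep = "")
  if (x$n_dropped > 0) cat(" (", x$n_dropped, " dropped)", sep = "")
  cat("\n")
  if (nrow(x$records) > 0) {
    tab <- table(x$records$metric, x$records$treatment)
    print(tab)
  }
  invisible(x)
}

# Per-row invariant checks; returns a character vector of violation
# messages ("" where the row is valid).
.validate_rows <- function(df) {
  msg <- character(nrow(df))
  flag <- function(bad, text) {
    bad[is.na(bad)] <- TRUE
    msg[bad & msg == ""] <<- text
  }
  flag(!(df$metric %in% METRICS), "unknown metric")
  flag(!(df$treatment %in% TREATMENTS), "unknown treatment")
  flag(!(df$driver_window %in% c("annual", "growing_season")),
       "unknown driver_window")
  flag(!(df$mean_treat > 0), "mean_treat must be > 0")
  flag(!(df$mean_ctrl > 0), "mean_ctrl must be > 0")
  flag(!(df$sd_treat >= 0), "sd_treat must be >= 0")
  flag(!(df$sd_ctrl >= 0), "sd_ctrl must be >= 0")
  flag(!(df$n_treat >= 2 & df$n_treat == round(df$n_treat)),
       "n_treat must be an integer >= 2")
  flag(!(df$n_ctrl >= 2 & df$n_ctrl == round(df$n_ctrl)),
       "n_ctrl must be an integer >= 2")
  flag(df$treatment == "drought" & !(df$driver_magnitude < 0),
       "drought requires driver_magnitude < 0")
  flag(df$treatment %in% c("increased_precipitation", "warming",
                           "nitrogen") & !(df$driver_magnitude > 0),
       "driver_magnitude must be > 0 for this treatment")
  flag(!(df$duration_yr > 0), "duration_yr must be > 0")
  flag(!(df$aridity_index > 0), "aridity_index must be > 0")
  msg
}

#' Read experiment records from CSV
#'
#' Reads a flat comma-separated table of treatment-control contrasts.
#' Required columns: `site_id`, `metric`, `treatment`, `mean_treat`,
#' `mean_ctrl`, `sd_treat`, `sd_ctrl`, `n_treat`, `n_ctrl`,
#' `driver_magnitude`, `duration_yr`, `mat_c`, `aridity_index`; the
#' optional `driver_window` column (warming only) defaults to
#' `"annual"`. Rows violating the record invariants (positive means,
#' at least two replicates per arm, treatment-consistent sign of the
#' driver magnitude, positive aridity index) abort the read in strict
#' mode and are dropped (and counted) otherwise. Duplicate
#' (site, metric, treatment, window) keys are allowed here — they are
#' multiple timepoints, collapsed later by [aggregate_studyset()].
#'
#' @param path path to a CSV file with a header row.
#' @param strict if `TRUE`, any invariant violation aborts; otherwise
#'   offending rows are dropped with a message.
#' @param provenance source tag stored on the result.
#' @return a [study_set()].
#' @export
read_records <- function(path, strict = FALSE, provenance = basename(path)) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop("cannot read records file: ", path)
  if (isTRUE(file.info(path)$size == 0))
    stop("empty input: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character",
                         strip.white = TRUE)
  if (nrow(raw) == 0L)
    stop("empty input: no data rows in ", path)
  if (!("driver_window" %in% names(raw)))
    raw$driver_window <- "annual"
  raw$driver_window[raw$driver_window %in% c("", "NA")] <- "annual"
  missing <- setdiff(.record_columns, names(raw))
  if (length(missing))
    stop("schema error: missing column(s): ",
         paste(missing, collapse = ", "))
  for (col in .numeric_columns) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !(raw[[col]] %in% c("", "NA")))
    if (length(bad))
      stop(sprintf("parse error: non-numeric value '%s' in column '%s' at data row %d",
                   raw[[col]][bad[1]], col, bad[1]))
    raw[[col]] <- v
  }
  df <- raw[, .record_columns]
  msg <- .validate_rows(df)
  bad <- msg != ""
  if (any(bad)) {
    detail <- paste(sprintf("row %d: %s", which(bad), msg[bad]),
                    collapse = "; ")
    if (strict)
      stop("invalid records (strict mode): ", detail)
    message("read_records: dropped ", sum(bad), " invalid row(s): ",
            detail)
  }
  study_set(df[!bad, , drop = FALSE], provenance = provenance,
            n_dropped = sum(bad))
}

#' Write experiment records to CSV
#'
#' Inverse of [read_records()]: writes the records table so that
#' read -> write -> read is the identity on valid records.
#'
#' @param x a [study_set()] or a records data.frame.
#' @param path output CSV path.
#' @export
write_records <- function(x, path) {
  df <- if (inherits(x, "study_set")) x$records else x
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.assert_finite <- function(x, where = "result") {
  if (is.list(x)) {
    nms <- names(x)
    for (i in seq_along(x)) {
      lab <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else i
      .assert_finite(x[[i]], paste0(where, "$", lab))
    }
  } else if (is.numeric(x)) {
    # NA marks a quantity that is legitimately unavailable (e.g. the
    # p-value of a single-study stratum); NaN/Inf mark computation bugs.
    if (any(is.nan(x) | is.infinite(x)))
      stop("non-finite value in ", where)
  }
  invisible(TRUE)
}

#' Write a result object to JSON
#'
#' Serialises any pipeline result (pooled results, bias diagnostics,
#' whole reports) as JSON with stable key order and full numeric
#' precision, so that re-reading reproduces every number exactly.
#' `NaN` or infinite fields are a contract violation and abort; `NA`
#' (unavailable quantity) is serialised as `null`.
#'
#' @param results a list-like result object (or list of them).
#' @param path output path.
#' @export
write_results <- function(results, path) {
  .assert_finite(unclass_deep(results))
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) stop("cannot write to ", path, ": ",
                                           conditionMessage(e)))
  on.exit(close(con))
  # I(17) = 17 significant digits, enough for doubles to re-read exactly
  json <- jsonlite::toJSON(unclass_deep(results), auto_unbox = TRUE,
                           digits = I(17), null = "null", na = "null",
                           pretty = TRUE)
  writeLines(json, con)
  invisible(path)
}

# Strip S3 classes recursively so jsonlite serialises plain lists.
unclass_deep <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(unclass(x), unclass_deep))
  x
}

#' Read back a JSON result document
#'
#' @param path path written by [write_results()].
#' @return the parsed list.
#' @export
read_results <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
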