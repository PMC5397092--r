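measurement_cols <- c("cell_id", "genotype", "dose_ng_ml", "time_min", "response")

#' Validate a long-format measurement table
#'
#' The canonical input is a long table with one row per (cell, time point):
#' columns `cell_id`, `genotype`, `dose_ng_ml`, `time_min`, `response`.
#' Checks: nonnegative doses, positive times, finite numeric responses, no
#' duplicate (cell_id, genotype, dose, time) rows.
#'
#' @param table A data frame.
#' @return The validated table as a tibble.
#' @export
validate_measurements <- function(table) {
  table <- tibble::as_tibble(table)
  missing_cols <- setdiff(measurement_cols, names(table))
  if (length(missing_cols)) {
    stop_cd(paste0("Measurement table is missing column(s): ",
                   paste(missing_cols, collapse = ", "), "."), "parse_error")
  }
  if (!is.numeric(table$dose_ng_ml) || anyNA(table$dose_ng_ml) ||
      any(table$dose_ng_ml < 0)) {
    stop_cd("`dose_ng_ml` must be numeric and >= 0.", "parse_error")
  }
  if (!is.numeric(table$time_min) || anyNA(table$time_min) ||
      any(table$time_min <= 0)) {
    stop_cd("`time_min` must be numeric and > 0.", "parse_error")
  }
  if (!is.numeric(table$response) || any(!is.finite(table$response))) {
    stop_cd("`response` must be finite numeric.", "parse_error")
  }
  dup <- table |>
    dplyr::count(.data$cell_id, .data$genotype, .data$dose_ng_ml,
                 .data$time_min) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup)) {
    stop_cd(sprintf(
      "Duplicate (cell_id, genotype, dose, time) rows, e.g. cell '%s'.",
      dup$cell_id[1]), "parse_error")
  }
  table
}

#' Read single-cell measurements
#'
#' Reads the canonical long-format table from CSV or TSV (header required,
#' UTF-8), or from a MATLAB `.mat` file through a field-mapping adapter
#' (see [read_measurements_mat()]), and validates it.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"csv"`, `"tsv"` or `"mat"`.
#' @param mat_mapping Field mapping for `.mat` input; see
#'   [read_measurements_mat()].
#' @return A validated measurement tibble.
#' @export
read_measurements <- function(path, format = c("auto", "csv", "tsv", "mat"),
                              mat_mapping = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_cd(sprintf("File not found: %s", path), "parse_error")
  }
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", tsv = "tsv", tab = "tsv", mat = "mat",
                     stop_cd(sprintf("Cannot infer format from '%s'.", path),
                             "parse_error"))
  }
  tbl <- switch(format,
    csv = readr::read_csv(path, show_col_types = FALSE),
    tsv = readr::read_tsv(path, show_col_types = FALSE),
    mat = return(read_measurements_mat(path, mapping = mat_mapping))
  )
  validate_measurements(tbl)
}

#' Write single-cell measurements to CSV
#'
#' @param table A measurement table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(table, path) {
  readr::write_csv(validate_measurements(table), path)
  invisible(path)
}

#' MATLAB adapter for measurement tables
#'
#' Maps 1-D arrays inside a `.mat` file onto the canonical long-format
#' columns. Because the internal structure of third-party `.mat` archives
#' is not standardized, the variable names must be supplied explicitly via
#' `mapping` after inspecting the file: a named list whose names are the
#' canonical columns (`cell_id`, `genotype`, `dose_ng_ml`, `time_min`,
#' `response`) and whose values are the corresponding `.mat` variable
#' names; all mapped variables must be flat arrays of equal length.
#'
#' The file is decoded by the `python` interpreter's `scipy.io` (no R
#' MATLAB reader is used), so a `python` with scipy must be on the PATH.
#'
#' @param path `.mat` file path.
#' @param mapping Named list/character vector of field names (see above).
#' @param python Python executable; found on the PATH by default.
#' @return A validated measurement tibble.
#' @export
read_measurements_mat <- function(path, mapping,
                                  python = Sys.which("python")) {
  if (is.null(mapping)) {
    stop_cd(paste0(
      "Reading .mat input requires `mat_mapping`: a named list mapping the ",
      "canonical columns (", paste(measurement_cols, collapse = ", "),
      ") to variable names inside the file. Inspect the file to determine ",
      "them; the structure is not assumed."), "parse_error")
  }
  mapping <- as.list(mapping)
  if (!all(measurement_cols %in% names(mapping))) {
    stop_cd(paste0("`mapping` must name all of: ",
                   paste(measurement_cols, collapse = ", "), "."),
            "parse_error")
  }
  if (!nzchar(python)) {
    stop_cd("No `python` executable found; needed to decode .mat input.",
            "parse_error")
  }
  out_csv <- tempfile(fileext = ".csv")
  script <- tempfile(fileext = ".py")
  spec_json <- paste(sprintf('"%s": "%s"', names(mapping), unlist(mapping)),
                     collapse = ", ")
  writeLines(c(
    "import sys, scipy.io, pandas as pd, numpy as np",
    sprintf("m = scipy.io.loadmat(%s, squeeze_me=True)", deparse(path)),
    sprintf("mapping = {%s}", spec_json),
    "cols = {}",
    "for col, var in mapping.items():",
    "    if var not in m:",
    "        sys.exit(f'variable {var!r} not present in .mat file')",
    "    cols[col] = np.ravel(m[var])",
    "lengths = {len(v) for v in cols.values()}",
    "if len(lengths) != 1:",
    "    sys.exit(f'mapped variables have unequal lengths: {lengths}')",
    sprintf("pd.DataFrame(cols).to_csv(%s, index=False)", deparse(out_csv))
  ), script)
  status <- system2(python, script, stdout = TRUE, stderr = TRUE)
  code <- attr(status, "status") %||% 0L
  if (code != 0L || !file.exists(out_csv)) {
    stop_cd(paste0("Failed to decode .mat file: ",
                   paste(status, collapse = "\n")), "parse_error")
  }
  validate_measurements(readr::read_csv(out_csv, show_col_types = FALSE))
}
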