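#' @name cell_table
#' @title The cell-table format
#' @description
#' A cell table is a plain data.frame with one row per segmented cell:
#' `cell_id` (unique within its core), `core_id`, `x_um`/`y_um` centroid
#' coordinates in micrometres (image convention: origin at the core's
#' top-left bounding box, y increasing downward), one strictly binary column
#' per marker, and optionally a `phenotype` label column. On disk it is a
#' tab-separated UTF-8 file with a header row, "." decimal separator and no
#' quoting. Marker columns are auto-detected as all columns other than the
#' reserved names.
NULL

.reserved_cell_cols <- c("cell_id", "core_id", "x_um", "y_um", "phenotype")

#' Marker columns of a cell table
#' @param cells a cell table
#' @return character vector of marker column names
#' @export
marker_columns <- function(cells) {
  setdiff(names(cells), .reserved_cell_cols)
}

#' Validate a cell table
#'
#' Checks the required columns, coordinate finiteness, strict binarity of
#' marker columns and cell-id uniqueness within each core; coerces marker
#' columns to integer.
#'
#' @param cells data.frame to validate
#' @return the validated cell table (invisibly modified: markers as integer)
#' @export
validate_cell_table <- function(cells) {
  if (!is.data.frame(cells)) stop_osimc("cell table must be a data.frame")
  for (col in c("cell_id", "core_id", "x_um", "y_um")) {
    if (!col %in% names(cells))
      stop_osimc("missing column ", col)
  }
  cells$cell_id <- as.character(cells$cell_id)
  cells$core_id <- as.character(cells$core_id)
  if (nrow(cells) > 0L) {
    if (!all(is.finite(cells$x_um)) || !all(is.finite(cells$y_um)))
      stop_osimc("non-finite coordinates in cell table")
    if (anyDuplicated(paste(cells$core_id, cells$cell_id, sep = "\r")))
      stop_osimc("cell_id values are not unique within core_id")
  }
  for (m in marker_columns(cells)) {
    v <- cells[[m]]
    bad <- which(!(v %in% c(0, 1)) | is.na(v))
    if (length(bad) > 0L)
      stop_osimc("non-binary value in marker column '", m,
                 "' at row ", bad[1L])
    cells[[m]] <- as.integer(v)
  }
  cells
}

#' Read a cell table from TSV
#' @param path path to a tab-separated cell table
#' @return validated cell table data.frame
#' @export
read_cell_table <- function(path) {
  if (!file.exists(path)) stop_osimc("file not found: ", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_cell_table(df)
}

#' Write a cell table to TSV
#' @param cells cell table
#' @param path output path
#' @return `path`, invisibly
#' @export
write_cell_table <- function(cells, path) {
  cells <- validate_cell_table(cells)
  write.table(cells, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate a clinical table
#'
#' One row per case: `case_id`, logical `initial_metastasis`, and for the
#' metastasis-free (MFS) and recurrence-free (RFS) endpoints an event
#' indicator and a time in months (`met_event`/`met_time`,
#' `rec_event`/`rec_time`). Times must be non-negative and events must carry
#' positive times.
#'
#' @param clin data.frame to validate
#' @return validated clinical data.frame
#' @export
validate_clinical <- function(clin) {
  req <- c("case_id", "initial_metastasis", "met_event", "met_time",
           "rec_event", "rec_time")
  for (col in req) if (!col %in% names(clin))
    stop_osimc("missing column ", col)
  clin$case_id <- as.character(clin$case_id)
  dup <- unique(clin$case_id[duplicated(clin$case_id)])
  if (length(dup) > 0L)
    stop_osimc("duplicate case_id: ", paste(dup, collapse = ", "))
  for (col in c("initial_metastasis", "met_event", "rec_event"))
    clin[[col]] <- as.logical(clin[[col]])
  for (col in c("met_time", "rec_time")) {
    if (any(!is.finite(clin[[col]])) || any(clin[[col]] < 0))
      stop_osimc("negative or non-finite ", col)
  }
  if (any(clin$met_event & clin$met_time <= 0) ||
      any(clin$rec_event & clin$rec_time <= 0))
    stop_osimc("event with non-positive time")
  clin
}

#' Read a clinical table from CSV
#' @param path path to a comma-separated clinical table
#' @return validated clinical data.frame
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop_osimc("file not found: ", path)
  validate_clinical(read.csv(path, stringsAsFactors = FALSE))
}

#' Write a clinical table to CSV
#' @param clin clinical table
#' @param path output path
#' @return `path`, invisibly
#' @export
write_clinical <- function(clin, path) {
  clin <- validate_clinical(clin)
  write.csv(clin, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long-format cytokine plate from TSV
#'
#' Columns: `analyte`, `condition`, `cell_line`, `replicate`, `mfi`.
#'
#' @param path path to TSV
#' @return cytokine plate data.frame
#' @export
read_cytokine_plate <- function(path) {
  if (!file.exists(path)) stop_osimc("file not found: ", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("analyte", "condition", "cell_line", "replicate", "mfi")
  for (col in req) if (!col %in% names(df)) stop_osimc("missing column ", col)
  df
}

#' Write a long-format cytokine plate to TSV
#' @param plate cytokine plate data.frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_cytokine_plate <- function(plate, path) {
  write.table(plate, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
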