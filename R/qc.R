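#' Core-level nuclear-stain quality control
#'
#' Computes, per core, the fraction of cells positive for the nuclear stain
#' (Ir191 DNA intercalator) relative to all nuclear-segmented cells, and
#' excludes cores whose fraction falls strictly below the threshold (the
#' conventional cutoff is 25%, an inflection point for poor staining
#' quality; a core at exactly the threshold is retained). Retained cells are
#' the Ir191-positive cells of retained cores — downstream, "total
#' detectable cells" means exactly this set.
#'
#' @param cells cell table with an Ir191 marker column
#' @param min_ir191_frac minimum retained Ir191-positive fraction (default 0.25)
#' @param ir191_col name of the nuclear-stain column (default `"Ir191"`)
#' @return list with `cores` (data.frame: core_id, n_cells, n_ir191_pos,
#'   ir191_fraction, pass), `cells` (filtered cell table), and the threshold
#'   used
#' @export
core_qc <- function(cells, min_ir191_frac = 0.25, ir191_col = "Ir191") {
  cells <- validate_cell_table(cells)
  if (!ir191_col %in% names(cells))
    stop_osimc("no ", ir191_col, " column in cell table")
  stopifnot(min_ir191_frac >= 0, min_ir191_frac <= 1)
  core_ids <- unique(cells$core_id)
  n_all <- tapply(rep(1L, nrow(cells)), cells$core_id, sum)[core_ids]
  n_pos <- tapply(cells[[ir191_col]], cells$core_id, sum)[core_ids]
  frac <- as.numeric(n_pos) / as.numeric(n_all)
  pass <- frac >= min_ir191_frac
  report <- data.frame(
    core_id = core_ids,
    n_cells = as.integer(n_all),
    n_ir191_pos = as.integer(n_pos),
    ir191_fraction = frac,
    pass = pass,
    stringsAsFactors = FALSE
  )
  keep <- cells$core_id %in% core_ids[pass] & cells[[ir191_col]] == 1L
  list(cores = report,
       cells = cells[keep, , drop = FALSE],
       min_ir191_frac = min_ir191_frac)
}

#' Marker-level quality control
#'
#' A case (core) counts as positive for a marker if at least
#' `min_cells_per_core` of its cells stain positive; a marker is retained if
#' at least `min_case_frac` of cases are positive (both boundaries inclusive
#' on the keep side: exactly 3 positive cells make a positive case, exactly
#' 10% positive cases retain the marker).
#'
#' @param cells cell table (normally the Ir191-filtered output of [core_qc()])
#' @param min_cells_per_core positive cells needed for a positive case (default 3)
#' @param min_case_frac minimum fraction of positive cases (default 0.10)
#' @param exclude markers to skip (default the nuclear stain `"Ir191"`)
#' @return list with `markers` (data.frame: marker, n_positive_cases,
#'   positive_case_fraction, pass), `retained` (character vector), and the
#'   thresholds used
#' @export
marker_qc <- function(cells, min_cells_per_core = 3, min_case_frac = 0.10,
                      exclude = "Ir191") {
  cells <- validate_cell_table(cells)
  if (nrow(cells) == 0L) stop_osimc("empty cell table")
  markers <- setdiff(marker_columns(cells), exclude)
  n_cases <- length(unique(cells$core_id))
  rows <- lapply(markers, function(m) {
    pos_per_core <- tapply(cells[[m]], cells$core_id, sum)
    n_pos_cases <- sum(pos_per_core >= min_cells_per_core)
    frac <- n_pos_cases / n_cases
    data.frame(marker = m, n_positive_cases = n_pos_cases,
               positive_case_fraction = frac,
               pass = frac >= min_case_frac, stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  list(markers = report,
       retained = report$marker[report$pass],
       min_cells_per_core = min_cells_per_core,
       min_case_frac = min_case_frac)
}
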