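#' Per-core phenotype abundance matrix
#'
#' Abundance of each phenotype as the percentage of that core's detectable
#' cells: `100 * count(label) / count(all cells in core)`. Every row sums to
#' 100 (the fallback "Unassigned" column included).
#'
#' @param cells labeled cell table (output of [assign_phenotypes()])
#' @param labels column order / guaranteed columns; defaults to the labels
#'   observed. Labels with no cells anywhere get all-zero columns.
#' @return data.frame, rows = cores (rownames core_id, plus a `core_id`
#'   column), one numeric percentage column per label
#' @export
abundance_matrix <- function(cells, labels = NULL) {
  cells <- validate_cell_table(cells)
  if (!"phenotype" %in% names(cells))
    stop_osimc("cells carry no phenotype column; run assign_phenotypes() first")
  if (nrow(cells) == 0L) stop_osimc("empty cell table")
  if (is.null(labels)) labels <- sort(unique(cells$phenotype))
  labels <- union(labels, unique(cells$phenotype))
  tab <- table(factor(cells$core_id), factor(cells$phenotype, levels = labels))
  tab <- matrix(as.numeric(tab), nrow = nrow(tab), dimnames = dimnames(tab))
  n <- rowSums(tab)
  if (any(n == 0L))
    stop_osimc("core with 0 cells: ", paste(rownames(tab)[n == 0], collapse = ", "))
  pct <- sweep(tab, 1, n, "/") * 100
  out <- data.frame(core_id = rownames(pct), pct, check.names = FALSE,
                    stringsAsFactors = FALSE)
  rownames(out) <- out$core_id
  out
}

# Pooled MDSC percentage: an explicit MDSC column if present, else
# mMDSC + pMDSC (treating an absent subtype column as absent, not zero).
pooled_component <- function(ab, comp) {
  if (comp %in% names(ab)) return(ab[[comp]])
  if (comp == "MDSC") {
    missing <- setdiff(c("mMDSC", "pMDSC"), names(ab))
    if (length(missing) > 0L)
      stop_osimc("missing component column(s) for MDSC pooling: ",
                 paste(missing, collapse = ", "))
    return(ab[["mMDSC"]] + ab[["pMDSC"]])
  }
  stop_osimc("missing component column: ", comp)
}

#' Composite abundance over a set of phenotypes
#'
#' Mean (or sum) of the component percentages per core. `"MDSC"` as a
#' component means the pooled mMDSC + pMDSC percentage unless an explicit
#' MDSC column exists. Since sum = k * mean, a median dichotomization of the
#' two modes produces identical groups.
#'
#' @param ab abundance matrix from [abundance_matrix()]
#' @param components character vector of component labels
#' @param mode `"mean"` or `"sum"`
#' @return named numeric vector, one value per core
#' @export
pairwise_composite <- function(ab, components, mode = c("mean", "sum")) {
  mode <- match.arg(mode)
  if (length(components) == 0L) stop_osimc("no components given")
  vals <- vapply(components, function(comp) pooled_component(ab, comp),
                 numeric(nrow(ab)))
  vals <- matrix(vals, nrow = nrow(ab))
  out <- if (mode == "mean") rowMeans(vals) else rowSums(vals)
  setNames(out, ab$core_id)
}

#' Immunosuppressive-cell (IMSC) composite score
#'
#' The IMSC abundance per core: the mean (default) or sum of the M2,
#' pooled-MDSC and Treg percentages.
#'
#' @inheritParams pairwise_composite
#' @return named numeric vector, one value per core
#' @export
imsc_score <- function(ab, mode = c("mean", "sum")) {
  pairwise_composite(ab, c("M2", "MDSC", "Treg"), mode = match.arg(mode))
}
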