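#' Construct a gating rule
#'
#' A phenotype definition: markers that must be positive, markers that must be
#' negative, and a priority rank used to resolve cells matching several rules
#' (lower rank is evaluated first). Markers not listed are "don't care",
#' matching conventional manual-gating practice.
#'
#' @param label phenotype name (unique within a rule set)
#' @param positive character vector of required-positive marker names
#' @param negative character vector of required-negative marker names
#' @param priority integer rank; lower = evaluated first
#' @return an object of class `gating_rule`
#' @export
gating_rule <- function(label, positive, negative = character(), priority) {
  stopifnot(is.character(label), length(label) == 1L, nchar(label) > 0L)
  positive <- as.character(positive)
  negative <- as.character(negative)
  if (length(positive) == 0L)
    stop_osimc("gating rule '", label, "' has no positive markers")
  if (length(intersect(positive, negative)) > 0L)
    stop_osimc("gating rule '", label, "' lists markers as both positive and negative: ",
               paste(intersect(positive, negative), collapse = ", "))
  structure(
    list(label = label, positive = positive, negative = negative,
         priority = as.integer(priority)),
    class = "gating_rule"
  )
}

#' Construct a rule set
#'
#' An ordered collection of [gating_rule()]s. Labels and priorities must be
#' unique; rules are stored sorted by priority. Cells matching no rule receive
#' the fallback label `"Unassigned"`.
#'
#' @param rules list of `gating_rule` objects
#' @param fallback label for cells matching no rule
#' @return an object of class `ruleset`
#' @export
ruleset <- function(rules, fallback = "Unassigned") {
  stopifnot(all(vapply(rules, inherits, logical(1), "gating_rule")))
  labels <- vapply(rules, `[[`, character(1), "label")
  prios  <- vapply(rules, `[[`, integer(1), "priority")
  if (anyDuplicated(labels))
    stop_osimc("duplicate rule labels: ",
               paste(unique(labels[duplicated(labels)]), collapse = ", "))
  if (anyDuplicated(prios))
    stop_osimc("duplicate rule priorities")
  rules <- rules[order(prios)]
  structure(list(rules = rules, fallback = fallback), class = "ruleset")
}

#' @export
print.ruleset <- function(x, ...) {
  cat("<ruleset> ", length(x$rules), " rules, fallback '", x$fallback, "'\n",
      sep = "")
  for (r in x$rules) {
    cat(sprintf("  %2d %-12s +{%s}", r$priority, r$label,
                paste(r$positive, collapse = ",")))
    if (length(r$negative))
      cat(" -{", paste(r$negative, collapse = ","), "}", sep = "")
    cat("\n")
  }
  invisible(x)
}

#' Marker names referenced by a rule set
#' @param rules a `ruleset`
#' @return character vector of marker names
#' @export
ruleset_markers <- function(rules) {
  sort(unique(unlist(lapply(rules$rules, function(r) c(r$positive, r$negative)))))
}

#' Phenotype labels defined by a rule set
#' @param rules a `ruleset`
#' @param include_fallback include the fallback label
#' @return character vector of labels in priority order
#' @export
ruleset_labels <- function(rules, include_fallback = TRUE) {
  lab <- vapply(rules$rules, `[[`, character(1), "label")
  if (include_fallback) c(lab, rules$fallback) else lab
}

#' The default osteosarcoma TME gating rule set
#'
#' Marker-combination definitions for the immune and stromal populations of
#' the osteosarcoma tumor microenvironment: macrophage subtypes (M2
#' CD68+CD163+, M1 CD68+HLA-DR+, M0 CD68+HLA-DR-CD163-), monocytic and
#' polymorphonuclear MDSC, classical/non-classical monocytes, neutrophils,
#' dendritic cells, NK subsets, T-cell subsets including Treg (CD3+FoxP3+)
#' and memory T cells, endothelial cells, fibroblasts, epithelial-like cells,
#' CD44+ stem-like cells and Ki-67+ proliferating cells.
#'
#' Priorities are most-specific-first so that each cell receives exactly one
#' label: memory T subsets precede their parent helper/cytotoxic subsets,
#' Treg precedes helper T, macrophage subtypes precede generic myeloid rules.
#' M1 carries an explicit CD163- constraint (beyond its CD68+HLA-DR+
#' definition) so M1 and M2 are disjoint regardless of priority; this is a
#' deliberate tightening and the rule set is user-editable.
#'
#' @return a `ruleset` with 23 rules
#' @export
default_ruleset <- function() {
  r <- list(
    gating_rule("Treg",        c("CD3", "FoxP3"),           priority = 1),
    gating_rule("mhT",         c("CD3", "CD4", "CD45RO"),   priority = 2),
    gating_rule("mcT",         c("CD3", "CD8", "CD45RO"),   priority = 3),
    gating_rule("hT",          c("CD3", "CD4"),             priority = 4),
    gating_rule("cT",          c("CD3", "CD8"),             priority = 5),
    gating_rule("tNK",         c("CD56", "CD3"),            priority = 6),
    gating_rule("aNK",         c("CD56", "GZMB"),           priority = 7),
    gating_rule("cNK",         c("CD56", "CD16"),           priority = 8),
    gating_rule("M2",          c("CD68", "CD163"),          priority = 9),
    gating_rule("M1",          c("CD68", "HLA-DR"), "CD163", priority = 10),
    gating_rule("M0",          "CD68", c("HLA-DR", "CD163"), priority = 11),
    gating_rule("mMDSC",       c("CD11b", "CD14"), "CD15",  priority = 12),
    gating_rule("pMDSC",       c("CD11b", "CD15"), "CD14",  priority = 13),
    gating_rule("ncMono",      c("CD14", "CD16"), "CD68",   priority = 14),
    gating_rule("cMono",       "CD14", c("CD16", "CD68"),   priority = 15),
    gating_rule("Neutrophil",  c("CD15", "CD16"),           priority = 16),
    gating_rule("DC",          "CD11c", c("CD3", "CD14", "CD56"), priority = 17),
    gating_rule("Endothelial", "CD31",                      priority = 18),
    gating_rule("Fibroblast",  "aSMA",                      priority = 19),
    gating_rule("Epithelial_PanCK", "Pan-CK",               priority = 20),
    gating_rule("Epithelial_Ecad",  "E-cadherin",           priority = 21),
    gating_rule("StemC",       "CD44",                      priority = 22),
    gating_rule("Proliferating", "Ki-67",                   priority = 23)
  )
  ruleset(r)
}

#' Assign one phenotype label per cell
#'
#' Tests rules in priority order; the first rule whose positive markers are
#' all 1 and negative markers all 0 wins. Cells matching no rule receive the
#' fallback label. The result is a partition: exactly one label per cell.
#'
#' @param cells a cell table (see [read_cell_table()]) with binary marker
#'   columns covering every marker a rule references
#' @param rules a `ruleset` (default [default_ruleset()])
#' @return `cells` with a `phenotype` character column appended (replaced if
#'   already present)
#' @export
assign_phenotypes <- function(cells, rules = default_ruleset()) {
  cells <- validate_cell_table(cells)
  for (r in rules$rules) {
    missing <- setdiff(c(r$positive, r$negative), names(cells))
    if (length(missing) > 0L)
      stop_osimc("rule '", r$label, "' references missing marker(s): ",
                 paste(missing, collapse = ", "))
  }
  n <- nrow(cells)
  label <- rep(NA_character_, n)
  unmatched <- rep(TRUE, n)
  for (r in rules$rules) {
    if (!any(unmatched)) break
    hit <- unmatched
    for (m in r$positive) hit <- hit & (cells[[m]] == 1L)
    for (m in r$negative) hit <- hit & (cells[[m]] == 0L)
    label[hit] <- r$label
    unmatched <- unmatched & !hit
  }
  label[unmatched] <- rules$fallback
  cells$phenotype <- label
  cells
}
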