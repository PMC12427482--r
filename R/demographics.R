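#' Summarize categorical clinical characteristics
#'
#' Builds a demographics table: for each characteristic column, category
#' counts, the common denominator (rows with a non-missing... all rows —
#' missing values are recoded to `"Unknown"`), and integer percentages
#' rounded half away from zero.
#'
#' @param tbl data.frame, one row per case
#' @param characteristics character vector of categorical column names
#' @return data.frame: characteristic, category, count, denominator, percent
#' @export
summarize_demographics <- function(tbl, characteristics = names(tbl)) {
  if (!is.data.frame(tbl) || nrow(tbl) == 0L) stop_osimc("empty table")
  missing <- setdiff(characteristics, names(tbl))
  if (length(missing) > 0L)
    stop_osimc("missing column(s): ", paste(missing, collapse = ", "))
  rows <- lapply(characteristics, function(ch) {
    v <- as.character(tbl[[ch]])
    v[is.na(v) | v == ""] <- "Unknown"
    tab <- table(v)
    data.frame(characteristic = ch, category = names(tab),
               count = as.integer(tab), denominator = length(v),
               percent = round_half_up(100 * as.integer(tab) / length(v)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Printed demographics of the 58-case osteosarcoma cohort
#'
#' The published per-characteristic category counts of the 58-case
#' osteosarcoma tissue-microarray cohort (site-of-metastasis rows use the 34
#' metastatic cases as denominator), together with the percentages as
#' printed. Some printed percentages are internally inconsistent with their
#' counts (the sex rows); use [verify_demographics()] to recompute and flag
#' them.
#'
#' @return data.frame: characteristic, category, count, denominator,
#'   reported_percent
#' @export
os_demographics <- function() {
  d <- function(ch, cat, count, denom, rep_pct)
    data.frame(characteristic = ch, category = cat, count = count,
               denominator = denom, reported_percent = rep_pct,
               stringsAsFactors = FALSE)
  rbind(
    d("age", c("<18", ">=18", "Unknown"), c(24, 30, 4), 58, c(41, 52, 7)),
    d("sex", c("Male", "Female", "Unknown"), c(27, 4, 27), 58, c(47, 6, 47)),
    d("race", c("Caucasian", "African American", "Other"), c(45, 6, 7), 58,
      c(78, 10, 12)),
    d("histology", c("Osteoblastic", "Fibroblastic", "Chondroblastic",
                     "Telangiectatic", "Other"), c(19, 18, 10, 4, 7), 58,
      c(33, 31, 17, 7, 12)),
    d("primary_site", c("Femur", "Tibia", "Other"), c(27, 12, 19), 58,
      c(47, 21, 32)),
    d("stage", c("IIA", "IIB", "III or higher", "Undetermined"),
      c(23, 20, 6, 9), 58, c(40, 34, 10, 16)),
    d("metastasis", c("Yes", "No", "Unknown"), c(30, 24, 4), 58, c(52, 41, 7)),
    d("metastasis_site", c("Lung", "Other"), c(28, 6), 34, c(82, 18)),
    d("recurrence", c("Yes", "No", "Unknown"), c(30, 23, 5), 58, c(52, 40, 8))
  )
}

#' Recompute demographic percentages and flag mismatches
#'
#' Recomputes `percent = round_half_up(100 * count / denominator)` for every
#' row and flags rows whose reported percentage disagrees — rather than
#' reproducing inconsistent printed values.
#'
#' @param demo data.frame with `count`, `denominator` and optionally a
#'   `reported_percent` column (default [os_demographics()])
#' @return `demo` with `percent` (recomputed) and, when a reported column is
#'   present, logical `mismatch`
#' @export
verify_demographics <- function(demo = os_demographics()) {
  stopifnot(all(c("count", "denominator") %in% names(demo)))
  demo$percent <- round_half_up(100 * demo$count / demo$denominator)
  if ("reported_percent" %in% names(demo))
    demo$mismatch <- demo$percent != demo$reported_percent
  demo
}
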