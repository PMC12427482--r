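#' Background-subtract a cytokine plate
#'
#' Subtracts, per analyte, the mean MFI of the plate's background rows
#' (condition `"background"`) from every measurement, flooring at 0 (MFI is
#' a non-negative physical quantity). Background rows are dropped from the
#' result.
#'
#' @param plate long-format plate: `analyte`, `condition`, `cell_line`,
#'   `replicate`, `mfi`
#' @param background_condition condition label of the background rows
#' @return background-subtracted plate without the background rows
#' @export
subtract_background <- function(plate, background_condition = "background") {
  req <- c("analyte", "condition", "cell_line", "replicate", "mfi")
  for (col in req) if (!col %in% names(plate)) stop_osimc("missing column ", col)
  is_bg <- plate$condition == background_condition
  bg <- tapply(plate$mfi[is_bg], plate$analyte[is_bg], mean)
  missing <- setdiff(unique(plate$analyte), names(bg))
  if (length(missing) > 0L)
    stop_osimc("missing background for analyte(s): ",
               paste(missing, collapse = ", "))
  out <- plate[!is_bg, , drop = FALSE]
  out$mfi <- pmax(out$mfi - unname(bg[out$analyte]), 0)
  rownames(out) <- NULL
  out
}

# Tukey-adjusted p-value for the (condition a):(line) vs (condition b):(line)
# contrast out of TukeyHSD on the interaction term.
tukey_pair_p <- function(tk, a, b, line) {
  rn <- rownames(tk)
  k1 <- paste0(a, ":", line, "-", b, ":", line)
  k2 <- paste0(b, ":", line, "-", a, ":", line)
  i <- match(k1, rn)
  if (is.na(i)) i <- match(k2, rn)
  if (is.na(i)) stop_osimc("Tukey contrast not found: ", k1)
  tk[i, "p adj"]
}

#' Differential-abundance screen across co-culture conditions
#'
#' Per analyte, fits a two-way ANOVA of MFI on culture condition and cell
#' line (with interaction) and extracts Tukey-adjusted co-culture versus
#' mono-culture contrasts within each cell line. A cell line counts as
#' significant when the co-culture differs from both mono-culture controls
#' (tumor-alone and macrophage-alone) at the adjusted alpha — or from either,
#' in `contrast = "either"` mode. An analyte is selected when at least
#' `min_lines` of the cell lines are significant (the two-of-three rule).
#'
#' @param plate background-subtracted plate with conditions `co_culture`,
#'   `mono_OS`, `mono_mac`
#' @param alpha significance level for the Tukey-adjusted contrast (default 0.05)
#' @param min_lines minimum number of significant cell lines (default 2)
#' @param contrast `"both"` (default) or `"either"` mono-culture control
#' @param log_transform analyze log1p(MFI) instead of linear MFI? The
#'   conventional analysis is on the linear scale; default FALSE.
#' @return list: `selected` (character vector of analytes), `report`
#'   (data.frame with per-line adjusted p-values, n_significant_lines,
#'   selected)
#' @export
screen_differential <- function(plate, alpha = 0.05, min_lines = 2,
                                contrast = c("both", "either"),
                                log_transform = FALSE) {
  contrast <- match.arg(contrast)
  conds <- c("co_culture", "mono_OS", "mono_mac")
  missing_cond <- setdiff(conds, unique(plate$condition))
  if (length(missing_cond) > 0L)
    stop_osimc("plate lacks condition(s): ", paste(missing_cond, collapse = ", "))
  lines <- sort(unique(plate$cell_line))
  # full factorial check
  cells <- unique(plate[, c("analyte", "condition", "cell_line")])
  want <- expand.grid(analyte = unique(plate$analyte), condition = conds,
                      cell_line = lines, stringsAsFactors = FALSE)
  have <- paste(cells$analyte, cells$condition, cells$cell_line)
  miss <- want[!paste(want$analyte, want$condition, want$cell_line) %in% have, ]
  if (nrow(miss) > 0L)
    stop_osimc("missing factorial cell(s): ",
               paste(utils::head(paste0(miss$analyte, "/", miss$condition, "/",
                                        miss$cell_line), 5L), collapse = ", "))
  rows <- lapply(split(plate, plate$analyte), function(pa) {
    y <- if (log_transform) log1p(pa$mfi) else pa$mfi
    df <- data.frame(y = y,
                     condition = factor(pa$condition, levels = conds),
                     cell_line = factor(pa$cell_line, levels = lines))
    fit <- aov(y ~ condition * cell_line, data = df)
    tk <- TukeyHSD(fit, "condition:cell_line")[["condition:cell_line"]]
    p_os  <- vapply(lines, function(l)
      tukey_pair_p(tk, "co_culture", "mono_OS", l), numeric(1))
    p_mac <- vapply(lines, function(l)
      tukey_pair_p(tk, "co_culture", "mono_mac", l), numeric(1))
    sig <- if (contrast == "both") (p_os < alpha) & (p_mac < alpha)
           else (p_os < alpha) | (p_mac < alpha)
    out <- data.frame(analyte = pa$analyte[1L], stringsAsFactors = FALSE)
    for (i in seq_along(lines)) {
      out[[paste0("p_vs_OS_", lines[i])]] <- p_os[i]
      out[[paste0("p_vs_mac_", lines[i])]] <- p_mac[i]
    }
    out$n_significant_lines <- sum(sig)
    out$selected <- sum(sig) >= min_lines
    out
  })
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  list(selected = report$analyte[report$selected], report = report,
       alpha = alpha, min_lines = min_lines, contrast = contrast)
}
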