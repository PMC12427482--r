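#' Median dichotomization of a per-case metric
#'
#' Splits cases at the cohort median of the metric: values at or below the
#' median form the "low" (abundance/density metrics) or "near" (distance
#' metrics) group, values above form "high"/"far". Ties at the median go to
#' the low/near side. Missing values are excluded and recorded in the
#' `excluded` attribute.
#'
#' @param values named numeric vector (names = case ids)
#' @param direction `"abundance"` (low/high labels) or `"distance"`
#'   (near/far labels)
#' @return named factor of group labels with attributes `cutoff` (the
#'   median) and `excluded` (case ids with missing values)
#' @export
dichotomize_at_median <- function(values, direction = c("abundance", "distance")) {
  direction <- match.arg(direction)
  if (is.null(names(values))) stop_osimc("values must be named by case id")
  excluded <- names(values)[is.na(values)]
  v <- values[!is.na(values)]
  if (length(unique(v)) < 2L)
    stop_osimc("degenerate split: fewer than 2 distinct values")
  cutoff <- median(v)
  labs <- if (direction == "abundance") c("low", "high") else c("near", "far")
  grp <- factor(ifelse(v <= cutoff, labs[1L], labs[2L]), levels = labs)
  names(grp) <- names(v)
  attr(grp, "cutoff") <- cutoff
  attr(grp, "excluded") <- excluded
  grp
}

#' Kaplan-Meier, log-rank and Cox analysis of a two-group stratification
#'
#' Product-limit survival estimates per group, a two-sided log-rank test,
#' and a univariable Cox proportional-hazards hazard ratio of the second
#' group (high/far) versus the first (low/near) with a Wald 95% CI.
#'
#' @param time numeric event/censoring times (months)
#' @param event logical event indicators
#' @param group two-level factor from [dichotomize_at_median()]
#' @return list: `logrank_p`, `hazard_ratio`, `ci` (length 2), `n_per_group`,
#'   `n_events`, `km` (a `survfit` object), `cox` (a `coxph` fit)
#' @export
km_logrank <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2L)
    stop_osimc("group with zero members: need exactly 2 non-empty groups, got ",
               nlevels(group))
  event <- as.logical(event)
  if (sum(event) == 0L) stop_osimc("no events: all subjects censored")
  s <- survival::Surv(time, event)
  sd <- survival::survdiff(s ~ group)
  logrank_p <- pchisq(sd$chisq, df = 1L, lower.tail = FALSE)
  cx <- survival::coxph(s ~ group)
  hr <- unname(exp(cx$coefficients[1L]))
  se <- sqrt(cx$var[1L, 1L])
  ci <- exp(cx$coefficients[1L] + c(-1, 1) * 1.96 * se)
  km <- survival::survfit(s ~ group)
  list(logrank_p = logrank_p, hazard_ratio = hr, ci = unname(ci),
       loghr_se = se, n_per_group = as.vector(table(group)),
       n_events = sum(event), km = km, cox = cx)
}

#' Screen per-core metrics against survival endpoints
#'
#' For each metric column and each endpoint, excludes initially metastatic
#' cases, median-dichotomizes the metric among the remaining analysis set,
#' and runs [km_logrank()]. P-values are reported unadjusted (the analysis
#' is exploratory); an optional Benjamini-Hochberg column can be appended as
#' a clearly-labeled extension.
#'
#' @param metrics data.frame with a `core_id` column and one numeric column
#'   per metric (core ids double as case ids)
#' @param clinical validated clinical table (see [validate_clinical()])
#' @param endpoints subset of `c("MFS", "RFS")`
#' @param directions named character vector giving `"abundance"` or
#'   `"distance"` per metric; metrics whose name starts with `"dist"`
#'   default to distance, all others to abundance
#' @param adjust append a BH-adjusted p-value column (`p_adj_BH`)?
#' @return data.frame: metric, endpoint, n, n_events, group labels and sizes,
#'   cutoff, logrank_p, hazard_ratio, ci_low, ci_high, status
#' @export
screen_metrics <- function(metrics, clinical, endpoints = c("MFS", "RFS"),
                           directions = NULL, adjust = FALSE) {
  clinical <- validate_clinical(clinical)
  endpoints <- match.arg(endpoints, several.ok = TRUE)
  if (!"core_id" %in% names(metrics)) stop_osimc("metrics lack core_id column")
  ids <- intersect(metrics$core_id, clinical$case_id)
  if (length(ids) == 0L) stop_osimc("no overlapping case ids")
  clinical <- clinical[match(ids, clinical$case_id), , drop = FALSE]
  metrics <- metrics[match(ids, metrics$core_id), , drop = FALSE]
  analysis <- !clinical$initial_metastasis   # localized cases only
  metric_cols <- setdiff(names(metrics), "core_id")
  metric_cols <- metric_cols[vapply(metrics[metric_cols], is.numeric, logical(1))]
  rows <- list()
  for (m in metric_cols) {
    dir <- if (!is.null(directions) && m %in% names(directions))
      directions[[m]] else if (startsWith(m, "dist")) "distance" else "abundance"
    vals <- setNames(metrics[[m]], metrics$core_id)[analysis]
    for (ep in endpoints) {
      tm <- if (ep == "MFS") clinical$met_time[analysis] else clinical$rec_time[analysis]
      ev <- if (ep == "MFS") clinical$met_event[analysis] else clinical$rec_event[analysis]
      row <- data.frame(metric = m, endpoint = ep, direction = dir,
                        n = NA_integer_, n_events = NA_integer_,
                        n_low = NA_integer_, n_high = NA_integer_,
                        cutoff = NA_real_, logrank_p = NA_real_,
                        hazard_ratio = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, status = "ok",
                        stringsAsFactors = FALSE)
      res <- tryCatch({
        grp <- dichotomize_at_median(vals, dir)
        keep <- names(vals) %in% names(grp)
        fit <- km_logrank(tm[keep], ev[keep], grp)
        row$n <- sum(keep); row$n_events <- fit$n_events
        row$n_low <- fit$n_per_group[1L]; row$n_high <- fit$n_per_group[2L]
        row$cutoff <- attr(grp, "cutoff")
        row$logrank_p <- fit$logrank_p
        row$hazard_ratio <- fit$hazard_ratio
        row$ci_low <- fit$ci[1L]; row$ci_high <- fit$ci[2L]
        row
      }, error = function(e) {
        row$status <- paste0("skipped: ",
                             if (grepl("degenerate", conditionMessage(e)))
                               "degenerate" else conditionMessage(e))
        row
      })
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- do.call(rbind, rows)
  if (adjust)
    out$p_adj_BH <- stats::p.adjust(out$logrank_p, method = "BH")
  out
}
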