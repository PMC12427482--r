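#' Run the full quantification pipeline
#'
#' Orchestrates the stages in order: QC (core-level nuclear-stain filter,
#' then marker-level filter) -> phenotyping -> abundance + IMSC composite ->
#' spatial metrics -> survival screen. Input is either a pair of files
#' (cell table TSV + clinical CSV) or a simulation block — never both. Every
#' stage writes its TSV output under `out_dir`, a structured log is kept,
#' and the returned report echoes every threshold, seed and policy actually
#' applied.
#'
#' @param config a list, or the path of a YAML file, with elements:
#'   \describe{
#'     \item{inputs}{list(cells = path, clinical = path), or}
#'     \item{simulate}{list of [cohort_config()] arguments (and optionally
#'       `survival`, a list of [survival_config()] arguments)}
#'     \item{qc}{list(min_ir191_frac, min_cells_per_core, min_case_frac)}
#'     \item{spatial}{list(radius, missing_policy, clip_area, core_diameter)}
#'     \item{survival}{list(endpoints)}
#'     \item{composite_mode}{"mean" or "sum" IMSC composite}
#'     \item{rules}{optional list of label = list(positive, negative,
#'       priority) overriding [default_ruleset()]}
#'   }
#' @param out_dir output directory (default: no files written)
#' @return report list (invisibly if `out_dir` given): per-stage outputs,
#'   applied settings, and the log lines
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  has_inputs <- !is.null(config$inputs)
  has_sim <- !is.null(config$simulate)
  if (has_inputs && has_sim)
    stop_osimc("ambiguous input: both input paths and a simulation block given")
  if (!has_inputs && !has_sim)
    stop_osimc("config needs either an inputs or a simulate block")

  log_lines <- character(0)
  note <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    log_lines <<- c(log_lines, line)
  }
  stage <- function(name, expr) {
    note("stage ", name, " start")
    tryCatch(expr, error = function(e)
      stop_osimc("stage '", name, "' failed: ", conditionMessage(e)))
  }
  emit <- function(df, file) {
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write.table(df, file.path(out_dir, file), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    }
  }

  rules <- if (!is.null(config$rules)) {
    ruleset(lapply(names(config$rules), function(lb) {
      r <- config$rules[[lb]]
      gating_rule(lb, r$positive, r$negative %||% character(), r$priority)
    }))
  } else default_ruleset()

  dat <- stage("input", {
    if (has_sim) {
      sim <- config$simulate
      surv_args <- sim$survival %||% list()
      sim$survival <- NULL
      cc <- do.call(cohort_config, sim)
      sc <- do.call(survival_config, surv_args)
      cohort <- simulate_cohort(cc, sc, rules)
      list(cells = cohort$cells, clinical = cohort$clinical,
           provenance = list(simulate = unclass(cc), survival = unclass(sc)))
    } else {
      list(cells = read_cell_table(config$inputs$cells),
           clinical = read_clinical(config$inputs$clinical),
           provenance = config$inputs)
    }
  })

  qc_cfg <- config$qc %||% list()
  qc1 <- stage("qc", core_qc(dat$cells,
                             min_ir191_frac = qc_cfg$min_ir191_frac %||% 0.25))
  if (nrow(qc1$cells) == 0L) stop_osimc("no cores passed QC")
  qc2 <- stage("qc", marker_qc(qc1$cells,
                               min_cells_per_core = qc_cfg$min_cells_per_core %||% 3,
                               min_case_frac = qc_cfg$min_case_frac %||% 0.10))
  emit(qc1$cores, "qc_cores.tsv")
  emit(qc2$markers, "qc_markers.tsv")
  note("core QC: ", sum(qc1$cores$pass), "/", nrow(qc1$cores),
       " cores retained; marker QC: ", length(qc2$retained), "/",
       nrow(qc2$markers), " markers retained")

  # drop rules whose markers did not survive marker QC
  usable <- vapply(rules$rules, function(r)
    all(c(r$positive, r$negative) %in% qc2$retained), logical(1))
  if (!all(usable))
    note("dropped rules with excluded markers: ",
         paste(vapply(rules$rules[!usable], `[[`, character(1), "label"),
               collapse = ", "))
  rules_used <- ruleset(rules$rules[usable], fallback = rules$fallback)

  labeled <- stage("phenotype", assign_phenotypes(qc1$cells, rules_used))
  emit(labeled, "cells_phenotyped.tsv")

  ab <- stage("abundance",
              abundance_matrix(labeled, labels = ruleset_labels(rules_used)))
  mode <- config$composite_mode %||% "mean"
  imsc <- stage("abundance", imsc_score(ab, mode = mode))
  emit(ab, "abundance.tsv")

  sp_cfg <- config$spatial %||% list()
  sp <- stage("spatial", spatial_metrics(
    labeled,
    radius = sp_cfg$radius %||% 250,
    missing_policy = sp_cfg$missing_policy %||% "missing",
    clip_area = sp_cfg$clip_area %||% FALSE,
    core_diameter = sp_cfg$core_diameter %||% 1000))
  emit(sp, "spatial_metrics.tsv")

  surv_res <- NULL
  if (!is.null(dat$clinical)) {
    metrics <- data.frame(core_id = ab$core_id,
                          imsc_abundance = unname(imsc),
                          stringsAsFactors = FALSE)
    metrics <- merge(metrics, sp, by = "core_id", all.x = TRUE)
    surv_res <- stage("survival", screen_metrics(
      metrics, dat$clinical,
      endpoints = config$survival$endpoints %||% c("MFS", "RFS")))
    emit(surv_res, "survival_results.tsv")
  } else {
    note("no clinical table: survival stage skipped")
  }

  report <- list(
    settings = list(
      qc = list(min_ir191_frac = qc_cfg$min_ir191_frac %||% 0.25,
                min_cells_per_core = qc_cfg$min_cells_per_core %||% 3,
                min_case_frac = qc_cfg$min_case_frac %||% 0.10),
      spatial = list(radius = sp_cfg$radius %||% 250,
                     missing_policy = sp_cfg$missing_policy %||% "missing",
                     clip_area = sp_cfg$clip_area %||% FALSE),
      composite_mode = mode,
      rules = vapply(rules_used$rules, `[[`, character(1), "label"),
      provenance = dat$provenance),
    qc_cores = qc1$cores, qc_markers = qc2$markers,
    abundance = ab, imsc_score = imsc, spatial = sp, survival = surv_res,
    log = log_lines)
  if (!is.null(out_dir)) {
    yaml::write_yaml(report$settings, file.path(out_dir, "report.yaml"))
    writeLines(log_lines, file.path(out_dir, "log.txt"))
    return(invisible(report))
  }
  report
}
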