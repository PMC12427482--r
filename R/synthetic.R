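#' Default phenotype mixture for the synthetic cohort
#'
#' Proportions chosen to resemble an osteosarcoma tumor microenvironment
#' profiled at single-cell resolution: a macrophage-dominated myeloid
#' compartment (M0 > M2 > M1), sparse lymphocytes, moderate stromal
#' populations, and a large fraction of cells that match no immune/stromal
#' gate (tumor and other cells, labeled "Unassigned").
#'
#' @return named numeric vector of proportions summing to 1
#' @export
default_phenotype_mix <- function() {
  c(M2 = 0.060, M1 = 0.020, M0 = 0.090,
    mMDSC = 0.015, pMDSC = 0.010, cMono = 0.025, ncMono = 0.010,
    Neutrophil = 0.020, DC = 0.010,
    cNK = 0.005, aNK = 0.003, tNK = 0.002,
    Treg = 0.008, hT = 0.030, cT = 0.022, mhT = 0.010, mcT = 0.010,
    Endothelial = 0.050, Fibroblast = 0.080,
    Epithelial_PanCK = 0.030, Epithelial_Ecad = 0.020,
    StemC = 0.020, Proliferating = 0.050,
    Unassigned = 0.400)
}

#' Synthetic-cohort configuration
#'
#' Parameters of the marked-point-process generator. Defaults reproduce the
#' scale of the profiled cohort: 51 cores of 1.0 mm diameter with Poisson
#' cell counts averaging 111980/51 = 2196 cells per core. Phenotypes listed
#' in `clustered_children` are placed as Gaussian-displaced children of M2
#' parents (a Thomas process) instead of being drawn from the mixture; all
#' other cells are uniform in the core disc.
#'
#' @param n_cores number of cores (default 51)
#' @param core_diameter core diameter in um (default 1000)
#' @param cells_per_core Poisson mean cell count per core (default 111980/51)
#' @param phenotype_mix named proportions summing to 1
#' @param clustering_sigma Gaussian child displacement SD in um; 0 = children
#'   coincide with their parent
#' @param clustered_children named numeric: mean children per M2 parent, per
#'   phenotype label (labels must appear in `phenotype_mix`)
#' @param marker_flip_prob independent per-marker positivity flip probability
#' @param ir191_pos_frac per-core probability of nuclear-stain (Ir191)
#'   positivity; scalar or length `n_cores`
#' @param seed RNG seed
#' @return validated config list of class `cohort_config`
#' @export
cohort_config <- function(n_cores = 51, core_diameter = 1000,
                          cells_per_core = 111980 / 51,
                          phenotype_mix = default_phenotype_mix(),
                          clustering_sigma = 0,
                          clustered_children = numeric(0),
                          marker_flip_prob = 0.02,
                          ir191_pos_frac = 0.9,
                          seed = 1L) {
  stopifnot(n_cores >= 0, core_diameter > 0, cells_per_core > 0,
            clustering_sigma >= 0,
            marker_flip_prob >= 0, marker_flip_prob <= 1,
            all(ir191_pos_frac >= 0), all(ir191_pos_frac <= 1))
  if (is.null(names(phenotype_mix)) || any(names(phenotype_mix) == ""))
    stop_osimc("phenotype_mix must be fully named")
  if (any(phenotype_mix < 0))
    stop_osimc("phenotype_mix proportions must be non-negative")
  if (abs(sum(phenotype_mix) - 1) > 1e-9)
    stop_osimc("phenotype_mix proportions must sum to 1 (got ",
               sum(phenotype_mix), ")")
  if (length(clustered_children) > 0L) {
    bad <- setdiff(names(clustered_children), names(phenotype_mix))
    if (length(bad) > 0L)
      stop_osimc("clustered_children reference phenotype(s) absent from ",
                 "phenotype_mix: ", paste(bad, collapse = ", "))
    stopifnot(all(clustered_children >= 0))
  }
  structure(list(n_cores = as.integer(n_cores), core_diameter = core_diameter,
                 cells_per_core = cells_per_core,
                 phenotype_mix = phenotype_mix,
                 clustering_sigma = clustering_sigma,
                 clustered_children = clustered_children,
                 marker_flip_prob = marker_flip_prob,
                 ir191_pos_frac = ir191_pos_frac,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Survival-generator configuration
#'
#' Proportional-hazards generator for per-core clinical outcomes: event
#' times are exponential with hazard
#' `baseline_hazard * exp(log_hr * I[covariate > median])`, censoring is
#' uniform on [0, T] with T solved numerically so the expected censored
#' fraction equals `censor_frac`. Times are in abstract months.
#'
#' @param baseline_hazard events per month in the low group (default 0.02)
#' @param log_hr log hazard ratio of the high/near group (default log(2.5))
#' @param censor_frac expected censored fraction in [0, 1) (default 0.3)
#' @param covariate_name identifier echoed into the truth record
#' @param initial_met_frac probability a case is metastatic at diagnosis
#'   (such cases are excluded from survival analysis downstream)
#' @param seed RNG seed
#' @return config list of class `survival_config`
#' @export
survival_config <- function(baseline_hazard = 0.02, log_hr = log(2.5),
                            censor_frac = 0.3, covariate_name = "imsc",
                            initial_met_frac = 0, seed = 1L) {
  stopifnot(baseline_hazard > 0, censor_frac >= 0, censor_frac < 1,
            initial_met_frac >= 0, initial_met_frac <= 1)
  structure(list(baseline_hazard = baseline_hazard, log_hr = log_hr,
                 censor_frac = censor_frac, covariate_name = covariate_name,
                 initial_met_frac = initial_met_frac, seed = as.integer(seed)),
            class = "survival_config")
}

# Uniform points in a disc of radius R centered at (cx, cy).
runif_disc <- function(n, R, cx, cy) {
  r <- R * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  cbind(x = cx + r * cos(th), y = cy + r * sin(th))
}

# Gaussian displacement of children around parent points, resampled
# (rejection) until inside the disc.
thomas_children <- function(px, py, sigma, R, cx, cy) {
  n <- length(px)
  if (n == 0L) return(cbind(x = numeric(0), y = numeric(0)))
  x <- px + rnorm(n, 0, sigma)
  y <- py + rnorm(n, 0, sigma)
  bad <- (x - cx)^2 + (y - cy)^2 > R^2
  while (any(bad)) {
    x[bad] <- px[bad] + rnorm(sum(bad), 0, sigma)
    y[bad] <- py[bad] + rnorm(sum(bad), 0, sigma)
    bad <- (x - cx)^2 + (y - cy)^2 > R^2
  }
  cbind(x = x, y = y)
}

# Binary marker truth table for a rule set: positives on, negatives off,
# unlisted markers off; the fallback label is all-zero.
marker_truth_table <- function(rules) {
  markers <- ruleset_markers(rules)
  labels <- ruleset_labels(rules, include_fallback = TRUE)
  tt <- matrix(0L, nrow = length(labels), ncol = length(markers),
               dimnames = list(labels, markers))
  for (r in rules$rules) tt[r$label, r$positive] <- 1L
  tt
}

#' Simulate a synthetic TMA cohort
#'
#' Generates cells with coordinates, true phenotypes, noisy binary marker
#' calls and nuclear-stain (Ir191) positivity for every core, plus per-core
#' clinical outcomes tied to the true IMSC fraction. Deterministic given the
#' config seed.
#'
#' @param config a [cohort_config()]
#' @param survival a [survival_config()] for the clinical outcomes, or NULL
#'   to skip outcome generation
#' @param rules the `ruleset` whose marker truth table generates calls
#' @return list of class `synthetic_cohort`: `cells` (cell table including
#'   the Ir191 column), `clinical` (clinical table or NULL), `truth` (list:
#'   config, true `phenotype` per cell, per-core true IMSC fraction)
#' @export
simulate_cohort <- function(config = cohort_config(),
                            survival = survival_config(),
                            rules = default_ruleset()) {
  stopifnot(inherits(config, "cohort_config"))
  mix_labels <- names(config$phenotype_mix)
  rule_labels <- ruleset_labels(rules, include_fallback = TRUE)
  unknown <- setdiff(mix_labels, rule_labels)
  if (length(unknown) > 0L)
    stop_osimc("phenotype_mix label(s) not in the rule set: ",
               paste(unknown, collapse = ", "))
  clustered <- names(config$clustered_children)
  base_mix <- config$phenotype_mix[setdiff(mix_labels, clustered)]
  if (sum(base_mix) <= 0) stop_osimc("phenotype_mix has no non-clustered mass")
  base_mix <- base_mix / sum(base_mix)
  R <- config$core_diameter / 2
  ir <- rep_len(config$ir191_pos_frac, max(config$n_cores, 1L))
  tt <- marker_truth_table(rules)

  with_seed(config$seed, {
    core_rows <- vector("list", config$n_cores)
    for (k in seq_len(config$n_cores)) {
      core_id <- sprintf("core_%02d", k)
      n_base <- rpois(1L, config$cells_per_core)
      lab <- if (n_base > 0L)
        sample(names(base_mix), n_base, replace = TRUE, prob = base_mix)
      else character(0)
      xy <- runif_disc(n_base, R, R, R)
      # Thomas-process children around M2 parents
      if (length(clustered) > 0L) {
        par_idx <- which(lab == "M2")
        for (cl in clustered) {
          nk <- if (length(par_idx) > 0L)
            rpois(length(par_idx), config$clustered_children[[cl]])
          else integer(0)
          tot <- sum(nk)
          if (tot > 0L) {
            pidx <- rep(par_idx, nk)
            cxy <- thomas_children(xy[pidx, 1L], xy[pidx, 2L],
                                   config$clustering_sigma, R, R, R)
            xy <- rbind(xy, cxy)
            lab <- c(lab, rep(cl, tot))
          }
        }
      }
      n <- length(lab)
      if (n == 0L) { core_rows[[k]] <- NULL; next }
      mk <- tt[lab, , drop = FALSE]
      if (config$marker_flip_prob > 0) {
        flips <- matrix(rbinom(n * ncol(mk), 1L, config$marker_flip_prob),
                        nrow = n)
        mk <- abs(mk - flips)
      }
      df <- data.frame(cell_id = sprintf("c%05d", seq_len(n)),
                       core_id = core_id, x_um = xy[, 1L], y_um = xy[, 2L],
                       stringsAsFactors = FALSE)
      df <- cbind(df, as.data.frame(mk))
      names(df)[-(1:4)] <- colnames(mk)
      df$Ir191 <- rbinom(n, 1L, ir[k])
      df$.true_phenotype <- lab
      core_rows[[k]] <- df
    }
    cells <- if (config$n_cores > 0L && length(core_rows) > 0L)
      do.call(rbind, core_rows) else NULL
    if (is.null(cells)) {
      cells <- data.frame(cell_id = character(0), core_id = character(0),
                          x_um = numeric(0), y_um = numeric(0))
      for (m in colnames(tt)) cells[[m]] <- integer(0)
      cells$Ir191 <- integer(0)
      cells$.true_phenotype <- character(0)
    }
    rownames(cells) <- NULL
    truth_phenotype <- cells$.true_phenotype
    cells$.true_phenotype <- NULL

    imsc_labels <- c("M2", "mMDSC", "pMDSC", "Treg")
    core_ids <- unique(cells$core_id)
    imsc_frac <- vapply(core_ids, function(cid) {
      lab <- truth_phenotype[cells$core_id == cid]
      mean(lab %in% imsc_labels)
    }, numeric(1))
    names(imsc_frac) <- core_ids

    clinical <- NULL
    if (!is.null(survival) && length(core_ids) >= 2L &&
        length(unique(imsc_frac)) >= 2L) {
      clinical <- simulate_survival(imsc_frac, survival)
    } else if (!is.null(survival) && length(core_ids) > 0L) {
      clinical <- simulate_survival(imsc_frac, survival, .force_null_group = TRUE)
    }

    structure(list(cells = validate_cell_table(cells), clinical = clinical,
                   truth = list(config = config, phenotype = truth_phenotype,
                                imsc_fraction = imsc_frac)),
              class = "synthetic_cohort")
  })
}

# Solve the uniform-censoring horizon T so the expected censored fraction
# over the cohort's hazards equals the target: P(C < E | h) integrated over
# C ~ U(0,T) is (1 - exp(-hT)) / (hT).
censor_horizon <- function(hazards, censor_frac) {
  f <- function(T) mean((1 - exp(-hazards * T)) / (hazards * T)) - censor_frac
  uniroot(f, lower = 1e-8, upper = 1e8, tol = 1e-10)$root
}

#' Simulate proportional-hazards clinical outcomes per core
#'
#' Event times are exponential with hazard
#' `baseline_hazard * exp(log_hr * I[covariate > median(covariate)])`;
#' censoring times are uniform on [0, T] with T solved so the expected
#' censored fraction equals `censor_frac` (no censoring when it is 0). The
#' metastasis and recurrence endpoints are generated independently with the
#' same parameters. Deterministic given the config seed.
#'
#' @param core_covariate named numeric, one value per core (names = core ids)
#' @param config a [survival_config()]
#' @param .force_null_group internal: bypass the median split (all cases in
#'   the baseline-hazard group) for degenerate covariates inside
#'   [simulate_cohort()]
#' @return clinical data.frame: case_id, initial_metastasis, met_event,
#'   met_time, rec_event, rec_time
#' @export
simulate_survival <- function(core_covariate, config = survival_config(),
                              .force_null_group = FALSE) {
  stopifnot(inherits(config, "survival_config"))
  if (is.null(names(core_covariate)))
    stop_osimc("core_covariate must be named by core id")
  if (anyNA(core_covariate)) stop_osimc("core_covariate contains NA")
  n <- length(core_covariate)
  if (!.force_null_group) {
    if (n < 2L) stop_osimc("need at least 2 cores")
    if (length(unique(core_covariate)) < 2L)
      stop_osimc("degenerate covariate: all values equal, median split undefined")
    high <- core_covariate > median(core_covariate)
  } else {
    high <- rep(FALSE, n)
  }
  h <- config$baseline_hazard * exp(config$log_hr * as.numeric(high))
  gen_endpoint <- function() {
    e_time <- rexp(n, rate = h)
    if (config$censor_frac > 0) {
      T <- censor_horizon(h, config$censor_frac)
      c_time <- runif(n, 0, T)
      list(time = pmin(e_time, c_time), event = e_time <= c_time)
    } else {
      list(time = e_time, event = rep(TRUE, n))
    }
  }
  with_seed(config$seed, {
    met <- gen_endpoint()
    rec <- gen_endpoint()
    init <- if (config$initial_met_frac > 0)
      as.logical(rbinom(n, 1L, config$initial_met_frac)) else rep(FALSE, n)
    validate_clinical(data.frame(
      case_id = names(core_covariate),
      initial_metastasis = init,
      met_event = met$event, met_time = met$time,
      rec_event = rec$event, rec_time = rec$time,
      stringsAsFactors = FALSE))
  })
}

#' The 48-analyte cytokine/chemokine panel
#'
#' Analyte names of a standard 48-plex human cytokine/chemokine bead panel.
#'
#' @return character vector of 48 analyte names
#' @export
luminex48_panel <- function() {
  c("sCD40L", "EGF", "Eotaxin", "FGF-2", "Flt-3L", "Fractalkine", "G-CSF",
    "GM-CSF", "GROa", "IFNa2", "IFNg", "IL-1a", "IL-1b", "IL-1ra", "IL-2",
    "IL-3", "IL-4", "IL-5", "IL-6", "IL-7", "IL-8", "IL-9", "IL-10",
    "IL-12p40", "IL-12p70", "IL-13", "IL-15", "IL-17A", "IL-17E", "IL-17F",
    "IL-18", "IL-22", "IL-27", "CXCL10", "MCP-1", "MCP-3", "M-CSF", "MDC",
    "MIG", "MIP-1a", "MIP-1b", "PDGF-AA", "PDGF-AB/BB", "RANTES", "TGFa",
    "TNFa", "TNFb", "VEGF-A")
}

#' Simulate a multiplex cytokine plate
#'
#' Log-normal MFI per (analyte, condition, cell line, replicate) with
#' conditions mono_OS, mono_mac and co_culture plus a background condition
#' for subtraction. The co-culture mean is shifted by the requested
#' log-fold-change per (analyte, cell line). Measurements are duplicated by
#' default.
#'
#' @param effects data.frame with columns `analyte`, `cell_line`, `lfc`
#'   (natural-log fold change of co-culture vs mono-cultures), or NULL for
#'   an all-null plate
#' @param noise_sd log-scale replicate noise SD (> 0)
#' @param n_replicates replicates per condition (>= 2)
#' @param seed RNG seed
#' @param analytes analyte names (default [luminex48_panel()], extended by
#'   any analytes named in `effects`)
#' @param cell_lines cell-line names (default the three OS lines)
#' @param baseline_log_mfi mean log MFI of culture conditions
#' @param background_log_mfi mean log MFI of the background condition
#' @return long-format plate data.frame: analyte, condition, cell_line,
#'   replicate, mfi
#' @export
simulate_cytokine_plate <- function(effects = NULL, noise_sd = 0.1,
                                    n_replicates = 2, seed = 1L,
                                    analytes = luminex48_panel(),
                                    cell_lines = c("143B", "LM7", "MG63.3"),
                                    baseline_log_mfi = log(500),
                                    background_log_mfi = log(40)) {
  if (noise_sd <= 0) stop_osimc("noise_sd must be > 0")
  if (n_replicates < 2) stop_osimc("need at least 2 replicates")
  if (!is.null(effects)) {
    stopifnot(all(c("analyte", "cell_line", "lfc") %in% names(effects)))
    analytes <- union(analytes, effects$analyte)
  }
  conds <- c("mono_OS", "mono_mac", "co_culture")
  with_seed(seed, {
    offset <- setNames(rnorm(length(analytes), 0, 0.4), analytes)
    grid <- expand.grid(analyte = analytes, condition = conds,
                        cell_line = cell_lines,
                        replicate = seq_len(n_replicates),
                        stringsAsFactors = FALSE)
    lfc <- rep(0, nrow(grid))
    if (!is.null(effects)) {
      key <- paste(grid$analyte, grid$cell_line)
      ekey <- paste(effects$analyte, effects$cell_line)
      hit <- match(key, ekey)
      lfc <- ifelse(!is.na(hit) & grid$condition == "co_culture",
                    effects$lfc[hit], 0)
    }
    mu <- baseline_log_mfi + offset[grid$analyte] + lfc
    grid$mfi <- exp(mu + rnorm(nrow(grid), 0, noise_sd))
    bg <- expand.grid(analyte = analytes, condition = "background",
                      cell_line = "none", replicate = seq_len(n_replicates),
                      stringsAsFactors = FALSE)
    bg$mfi <- exp(background_log_mfi + rnorm(nrow(bg), 0, noise_sd / 2))
    out <- rbind(grid, bg)
    rownames(out) <- NULL
    out
  })
}
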