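test_that("an empty configuration yields an empty cohort", {
  co <- simulate_cohort(cohort_config(n_cores = 0, seed = 1))
  expect_equal(nrow(co$cells), 0L)
  expect_null(co$clinical)
})

test_that("identical config and seed reproduce the cohort exactly", {
  cfg <- cohort_config(n_cores = 4, cells_per_core = 300, seed = 81,
                       clustering_sigma = 40,
                       clustered_children = c(mMDSC = 2, Treg = 1))
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$cells, b$cells)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$truth$phenotype, b$truth$phenotype)
})

test_that("all cells fall inside their core disc and cores match clinical 1:1", {
  cfg <- cohort_config(n_cores = 6, cells_per_core = 400, core_diameter = 800,
                       clustering_sigma = 100,
                       clustered_children = c(mMDSC = 3), seed = 82)
  co <- simulate_cohort(cfg)
  R <- 400
  d2 <- (co$cells$x_um - R)^2 + (co$cells$y_um - R)^2
  expect_true(all(d2 <= R^2 + 1e-9))
  expect_setequal(unique(co$cells$core_id), co$clinical$case_id)
  expect_equal(anyDuplicated(co$clinical$case_id), 0L)
})

test_that("the empirical mixture converges to the configured mixture", {
  mix <- c(M2 = 0.3, Treg = 0.1, Unassigned = 0.6)
  cfg <- cohort_config(n_cores = 10, cells_per_core = 1e4, phenotype_mix = mix,
                       marker_flip_prob = 0, seed = 83)
  co <- simulate_cohort(cfg, survival = NULL)
  n <- length(co$truth$phenotype)
  for (lb in names(mix)) {
    p_hat <- mean(co$truth$phenotype == lb)
    se <- sqrt(mix[[lb]] * (1 - mix[[lb]]) / n)
    expect_lt(abs(p_hat - mix[[lb]]), 3 * se + 1e-12)
  }
})

test_that("zero-sigma children coincide with their M2 parents", {
  cfg <- cohort_config(n_cores = 3, cells_per_core = 300, clustering_sigma = 0,
                       clustered_children = c(mMDSC = 1), marker_flip_prob = 0,
                       seed = 84)
  co <- simulate_cohort(cfg, survival = NULL)
  cells <- co$cells
  cells$phenotype <- co$truth$phenotype
  checked <- FALSE
  for (cc in split(cells, cells$core_id)) {
    kids <- which(cc$phenotype == "mMDSC")
    if (!length(kids)) next
    m2 <- cc[cc$phenotype == "M2", ]
    # every child coincides with an M2 parent
    for (i in kids) {
      dmin <- min(sqrt((m2$x_um - cc$x_um[i])^2 + (m2$y_um - cc$y_um[i])^2))
      expect_equal(dmin, 0)
    }
    # with a single parent in range the pooled median itself is 0
    if (nrow(m2) == 1L) {
      expect_equal(median_pair_distance(cc, "M2", "mMDSC", 250), 0)
      checked <- TRUE
    }
  }
  # a truly single-parent core, built directly: median is exactly 0
  solo <- cells_at(c(500, 500, 500), c(500, 500, 500),
                   c("M2", "mMDSC", "mMDSC"))
  expect_equal(median_pair_distance(solo, "M2", "mMDSC", 250), 0)
})

test_that("M2-MDSC proximity grows with the clustering bandwidth", {
  med_at <- function(sigma) {
    m <- vapply(1:20, function(s) {
      cfg <- cohort_config(n_cores = 1, cells_per_core = 300,
                           clustering_sigma = sigma,
                           clustered_children = c(mMDSC = 2),
                           marker_flip_prob = 0, seed = 8400 + s)
      co <- simulate_cohort(cfg, survival = NULL)
      cells <- co$cells
      cells$phenotype <- co$truth$phenotype
      median_pair_distance(cells, "M2", "mMDSC", 250)
    }, numeric(1))
    mean(m, na.rm = TRUE)
  }
  m <- vapply(c(0, 25, 100, 300), med_at, numeric(1))
  expect_true(all(diff(m) > 0))
})

test_that("clustered children must reference a mixture phenotype", {
  expect_error(cohort_config(clustered_children = c(Ghost = 2)),
               "absent from phenotype_mix")
})

test_that("a null hazard simulation recovers HR near 1", {
  cov <- setNames(runif(500), sprintf("k%03d", 1:500))
  clin <- simulate_survival(cov, survival_config(log_hr = 0, censor_frac = 0.3,
                                                 seed = 85))
  fit <- km_logrank(clin$met_time, clin$met_event, dichotomize_at_median(cov))
  expect_lt(abs(log(fit$hazard_ratio)), 3 * fit$loghr_se)
})

test_that("degenerate survival inputs raise the documented errors", {
  expect_error(simulate_survival(c(a = 1, b = 1, c = 1), survival_config()),
               "degenerate covariate")
  cov <- setNames(runif(20), sprintf("k%02d", 1:20))
  clin <- simulate_survival(cov, survival_config(censor_frac = 0.999, seed = 86))
  expect_error(km_logrank(clin$met_time, clin$met_event,
                          dichotomize_at_median(cov)),
               "no events")
})

test_that("the realized censoring fraction matches its target", {
  cov <- setNames(runif(2000), sprintf("k%04d", 1:2000))
  clin <- simulate_survival(cov, survival_config(censor_frac = 0.3, seed = 87))
  expect_lt(abs(mean(!clin$met_event) - 0.3), 3 * sqrt(0.3 * 0.7 / 2000))
})

test_that("the cytokine generator is reproducible and validates its inputs", {
  a <- simulate_cytokine_plate(noise_sd = 0.2, seed = 88, analytes = c("x", "y"))
  b <- simulate_cytokine_plate(noise_sd = 0.2, seed = 88, analytes = c("x", "y"))
  expect_identical(a, b)
  expect_error(simulate_cytokine_plate(noise_sd = 0), "noise_sd")
  expect_error(simulate_cytokine_plate(noise_sd = 0.1, n_replicates = 1),
               "replicates")
  expect_setequal(unique(a$condition),
                  c("mono_OS", "mono_mac", "co_culture", "background"))
})
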