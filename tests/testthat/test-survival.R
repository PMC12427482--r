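test_that("median dichotomization splits at the median with ties going low", {
  g <- dichotomize_at_median(c(a = 1, b = 2, c = 3, d = 4))
  expect_equal(attr(g, "cutoff"), 2.5)
  expect_identical(as.character(g), c("low", "low", "high", "high"))

  g2 <- dichotomize_at_median(c(a = 0, b = 0, c = 10, d = 20), "distance")
  expect_equal(attr(g2, "cutoff"), 5)
  expect_identical(as.character(g2), c("near", "near", "far", "far"))

  expect_error(dichotomize_at_median(c(a = 5, b = 5, c = 5)), "degenerate")

  g3 <- dichotomize_at_median(c(a = 1, b = NA, c = 3))
  expect_identical(attr(g3, "excluded"), "b")
})

test_that("identical groups give a null hazard ratio; no events is an error", {
  time <- rep(c(5, 10, 15, 20, 25), 2)
  event <- rep(c(TRUE, TRUE, FALSE, TRUE, FALSE), 2)
  group <- factor(rep(c("low", "high"), each = 5), levels = c("low", "high"))
  fit <- km_logrank(time, event, group)
  expect_equal(fit$hazard_ratio, 1, tolerance = 1e-6)
  expect_gt(fit$logrank_p, 0.99)
  expect_error(km_logrank(time, rep(FALSE, 10), group), "no events")
  expect_error(km_logrank(time, event, factor(rep("low", 10), levels = c("low", "high"))),
               "group")
})

test_that("the KM estimate with no censoring equals the empirical survivor", {
  set.seed(61)
  t <- rexp(40, 0.1)
  fit <- survival::survfit(survival::Surv(t, rep(TRUE, 40)) ~ 1)
  emp <- vapply(fit$time, function(x) mean(t > x), numeric(1))
  expect_equal(fit$surv, emp, tolerance = 1e-12)
})

test_that("the Cox fit recovers the generating log hazard ratio", {
  cov <- setNames(seq_len(200) + 0, sprintf("k%03d", 1:200))
  clin <- simulate_survival(cov, survival_config(log_hr = log(2.5),
                                                 censor_frac = 0.3, seed = 62))
  grp <- dichotomize_at_median(cov)
  fit <- km_logrank(clin$met_time, clin$met_event, grp)
  expect_lt(abs(log(fit$hazard_ratio) - log(2.5)), 3 * fit$loghr_se)
  expect_lt(fit$logrank_p, 0.05)
})

test_that("log-HR bias shrinks as the cohort grows", {
  bias <- vapply(c(100, 400, 1600), function(n) {
    b <- vapply(1:8, function(s) {
      cov <- setNames(seq_len(n) + 0, sprintf("k%04d", seq_len(n)))
      clin <- simulate_survival(cov, survival_config(log_hr = log(2),
                                                     censor_frac = 0.2,
                                                     seed = 63 + s))
      fit <- km_logrank(clin$met_time, clin$met_event, dichotomize_at_median(cov))
      log(fit$hazard_ratio)
    }, numeric(1))
    abs(mean(b) - log(2))
  }, numeric(1))
  expect_lt(bias[3], 0.1)
  expect_lt(bias[3], bias[1] + 0.05)
})

test_that("screen_metrics reports one row per metric and endpoint and flags degenerate splits", {
  set.seed(64)
  cov <- setNames(runif(30), sprintf("k%02d", 1:30))
  clin <- simulate_survival(cov, survival_config(seed = 65))
  metrics <- data.frame(core_id = names(cov), imsc_abundance = unname(cov),
                        dist_composite = runif(30, 0, 250),
                        flat = rep(1, 30))
  res <- screen_metrics(metrics, clin)
  expect_equal(nrow(res), 6L)
  expect_identical(res$direction[res$metric == "dist_composite"][1], "distance")
  expect_true(all(grepl("degenerate", res$status[res$metric == "flat"])))
  single <- screen_metrics(metrics[, c("core_id", "imsc_abundance")], clin)
  expect_equal(nrow(single), 2L)
})

test_that("stratification is invariant under strictly monotone metric transforms", {
  set.seed(66)
  cov <- setNames(runif(40, 1, 9), sprintf("k%02d", 1:40))
  clin <- simulate_survival(cov, survival_config(seed = 67))
  run <- function(v) {
    m <- data.frame(core_id = names(cov), metric = unname(v))
    screen_metrics(m, clin, endpoints = "MFS")
  }
  base <- run(cov)
  for (f in list(function(x) 10 * x + 3, exp, function(x) x^3)) {
    tr <- run(f(cov))
    expect_equal(tr$logrank_p, base$logrank_p, tolerance = 1e-12)
    expect_equal(tr$hazard_ratio, base$hazard_ratio, tolerance = 1e-12)
    expect_identical(tr[c("n_low", "n_high")], base[c("n_low", "n_high")])
  }
})

test_that("initially metastatic cases are excluded from the analysis set", {
  set.seed(68)
  cov <- setNames(runif(20), sprintf("k%02d", 1:20))
  clin <- simulate_survival(cov, survival_config(seed = 69))
  clin$initial_metastasis[1:5] <- TRUE
  res <- screen_metrics(data.frame(core_id = names(cov), m = unname(cov)), clin,
                        endpoints = "MFS")
  expect_equal(res$n, 15L)
})
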