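test_that("pair distances follow the geometry and the radius cutoff", {
  cells <- cells_at(c(0, 30, 0), c(0, 0, 300), c("M2", "M2", "mMDSC"))
  expect_equal(pair_distances(cells, "M2", "M2", 250), 30)
  expect_length(pair_distances(cells, "M2", "mMDSC", 250), 0)
  expect_equal(pair_distances(cells, "M2", "mMDSC", 300), 300)
})

test_that("median distance applies the empty-neighborhood policy", {
  cells <- cells_at(c(0, 10, 20, 40), c(0, 0, 0, 0),
                    c("M2", "Treg", "Treg", "Treg"))
  expect_equal(median_pair_distance(cells, "M2", "Treg", 250), 20)
  none <- cells_at(c(0), c(0), "M2")
  expect_true(is.na(median_pair_distance(none, "M2", "Treg", 250, "missing")))
  expect_equal(median_pair_distance(none, "M2", "Treg", 250, "zero"), 0)
  expect_equal(median_pair_distance(none, "M2", "Treg", 250, "radius_cap"), 250)
})

test_that("the composite proximity is the mean of the component medians", {
  expect_equal(composite_m2_imsc_distance(c(10, 20, 30)), 20)
  expect_equal(composite_m2_imsc_distance(c(0, 0, 0)), 0)
  expect_true(is.na(composite_m2_imsc_distance(c(10, NA, 30))))
})

test_that("a single center with 5 targets in radius gives 25.46 cells/mm^2", {
  cells <- cells_at(c(500, 520, 480, 500, 500, 450), c(500, 500, 500, 520, 480, 450),
                    c("M2", rep("Treg", 5)))
  expect_equal(density_around(cells, "Treg", "M2", 250), 5 / (pi * 0.25^2),
               tolerance = 1e-9)
  no_m2 <- cells_at(c(1), c(1), "Treg")
  expect_true(is.na(density_around(no_m2, "Treg", "M2", 250)))
})

test_that("summed IMSC counts add the per-population median counts", {
  # 1 M2 center at origin-ish; 3 M2, 2 MDSC, 1 Treg neighbors inside radius
  cells <- cells_at(c(500, 510, 520, 530, 540, 550, 560, 900),
                    c(500, 500, 500, 500, 500, 500, 500, 900),
                    c("M2", "M2", "M2", "M2", "mMDSC", "pMDSC", "Treg", "Treg"))
  # every M2 sees the other 3 M2s, both MDSC, one Treg (all within 250)
  expect_equal(imsc_count_sum(cells, radius = 250), 3 + 2 + 1)
  empty <- cells_at(c(0), c(0), "M2")
  expect_equal(imsc_count_sum(empty, radius = 250), 0)
})

test_that("grid index equals the all-pairs oracle on random cores", {
  set.seed(51)
  for (rep in 1:10) {
    cells <- random_core(sample(50:300, 1))
    for (tl in list("M2", c("mMDSC", "pMDSC"), "Treg")) {
      got <- sort(pair_distances(cells, "M2", tl, 250))
      want <- sort(bf_pair_distances(cells, "M2", tl, 250))
      expect_equal(got, want, tolerance = 1e-12)
    }
    expect_identical(osimc:::neighbor_counts(cells, "M2", "Treg", 250),
                     bf_neighbor_counts(cells, "M2", "Treg", 250))
  }
})

test_that("metrics are invariant under rigid motions and covariant under scaling", {
  set.seed(52)
  cells <- random_core(200)
  base <- spatial_metrics(cells, missing_policy = "missing")
  # rigid motion: rotate by 1 rad about the centroid, translate by (37, -12)
  th <- 1.0
  cx <- mean(cells$x_um); cy <- mean(cells$y_um)
  rot <- cells
  rot$x_um <- cx + cos(th) * (cells$x_um - cx) - sin(th) * (cells$y_um - cy) + 37
  rot$y_um <- cy + sin(th) * (cells$x_um - cx) + cos(th) * (cells$y_um - cy) - 12
  moved <- spatial_metrics(rot, missing_policy = "missing")
  for (col in grep("^dist", names(base), value = TRUE))
    expect_equal(moved[[col]], base[[col]], tolerance = 1e-9)
  expect_equal(moved$imsc_count_sum, base$imsc_count_sum)

  # scaling by c scales distances by c and densities by 1/c^2
  sc <- cells; sc$x_um <- 2 * cells$x_um; sc$y_um <- 2 * cells$y_um
  scaled <- spatial_metrics(sc, radius = 500)
  for (col in grep("^dist", names(base), value = TRUE))
    expect_equal(scaled[[col]], 2 * base[[col]], tolerance = 1e-9)
  for (col in grep("^density", names(base), value = TRUE))
    expect_equal(scaled[[col]], base[[col]] / 4, tolerance = 1e-9)
})

test_that("clipped-area density is unbiased for a homogeneous target field", {
  # one center per seed; targets at intensity 100 cells/mm^2 in a 1 mm core
  set.seed(53)
  n_seeds <- 50
  intensity <- 100                       # cells per mm^2
  n_target <- round(intensity * pi * 0.5^2)
  est <- vapply(seq_len(n_seeds), function(s) {
    tgt <- random_core(n_target, labels = "Treg")
    ctr <- random_core(1, labels = "M2")
    ctr$cell_id <- "m2_center"
    density_around(rbind(tgt, ctr), "Treg", "M2", 250, clip_area = TRUE,
                   core_diameter = 1000)
  }, numeric(1))
  se <- sd(est) / sqrt(n_seeds)
  expect_lt(abs(mean(est) - intensity), 3 * se + 1e-9)
})
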