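test_that("core QC excludes below 25% nuclear positivity and keeps the boundary", {
  set.seed(21)
  cells <- rbind(core_with_positivity("low", 100, "Ir191", 20),
                 core_with_positivity("edge", 100, "Ir191", 25),
                 core_with_positivity("high", 100, "Ir191", 80))
  q <- core_qc(cells)
  expect_identical(q$cores$pass[q$cores$core_id == "low"], FALSE)
  expect_identical(q$cores$pass[q$cores$core_id == "edge"], TRUE)
  # retained cells are Ir191-positive cells of retained cores
  expect_setequal(unique(q$cells$core_id), c("edge", "high"))
  expect_true(all(q$cells$Ir191 == 1L))
})

test_that("a 58-core fixture with 7 engineered failures retains 51 cores", {
  set.seed(22)
  frac <- c(runif(51, 0.30, 0.95), runif(7, 0.02, 0.20))
  cells <- do.call(rbind, lapply(seq_along(frac), function(i)
    core_with_positivity(sprintf("core_%02d", i), 100, "Ir191",
                         round(100 * frac[i]))))
  q <- core_qc(cells)
  expect_equal(nrow(q$cores), 58L)
  expect_equal(sum(q$cores$pass), 51L)
})

test_that("marker QC keeps both boundaries and drops never-expressed markers", {
  set.seed(23)
  # 10 cores; marker A positive in exactly 3 cells in exactly 1 core (10%),
  # marker B in at most 2 cells everywhere
  cores <- lapply(1:10, function(i) {
    df <- core_with_positivity(sprintf("core_%02d", i), 50, "A",
                               if (i == 1) 3L else 0L)
    df$B <- as.integer(seq_len(50) <= 2)
    df
  })
  cells <- do.call(rbind, cores)
  mq <- marker_qc(cells)
  expect_true(mq$markers$pass[mq$markers$marker == "A"])
  expect_false(mq$markers$pass[mq$markers$marker == "B"])
  expect_equal(mq$markers$positive_case_fraction[mq$markers$marker == "A"], 0.10)
})

test_that("a 33-marker fixture with 8 engineered failures retains 25", {
  set.seed(24)
  n_cores <- 20; n_per <- 60
  cores <- lapply(seq_len(n_cores), function(i) {
    df <- data.frame(cell_id = sprintf("c%03d", seq_len(n_per)),
                     core_id = sprintf("core_%02d", i),
                     x_um = runif(n_per, 0, 1000), y_um = runif(n_per, 0, 1000),
                     Ir191 = 1L, stringsAsFactors = FALSE)
    for (m in sprintf("good_%02d", 1:25)) df[[m]] <- rbinom(n_per, 1L, 0.3)
    for (m in sprintf("bad_%02d", 1:8))  df[[m]] <- as.integer(seq_len(n_per) <= 2)
    df
  })
  cells <- do.call(rbind, cores)
  mq <- marker_qc(cells)
  expect_equal(nrow(mq$markers), 33L)
  expect_equal(length(mq$retained), 25L)
  expect_true(all(startsWith(mq$retained, "good")))
})

test_that("filters are idempotent and core QC is monotone in its threshold", {
  set.seed(25)
  frac <- runif(12, 0.05, 0.95)
  cells <- do.call(rbind, lapply(seq_along(frac), function(i)
    core_with_positivity(sprintf("core_%02d", i), 80, "Ir191",
                         round(80 * frac[i]))))
  q1 <- core_qc(cells)
  q2 <- core_qc(q1$cells)
  expect_identical(q1$cells, q2$cells)

  kept <- lapply(c(0.1, 0.25, 0.5, 0.8), function(th)
    core_qc(cells, min_ir191_frac = th)$cores)
  for (i in seq_len(length(kept) - 1L)) {
    a <- kept[[i + 1]]$core_id[kept[[i + 1]]$pass]
    b <- kept[[i]]$core_id[kept[[i]]$pass]
    expect_true(all(a %in% b))
  }
})
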