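# Independent brute-force oracles and small fixture builders.

# All-pairs O(n^2) distance scan; same-label pairs unordered once, self
# excluded. Independent of the package's grid index.
bf_pair_distances <- function(cells, center_label, target_label, radius) {
  ci <- which(cells$phenotype %in% center_label)
  ti <- which(cells$phenotype %in% target_label)
  out <- numeric(0)
  same <- setequal(center_label, target_label)
  for (i in ci) {
    for (j in ti) {
      if (i == j) next
      if (same && j <= i) next
      d <- sqrt((cells$x_um[i] - cells$x_um[j])^2 +
                (cells$y_um[i] - cells$y_um[j])^2)
      if (d <= radius) out <- c(out, d)
    }
  }
  out
}

# Per-center target counts within radius, brute force.
bf_neighbor_counts <- function(cells, center_label, target_label, radius) {
  ci <- which(cells$phenotype %in% center_label)
  ti <- which(cells$phenotype %in% target_label)
  vapply(ci, function(i) {
    sum(vapply(setdiff(ti, i), function(j)
      sqrt((cells$x_um[i] - cells$x_um[j])^2 +
           (cells$y_um[i] - cells$y_um[j])^2) <= radius, logical(1)))
  }, integer(1))
}

# Naive priority-scan gating: per cell, walk rules in priority order.
bf_assign <- function(cells, rules) {
  ord <- rules$rules[order(vapply(rules$rules, `[[`, integer(1), "priority"))]
  vapply(seq_len(nrow(cells)), function(i) {
    for (r in ord) {
      ok <- all(cells[i, r$positive] == 1L) && all(cells[i, r$negative] == 0L)
      if (ok) return(r$label)
    }
    rules$fallback
  }, character(1))
}

# Random labeled core: n cells uniform in a disc of the given diameter.
random_core <- function(n, labels = c("M2", "mMDSC", "pMDSC", "Treg", "Other"),
                        diameter = 1000, core_id = "core_01") {
  r <- diameter / 2 * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  data.frame(cell_id = sprintf("c%04d", seq_len(n)), core_id = core_id,
             x_um = diameter / 2 + r * cos(th),
             y_um = diameter / 2 + r * sin(th),
             phenotype = sample(labels, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# Random binary marker table over the default ruleset's markers.
random_marker_table <- function(n, p = 0.2) {
  markers <- ruleset_markers(default_ruleset())
  df <- data.frame(cell_id = sprintf("c%04d", seq_len(n)), core_id = "core_01",
                   x_um = runif(n, 0, 1000), y_um = runif(n, 0, 1000),
                   stringsAsFactors = FALSE)
  for (m in markers) df[[m]] <- rbinom(n, 1L, p)
  df
}

# Minimal labeled cell table from explicit coordinates and labels.
cells_at <- function(x, y, phenotype, core_id = "core_01") {
  data.frame(cell_id = sprintf("c%03d", seq_along(x)), core_id = core_id,
             x_um = x, y_um = y, phenotype = phenotype,
             stringsAsFactors = FALSE)
}

# A core of n cells with exactly k positive for the given marker (plus an
# always-on Ir191 column unless the marker IS Ir191).
core_with_positivity <- function(core_id, n, marker, k) {
  df <- data.frame(cell_id = sprintf("c%04d", seq_len(n)), core_id = core_id,
                   x_um = runif(n, 0, 1000), y_um = runif(n, 0, 1000),
                   stringsAsFactors = FALSE)
  df[[marker]] <- as.integer(seq_len(n) <= k)
  if (marker != "Ir191") df$Ir191 <- 1L
  df
}
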