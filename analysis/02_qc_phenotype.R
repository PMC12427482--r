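#!/usr/bin/env Rscript
# Stage 2 — quality control, phenotyping, abundance.
#
# Core filter: cores with < 25% Ir191+ (nuclear stain) cells are dropped and
# downstream analysis is restricted to Ir191+ cells of retained cores.
# Marker filter: a case is positive for a marker if >= 3 of its cells stain
# positive; markers positive in < 10% of cases are dropped. Cells are then
# gated to one phenotype each and per-core abundances (% of detectable
# cells) and the IMSC composite (mean of M2, MDSC, Treg percentages) follow.

library(osimc)

cells <- read_cell_table("scratch/cohort/cells.tsv")

qc1 <- core_qc(cells)
cat(sprintf("core QC: %d/%d cores retained (Ir191+ fraction >= 0.25)\n",
            sum(qc1$cores$pass), nrow(qc1$cores)))
qc2 <- marker_qc(qc1$cells)
cat(sprintf("marker QC: %d/%d markers retained\n",
            length(qc2$retained), nrow(qc2$markers)))

write.table(qc1$cores, "results/qc_cores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(qc2$markers, "results/qc_markers.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

labeled <- assign_phenotypes(qc1$cells)
write_cell_table(labeled, "scratch/cohort/cells_phenotyped.tsv")

ab <- abundance_matrix(labeled, labels = ruleset_labels(default_ruleset()))
imsc <- imsc_score(ab)
ab$imsc_score <- unname(imsc)
write.table(ab, "results/abundance.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

top <- sort(colMeans(ab[, setdiff(names(ab), c("core_id", "imsc_score"))]),
            decreasing = TRUE)
cat("mean abundance, top phenotypes (% of detectable cells):\n")
print(round(head(top, 8), 2))
cat(sprintf("IMSC composite: median %.2f (IQR %.2f-%.2f)\n",
            median(imsc), quantile(imsc, 0.25), quantile(imsc, 0.75)))
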