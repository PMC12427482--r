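#!/usr/bin/env Rscript
# Stage 4 — survival stratification.
#
# Initially metastatic cases are excluded; each per-core metric (IMSC
# abundance composite, spatial proximity and density metrics) is
# median-dichotomized among the remaining localized cases (high/low for
# abundances and densities, near/far for distances) and tested against
# metastasis-free and recurrence-free survival with Kaplan-Meier, log-rank
# and a univariable Cox hazard ratio. P-values are unadjusted: the screen
# is exploratory.

library(osimc)

ab <- read.delim("results/abundance.tsv")
sp <- read.delim("results/spatial_metrics.tsv")
clinical <- read_clinical("scratch/cohort/clinical.csv")

metrics <- merge(ab[, c("core_id", "imsc_score")], sp, by = "core_id")
res <- screen_metrics(metrics, clinical)
write.table(res, "results/survival_screen.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("screened %d metric x endpoint combinations on %d localized cases\n",
            nrow(res), max(res$n, na.rm = TRUE)))
ok <- res[res$status == "ok", ]
ok <- ok[order(ok$logrank_p), ]
cat("strongest associations:\n")
print(head(ok[, c("metric", "endpoint", "n", "logrank_p", "hazard_ratio",
                  "ci_low", "ci_high")], 5), row.names = FALSE, digits = 3)
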