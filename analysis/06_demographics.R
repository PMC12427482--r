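#!/usr/bin/env Rscript
# Stage 6 — cohort demographics table.
#
# Recomputes integer percentages (half away from zero) from the published
# 58-case cohort category counts and flags rows whose printed percentage
# disagrees with its count.

library(osimc)

demo <- verify_demographics(os_demographics())
write.table(demo, "results/demographics.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("%d rows over %d characteristics; %d printed percentage(s) disagree with their counts:\n",
            nrow(demo), length(unique(demo$characteristic)),
            sum(demo$mismatch)))
print(demo[demo$mismatch, c("characteristic", "category", "count",
                            "denominator", "reported_percent", "percent")],
      row.names = FALSE)
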