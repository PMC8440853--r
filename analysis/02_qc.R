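#!/usr/bin/env Rscript

# Stage 2: genotype quality control.
#
# Reads the cohort PED/MAP, applies the standard array-QC filters (SNP and
# individual call rate >= 0.9, MAF > 0.01, autosomes only) and reports
# marker-panel descriptive statistics (mean MAF, observed and expected
# heterozygosity).

library(rohscan)

gm <- read_plink_text("results/sim/cohort.ped", "results/sim/cohort.map")
res <- qc_filter(gm, qc_thresholds())
print(res$report)

af <- allele_frequencies(res$genotypes)
het <- heterozygosity(res$genotypes)
message(sprintf("post-QC mean MAF: %.3f; Ho: %.3f; He: %.3f",
                mean(af$maf), het$ho_mean, het$he_mean))

dir.create("results/qc", showWarnings = FALSE, recursive = TRUE)
write_plink_text(res$genotypes, "results/qc/cohort_qc")
rep <- unclass(res$report)
write.table(data.frame(metric = names(rep)[1:8], value = unlist(rep[1:8])),
            "results/qc/qc_report.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
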