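#!/usr/bin/env Rscript

# Stage 4: genomic inbreeding coefficients.
#
# F_ROH per length class and in total (ROH length over the SNP-covered
# autosomal length) and F_HOM (excess homozygosity), with their pairwise
# Pearson correlations, and a check of F_ROH against the generator's
# planted autozygous fractions.

library(rohscan)

gm <- read_plink_text("results/qc/cohort_qc.ped", "results/qc/cohort_qc.map")
segs <- classify_segments(read.delim("results/roh/roh_segments.tsv",
                                     colClasses = c(chrom = "character")))
tab <- inbreeding_table(gm, segs)
corr <- pearson_correlations(tab)

message(sprintf("mean F_ROH_total: %.3f (range %.3f-%.3f)",
                mean(tab$f_roh_total), min(tab$f_roh_total),
                max(tab$f_roh_total)))
message(sprintf("mean F_HOM: %.3f (range %.3f-%.3f)", mean(tab$f_hom),
                min(tab$f_hom), max(tab$f_hom)))
message(sprintf("r(F_ROH_total, F_HOM) = %.2f; r(F_ROH_total, F_ROH>10) = %.2f",
                corr["f_roh_total", "f_hom"],
                corr["f_roh_total", "f_roh_gt10"]))

truth <- read.delim("results/sim/cohort.truth_tracts.tsv",
                    colClasses = c(chrom = "character"))
true_f <- tapply(truth$end_bp - truth$start_bp + 1, truth$sample_id, sum)
genome_bp <- sum(l_auto(read_plink_text("results/sim/cohort.ped",
                                        "results/sim/cohort.map"))$per_chrom$span_bp)
tf <- rep(0, nrow(tab)); names(tf) <- tab$sample_id
tf[names(true_f)] <- true_f / genome_bp
message(sprintf("recovery: mean F_ROH - mean truth = %+.4f; r = %.3f",
                mean(tab$f_roh_total) - mean(tf),
                cor(tab$f_roh_total, tf)))

dir.create("results/inbreeding", showWarnings = FALSE, recursive = TRUE)
write.table(tab, "results/inbreeding/inbreeding.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(round(corr, 4), "results/inbreeding/inbreeding_correlations.tsv",
            sep = "\t", quote = FALSE)
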