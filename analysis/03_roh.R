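#!/usr/bin/env Rscript

# Stage 3: ROH detection and length-class summaries.
#
# Sliding-window scan (50-SNP windows, <=1 het, <=5 missing per window, 5%
# window-hit threshold) followed by the segment criteria: >=1 Mb, >=50
# SNPs, <=100 kb/SNP. Segments are classified into 1-5 / 5-10 / >10 Mb and
# summarized per class, individual and chromosome.

library(rohscan)

gm <- read_plink_text("results/qc/cohort_qc.ped", "results/qc/cohort_qc.map")
segs <- classify_segments(detect_roh(gm, roh_params()))
sm <- summarize_roh(segs, gm)

message(sprintf("detected %d ROH segments in %d individuals (%.2f per animal)",
                nrow(segs), n_samples(gm), nrow(segs) / n_samples(gm)))
message(sprintf("mean segment length: %.2f Mb; longest: %.2f Mb on SSC%s",
                sm$mean_length_mb, max(segs$length_bp) / 1e6,
                segs$chrom[which.max(segs$length_bp)]))
t1 <- render_table1(sm$per_class)
print(t1)
cov <- sm$per_chromosome
message(sprintf("highest ROH coverage on SSC%s (%.2f%%), lowest on SSC%s (%.2f%%)",
                cov$chrom[which.max(cov$coverage_fraction)],
                100 * max(cov$coverage_fraction),
                cov$chrom[which.min(cov$coverage_fraction)],
                100 * min(cov$coverage_fraction)))

dir.create("results/roh", showWarnings = FALSE, recursive = TRUE)
write.table(segs, "results/roh/roh_segments.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(t1, "results/roh/table1.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(sm$per_chromosome, "results/roh/roh_per_chromosome.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sm$per_individual, "results/roh/roh_per_individual.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
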