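#!/usr/bin/env Rscript

# Stage 5: ROH islands.
#
# Per-SNP ROH incidence across individuals, top-1% threshold (ties
# included), merging of consecutive qualifying SNPs into islands, and a
# check that the planted shared region on chromosome 11 is recovered as
# the top island.

library(rohscan)

gm <- read_plink_text("results/qc/cohort_qc.ped", "results/qc/cohort_qc.map")
segs <- read.delim("results/roh/roh_segments.tsv",
                   colClasses = c(chrom = "character"))
inc <- snp_incidence(segs, gm$variants, n_samples(gm))
thr <- island_threshold(inc, top_fraction = 0.01)
islands <- merge_islands(inc, thr, min_island_snps = 2)

peak <- inc[which.max(inc$fraction), ]
message(sprintf("most frequent SNP in ROH: %s at %.1f Mb on SSC%s (%d occurrences, %.2f%%)",
                peak$id, peak$pos_bp / 1e6, peak$chrom, peak$n_in_roh,
                100 * peak$fraction))
message(sprintf("top-1%% incidence threshold: %.2f%%; %d islands found",
                100 * thr, nrow(islands)))
print(render_table2(islands))
top <- islands[which.max(islands$peak_fraction), ]
message(sprintf("top island: SSC%s %.1f-%.1f Mb (planted region: SSC11 34.0-37.2 Mb)",
                top$chrom, top$start_bp / 1e6, top$end_bp / 1e6))

dir.create("results/islands", showWarnings = FALSE, recursive = TRUE)
write.table(inc, "results/islands/snp_incidence.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(render_table2(islands), "results/islands/islands.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
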