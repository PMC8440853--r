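#!/usr/bin/env Rscript

# Stage 6: linkage-disequilibrium decay.
#
# Pairwise genotype-correlation r2 within chromosomes (pairs up to 1,000
# kb apart), averaged in 100-kb distance bins; LD extent at r2 = 0.3 and
# 0.2 and the SNP-panel sizes those extents imply for a 2.5 Gb genome.

library(rohscan)

gm <- read_plink_text("results/qc/cohort_qc.ped", "results/qc/cohort_qc.map")
pairs <- pairwise_r2(gm, ld_params(max_pair_kb = 1000))
bins <- bin_decay(pairs, bin_kb = 100)
s <- ld_adjacent_summary(pairs, gm)

message(sprintf("r2 over all pairs < 100 kb: %.3f +/- %.3f (n = %d)",
                s$all_pairs_lt_100kb["mean"], s$all_pairs_lt_100kb["sd"],
                s$all_pairs_lt_100kb["n"]))
message(sprintf("r2 over consecutive pairs < 100 kb: %.3f +/- %.3f (n = %d)",
                s$consecutive_lt_100kb["mean"], s$consecutive_lt_100kb["sd"],
                s$consecutive_lt_100kb["n"]))

anchor <- unname(s$consecutive_lt_100kb["mean"])
for (thr in c(0.3, 0.2)) {
  ext <- ld_extent(bins, thr, anchor_r2 = anchor)
  if (is.na(ext)) {
    message(sprintf("LD extent at r2 = %.1f: not crossed", thr))
  } else {
    message(sprintf("LD extent at r2 = %.1f: %.0f kb -> panel of >= %d SNPs for 2.5 Gb",
                    thr, ext, snp_panel_size(2.5e9, ext * 1000)))
  }
}

dir.create("results/ld", showWarnings = FALSE, recursive = TRUE)
write.table(bins, "results/ld/ld_decay.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
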