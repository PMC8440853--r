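#!/usr/bin/env Rscript

# Stage 1: build the synthetic study cohort.
#
# Emulates a composite-breed genotyping study: 262 individuals on an
# 18-autosome, 36,000-SNP map (~50 kb spacing, ~1.8 Gb), with planted
# autozygous tracts averaging ~8% of the genome, haplotype-block LD, a
# shared autozygous region on chromosome 11 (an island carried by 60% of
# individuals), light genotyping error and missingness. Ground truth is
# written alongside so later stages can be checked against it.

library(rohscan)

out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(
  n_chromosomes = 18, snps_per_chromosome = 2000, mean_spacing_bp = 50000,
  n_individuals = 262, target_f = 0.08, tract_mean_bp = 4e6,
  island_region = list(chrom = "11", start = 34e6, end = 37.2e6,
                       carrier_fraction = 0.6),
  het_error_rate = 0.005, missing_rate = 0.02, ld_block_snps = 20,
  seed = 2021)

sim <- simulate_population(cfg)
write_fixture(sim$genotypes, sim$truth, file.path(out, "cohort"))
yaml::write_yaml(unclass(cfg), file.path(out, "sim_config.yaml"))

message(sprintf("simulated %d individuals x %d SNPs on %d chromosomes (%.2f Gb)",
                n_samples(sim$genotypes), n_variants(sim$genotypes),
                cfg$n_chromosomes, sim$truth$genome_bp / 1e9))
message(sprintf("mean true autozygous fraction: %.4f (target %.2f); %d planted tracts",
                mean(sim$truth$true_fraction), cfg$target_f,
                nrow(sim$truth$tracts)))
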