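#' Configuration of the synthetic SNP-array population
#'
#' The generator emulates a medium-density (~50K) livestock array: per
#' chromosome, SNP spacings are exponential with mean `mean_spacing_bp`
#' (minimum 1 bp), giving ~100 Mb chromosomes at the defaults; allele
#' frequencies are uniform on `[maf_min, 0.5]`; background genotypes are
#' Hardy-Weinberg draws, optionally with haplotype-block structure to induce
#' decaying LD; autozygosity is modelled by planting homozygous
#' identity-by-descent tracts directly, the minimal generative model for a
#' tract-based ROH analysis.
#'
#' Per individual, the number of random tracts is Poisson with mean
#' `target_f * genome_bp / E[tract length]`, so the autozygous genome
#' fraction averages `target_f` across individuals while varying between
#' them. Tract lengths are exponential with mean `tract_mean_bp`,
#' conditioned on being at least 1 Mb (equivalently, by memorylessness,
#' 1 Mb plus an exponential of the same mean — there is no atom at the
#' minimum). An optional `island_region` forces a shared tract into a
#' stated fraction of individuals, creating a ROH island. Inside tracts a
#' single allele is drawn per SNP and doubled; `het_error_rate` then flips
#' tract genotypes to heterozygous (exercising the per-window heterozygote
#' allowance) and `missing_rate` masks genotypes genome-wide.
#'
#' @param n_chromosomes,snps_per_chromosome map dimensions.
#' @param mean_spacing_bp mean inter-SNP spacing in bp.
#' @param maf_min lower end of the uniform allele-frequency distribution.
#' @param n_individuals samples to simulate.
#' @param target_f expected autozygous genome fraction per individual.
#' @param tract_mean_bp mean of the exponential tract-length distribution in
#'   bp (lengths conditioned on >= 1 Mb).
#' @param island_region optional `list(chrom =, start =, end =,
#'   carrier_fraction =)` forcing a shared tract.
#' @param het_error_rate probability a tract genotype is rendered
#'   heterozygous.
#' @param missing_rate genome-wide missingness probability.
#' @param ld_block_snps haplotype-block size in SNPs (1 = independent SNPs).
#' @param n_founder_haplotypes founder haplotypes per block when
#'   `ld_block_snps > 1`; a small pool mimics the strong LD of livestock
#'   populations.
#' @param seed mandatory RNG seed; all randomness flows from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_chromosomes = 18,
                       snps_per_chromosome = 2000,
                       mean_spacing_bp = 50000,
                       maf_min = 0.05,
                       n_individuals = 200,
                       target_f = 0.1,
                       tract_mean_bp = 4e6,
                       island_region = NULL,
                       het_error_rate = 0,
                       missing_rate = 0,
                       ld_block_snps = 1,
                       n_founder_haplotypes = 8,
                       seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  stopifnot(n_chromosomes >= 1, snps_per_chromosome >= 1,
            mean_spacing_bp >= 1, maf_min >= 0, maf_min <= 0.5,
            n_individuals >= 1, target_f >= 0, target_f <= 1,
            tract_mean_bp >= 1e6, het_error_rate >= 0, het_error_rate <= 1,
            missing_rate >= 0, missing_rate <= 1, ld_block_snps >= 1,
            n_founder_haplotypes >= 2)
  if (!is.null(island_region)) {
    stopifnot(all(c("chrom", "start", "end", "carrier_fraction") %in%
                    names(island_region)),
              island_region$carrier_fraction >= 0,
              island_region$carrier_fraction <= 1,
              island_region$end > island_region$start)
  }
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 snps_per_chromosome = as.integer(snps_per_chromosome),
                 mean_spacing_bp = mean_spacing_bp, maf_min = maf_min,
                 n_individuals = as.integer(n_individuals),
                 target_f = target_f, tract_mean_bp = tract_mean_bp,
                 island_region = island_region,
                 het_error_rate = het_error_rate,
                 missing_rate = missing_rate,
                 ld_block_snps = as.integer(ld_block_snps),
                 n_founder_haplotypes = as.integer(n_founder_haplotypes),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Map generation from the current RNG stream (no reseeding) so that
# simulate_map() and simulate_population() agree on the map.
.sim_map_draw <- function(cfg) {
  rows <- lapply(seq_len(cfg$n_chromosomes), function(ch) {
    sp <- pmax(1, round(stats::rexp(cfg$snps_per_chromosome,
                                    rate = 1 / cfg$mean_spacing_bp)))
    pos <- cumsum(sp)
    data.frame(chrom = as.character(ch),
               id = sprintf("snp_%02d_%05d", ch,
                            seq_len(cfg$snps_per_chromosome)),
               pos_bp = pos, allele_a = "A", allele_b = "B",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate the SNP map
#'
#' Positions are 1-based cumulative sums of exponential spacings per
#' chromosome; deterministic under the config seed.
#'
#' @param cfg a [sim_config()].
#' @return variant data.frame as in [genotype_matrix()].
#' @export
simulate_map <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  .sim_map_draw(cfg)
}

#' Simulate a genotyped population with planted autozygosity
#'
#' See [sim_config()] for the generative model. All draws come from a
#' single generator seeded once, so identical configs give identical output.
#'
#' @param cfg a [sim_config()].
#' @return list with `genotypes` (a [genotype_matrix()]) and `truth` (class
#'   `sim_truth`: `tracts` data.frame (`sample_id`, `chrom`, `start_bp`,
#'   `end_bp`), per-individual `true_fraction`, per-SNP `true_freq`, and
#'   `genome_bp`).
#' @export
simulate_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  variants <- .sim_map_draw(cfg)
  m <- nrow(variants)
  n <- cfg$n_individuals
  p <- stats::runif(m, cfg$maf_min, 0.5)
  chrom_ends <- tapply(variants$pos_bp, variants$chrom, max)
  chrom_labels <- as.character(seq_len(cfg$n_chromosomes))
  chrom_ends <- chrom_ends[chrom_labels]
  genome_bp <- sum(chrom_ends)

  # background genotypes
  if (cfg$ld_block_snps == 1L) {
    dosage <- matrix(stats::rbinom(n * m, 2L, rep(p, each = n)), n, m)
  } else {
    dosage <- matrix(0L, n, m)
    for (ch in chrom_labels) {
      vidx <- which(variants$chrom == ch)
      blocks <- split(vidx, ceiling(seq_along(vidx) / cfg$ld_block_snps))
      for (blk in blocks) {
        H <- cfg$n_founder_haplotypes
        founders <- matrix(stats::rbinom(H * length(blk), 1L,
                                         rep(p[blk], each = H)), H, length(blk))
        h1 <- sample.int(H, n, replace = TRUE)
        h2 <- sample.int(H, n, replace = TRUE)
        dosage[, blk] <- founders[h1, , drop = FALSE] +
          founders[h2, , drop = FALSE]
      }
    }
  }

  # plant autozygous tracts: forced island tracts first, then random tracts
  # up to the per-individual expected autozygous fraction. Tract lengths are
  # exponential conditioned on >= 1 Mb; by memorylessness that is
  # 1 Mb + exp(tract_mean_bp), with no atom at the minimum.
  mean_tract <- 1e6 + cfg$tract_mean_bp
  tract_rows <- list()
  tracts_by_ind <- replicate(n, NULL, simplify = FALSE)
  carriers <- integer()
  if (!is.null(cfg$island_region)) {
    ir <- cfg$island_region
    n_carriers <- round(ir$carrier_fraction * n)
    carriers <- sort(sample.int(n, n_carriers))
    for (i in carriers) {
      tracts_by_ind[[i]] <- rbind(tracts_by_ind[[i]],
                                  c(as.numeric(ir$chrom), ir$start, ir$end))
    }
  }
  target_bp <- cfg$target_f * genome_bp
  if (cfg$target_f >= 1) {
    # fully autozygous genome: one tract per chromosome, no random placement
    full <- cbind(seq_len(cfg$n_chromosomes), 1, chrom_ends)
    for (i in seq_len(n)) tracts_by_ind[[i]] <- full
  } else for (i in seq_len(n)) {
    have <- if (is.null(tracts_by_ind[[i]])) 0 else
      sum(tracts_by_ind[[i]][, 3] - tracts_by_ind[[i]][, 2] + 1)
    lambda <- max(0, target_bp - have) / mean_tract
    n_tracts <- stats::rpois(1, lambda)
    for (k in seq_len(n_tracts)) {
      len <- 1e6 + stats::rexp(1, rate = 1 / cfg$tract_mean_bp)
      ch <- sample.int(cfg$n_chromosomes, 1, prob = chrom_ends)
      if (len >= chrom_ends[ch]) {
        warning("tract longer than chromosome ", ch, "; truncated")
        cand <- c(ch, 1, chrom_ends[ch])
        placed <- TRUE
      } else {
        placed <- FALSE
        for (try in 1:25) {
          start <- floor(stats::runif(1, 1, chrom_ends[ch] - len + 1))
          cand <- c(ch, start, start + len - 1)
          ex <- tracts_by_ind[[i]]
          overlap <- !is.null(ex) &&
            any(ex[, 1] == ch & ex[, 2] <= cand[3] & ex[, 3] >= cand[2])
          if (!overlap) { placed <- TRUE; break }
        }
      }
      if (placed) tracts_by_ind[[i]] <- rbind(tracts_by_ind[[i]], cand)
    }
  }

  # apply tract homozygosity, then heterozygote error inside tracts
  true_fraction <- numeric(n)
  for (i in seq_len(n)) {
    tr <- tracts_by_ind[[i]]
    if (is.null(tr)) next
    true_fraction[i] <- sum(tr[, 3] - tr[, 2] + 1) / genome_bp
    for (k in seq_len(nrow(tr))) {
      ch <- as.character(tr[k, 1])
      tract_rows[[length(tract_rows) + 1L]] <- data.frame(
        sample_id = sprintf("ind_%03d", i), chrom = ch,
        start_bp = tr[k, 2], end_bp = tr[k, 3], stringsAsFactors = FALSE)
      vidx <- which(variants$chrom == ch & variants$pos_bp >= tr[k, 2] &
                      variants$pos_bp <= tr[k, 3])
      if (!length(vidx)) next
      hap <- stats::rbinom(length(vidx), 1L, p[vidx])
      g <- 2L * hap
      if (cfg$het_error_rate > 0) {
        flip <- stats::runif(length(vidx)) < cfg$het_error_rate
        g[flip] <- 1L
      }
      dosage[i, vidx] <- g
    }
  }

  if (cfg$missing_rate > 0) {
    dosage[stats::runif(n * m) < cfg$missing_rate] <- NA_integer_
  }

  samples <- sprintf("ind_%03d", seq_len(n))
  gm <- genotype_matrix(variants, samples, dosage)
  tracts <- if (length(tract_rows)) do.call(rbind, tract_rows) else
    data.frame(sample_id = character(), chrom = character(),
               start_bp = numeric(), end_bp = numeric(),
               stringsAsFactors = FALSE)
  truth <- structure(list(tracts = tracts,
                          true_fraction = stats::setNames(true_fraction, samples),
                          true_freq = stats::setNames(p, variants$id),
                          island_carriers = samples[carriers],
                          genome_bp = genome_bp),
                     class = "sim_truth")
  list(genotypes = gm, truth = truth)
}

#' Write a simulated fixture to disk
#'
#' Writes the PED/MAP pair plus `"<prefix>.truth_tracts.tsv"` and
#' `"<prefix>.truth_freqs.tsv"`. Re-reading the PED/MAP with
#' [read_plink_text()] reproduces the genotype matrix exactly; a fixed seed
#' gives byte-identical files.
#'
#' @param gm a [genotype_matrix()] from [simulate_population()].
#' @param truth the matching `sim_truth`.
#' @param prefix output path prefix.
#' @return invisibly, the file paths.
#' @export
write_fixture <- function(gm, truth, prefix) {
  paths <- write_plink_text(gm, prefix)
  tr_path <- paste0(prefix, ".truth_tracts.tsv")
  fq_path <- paste0(prefix, ".truth_freqs.tsv")
  utils::write.table(truth$tracts, tr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(id = names(truth$true_freq),
                                freq_b = unname(truth$true_freq)),
                     fq_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, truth_tracts = tr_path, truth_freqs = fq_path))
}
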