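#' QC thresholds for SNP-array genotypes
#'
#' Defaults follow standard array QC for livestock panels: SNP and sample
#' call rate at least 0.9 (a rate of exactly 0.9 is retained), minor allele
#' frequency strictly greater than 0.01 (a MAF of exactly 0.01 is removed),
#' autosomal SNPs only (pig: chromosomes 1-18).
#'
#' @param min_snp_call_rate,min_sample_call_rate minimum call-rate fractions
#'   (inclusive bounds).
#' @param min_maf strict lower bound on minor allele frequency.
#' @param autosomes_only drop SNPs whose chromosome label is not in
#'   `autosomes`.
#' @param autosomes character vector of autosome labels.
#' @return a `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_snp_call_rate = 0.9,
                          min_sample_call_rate = 0.9,
                          min_maf = 0.01,
                          autosomes_only = TRUE,
                          autosomes = autosome_labels(18)) {
  stopifnot(min_snp_call_rate >= 0, min_snp_call_rate <= 1,
            min_sample_call_rate >= 0, min_sample_call_rate <= 1,
            min_maf >= 0, min_maf <= 1)
  structure(list(min_snp_call_rate = min_snp_call_rate,
                 min_sample_call_rate = min_sample_call_rate,
                 min_maf = min_maf,
                 autosomes_only = isTRUE(autosomes_only),
                 autosomes = as.character(autosomes)),
            class = "qc_thresholds")
}

#' Per-variant allele frequency, MAF and call rate
#'
#' @param gm a [genotype_matrix()].
#' @return data.frame with one row per variant: `chrom`, `id`, `pos_bp`,
#'   `n_obs` (non-missing genotypes), `freq_b` (frequency of `allele_b`),
#'   `maf = min(freq_b, 1 - freq_b)` and `call_rate`. A SNP with all
#'   genotypes missing has `freq_b`/`maf` `NA` and call rate 0.
#' @export
allele_frequencies <- function(gm) {
  d <- gm$dosage
  n_obs <- colSums(!is.na(d))
  s <- colSums(d, na.rm = TRUE)
  freq_b <- ifelse(n_obs > 0, s / (2 * n_obs), NA_real_)
  data.frame(chrom = gm$variants$chrom, id = gm$variants$id,
             pos_bp = gm$variants$pos_bp, n_obs = n_obs,
             freq_b = freq_b, maf = pmin(freq_b, 1 - freq_b),
             call_rate = if (nrow(d)) n_obs / nrow(d) else rep(0, ncol(d)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Observed and expected heterozygosity
#'
#' Per SNP, observed heterozygosity Ho is the fraction of non-missing
#' genotypes that are heterozygous, and expected heterozygosity He is the
#' Hardy-Weinberg value `2 p (1 - p)` with `p` the sample allele frequency
#' (no small-sample correction; the `2N/(2N-1)` correction is reserved for
#' the expected-homozygosity term of F_HOM, see [f_hom()]). SNPs with all
#' genotypes missing are excluded from both averages.
#'
#' @param gm a [genotype_matrix()].
#' @return list with per-SNP vectors `ho` and `he` and scalar means
#'   `ho_mean`, `he_mean` (averaged over SNPs).
#' @export
heterozygosity <- function(gm) {
  d <- gm$dosage
  n_obs <- colSums(!is.na(d))
  ho <- ifelse(n_obs > 0, colSums(d == 1L, na.rm = TRUE) / n_obs, NA_real_)
  af <- allele_frequencies(gm)
  he <- 2 * af$freq_b * (1 - af$freq_b)
  keep <- n_obs > 0
  list(ho = ho, he = he,
       ho_mean = if (any(keep)) mean(ho[keep]) else NA_real_,
       he_mean = if (any(keep)) mean(he[keep]) else NA_real_)
}

#' Quality-control filter for a genotype matrix
#'
#' Filters are applied in the conventional array-QC order, recorded in the
#' returned report: (1) drop non-autosomal SNPs; (2) drop samples with call
#' rate below `min_sample_call_rate`; (3) drop SNPs with call rate (on the
#' retained samples) below `min_snp_call_rate`; (4) drop SNPs with
#' `maf <= min_maf` (strict inequality, recomputed on retained samples).
#'
#' @param gm a [genotype_matrix()].
#' @param thresholds a [qc_thresholds()].
#' @return list with elements `genotypes` (filtered [genotype_matrix()]) and
#'   `report` (class `qc_report`: removal counts per step plus retained
#'   dimensions and the filter order).
#' @export
qc_filter <- function(gm, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  n0 <- n_samples(gm)
  m0 <- n_variants(gm)

  if (thresholds$autosomes_only) {
    keep_v <- gm$variants$chrom %in% thresholds$autosomes
  } else {
    keep_v <- rep(TRUE, m0)
  }
  n_nonauto <- sum(!keep_v)
  gm1 <- subset_genotypes(gm, variants = which(keep_v))

  cr_sample <- if (n_variants(gm1)) rowMeans(!is.na(gm1$dosage)) else
    rep(0, n_samples(gm1))
  keep_s <- cr_sample >= thresholds$min_sample_call_rate
  n_samp_rm <- sum(!keep_s)
  gm2 <- subset_genotypes(gm1, samples = which(keep_s))

  cr_snp <- if (n_samples(gm2)) colMeans(!is.na(gm2$dosage)) else
    rep(0, n_variants(gm2))
  keep_cr <- cr_snp >= thresholds$min_snp_call_rate
  n_snp_cr <- sum(!keep_cr)
  gm3 <- subset_genotypes(gm2, variants = which(keep_cr))

  maf <- allele_frequencies(gm3)$maf
  keep_maf <- !is.na(maf) & maf > thresholds$min_maf
  n_snp_maf <- sum(!keep_maf)
  gm4 <- subset_genotypes(gm3, variants = which(keep_maf))

  if (n_samples(gm4) == 0 || n_variants(gm4) == 0) {
    warning("QC removed everything: ", n_samples(gm4), " samples and ",
            n_variants(gm4), " SNPs retained")
  }
  report <- structure(list(
    n_samples_input = n0,
    n_snps_input = m0,
    n_snps_removed_nonautosomal = n_nonauto,
    n_samples_removed_callrate = n_samp_rm,
    n_snps_removed_callrate = n_snp_cr,
    n_snps_removed_maf = n_snp_maf,
    n_samples_retained = n_samples(gm4),
    n_snps_retained = n_variants(gm4),
    filter_order = c("non_autosomal_snps", "sample_call_rate",
                     "snp_call_rate", "snp_maf"),
    thresholds = thresholds), class = "qc_report")
  list(genotypes = gm4, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(paste0(
    "QC report (%d samples x %d SNPs in)\n",
    "  SNPs removed, non-autosomal : %d\n",
    "  samples removed, call rate  : %d\n",
    "  SNPs removed, call rate     : %d\n",
    "  SNPs removed, MAF           : %d\n",
    "  retained: %d samples x %d SNPs\n"),
    x$n_samples_input, x$n_snps_input, x$n_snps_removed_nonautosomal,
    x$n_samples_removed_callrate, x$n_snps_removed_callrate,
    x$n_snps_removed_maf, x$n_samples_retained, x$n_snps_retained))
  invisible(x)
}
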