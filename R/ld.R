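#' Parameters for pairwise r-squared computation
#'
#' Defaults mirror the conventional whole-chromosome scan for array data:
#' pairs up to 99,999 SNPs apart and 1,000 kb apart, reporting all r-squared
#' values (no lower cutoff). `max_pair_kb` is configurable upward for decay
#' curves extending beyond 1 Mb.
#'
#' @param max_pair_snps maximum SNP-index separation of a pair.
#' @param max_pair_kb maximum physical separation in kb.
#' @param min_r2_report drop pairs with r-squared below this value.
#' @return an `ld_params` list.
#' @export
ld_params <- function(max_pair_snps = 99999, max_pair_kb = 1000,
                      min_r2_report = 0) {
  stopifnot(max_pair_snps >= 1, max_pair_kb > 0,
            min_r2_report >= 0, min_r2_report <= 1)
  structure(list(max_pair_snps = as.integer(max_pair_snps),
                 max_pair_kb = max_pair_kb, min_r2_report = min_r2_report),
            class = "ld_params")
}

#' Pairwise genotype-correlation r-squared within chromosomes
#'
#' r-squared for a SNP pair is the squared Pearson correlation of the two
#' dosage vectors over the samples non-missing at both SNPs (the composite,
#' genotype-level LD estimator; no haplotype phasing). Pairs are restricted
#' to the same chromosome, an index separation of at most `max_pair_snps`
#' and a distance of at most `max_pair_kb`. Pairs where either SNP is
#' monomorphic on the common support, or with fewer than 2 common
#' non-missing samples, are skipped and tallied in the `n_skipped`
#' attribute.
#'
#' @param gm a post-QC [genotype_matrix()].
#' @param params an [ld_params()].
#' @return data.frame with `chrom`, `id_a`, `id_b`, `dist_bp`, `r2`;
#'   attribute `n_skipped` counts undefined pairs within the constraints.
#' @export
pairwise_r2 <- function(gm, params = ld_params()) {
  out <- list()
  n_skipped <- 0L
  for (ch in chrom_levels(gm$variants$chrom)) {
    vidx <- which(gm$variants$chrom == ch)
    m <- length(vidx)
    if (m < 2) next
    D <- gm$dosage[, vidx, drop = FALSE]
    storage.mode(D) <- "double"
    C <- if (anyNA(D)) {
      suppressWarnings(stats::cor(D, use = "pairwise.complete.obs"))
    } else {
      suppressWarnings(stats::cor(D))
    }
    pos <- gm$variants$pos_bp[vidx]
    ids <- gm$variants$id[vidx]
    pr <- which(upper.tri(C), arr.ind = TRUE)
    i <- pr[, 1]; j <- pr[, 2]
    dist <- pos[j] - pos[i]
    keep <- (j - i) <= params$max_pair_snps &
      dist <= params$max_pair_kb * 1000
    i <- i[keep]; j <- j[keep]; dist <- dist[keep]
    r2 <- C[cbind(i, j)]^2
    ok <- is.finite(r2)
    n_skipped <- n_skipped + sum(!ok)
    rep_ok <- ok & r2 >= params$min_r2_report
    out[[length(out) + 1L]] <- data.frame(
      chrom = rep(ch, sum(rep_ok)), id_a = ids[i[rep_ok]],
      id_b = ids[j[rep_ok]], dist_bp = dist[rep_ok], r2 = r2[rep_ok],
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), id_a = character(), id_b = character(),
               dist_bp = numeric(), r2 = numeric(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "n_skipped") <- n_skipped
  res
}

#' Bin pairwise r-squared by physical distance
#'
#' Pairs are assigned to contiguous half-open distance bins
#' `[k * bin_kb, (k + 1) * bin_kb)` starting at 0, so a pair at exactly
#' 100,000 bp falls in the `[100, 200)` kb bin when `bin_kb = 100`.
#' Empty bins are reported with `n_pairs = 0` and `NA` mean.
#'
#' @param pairs a [pairwise_r2()] result.
#' @param bin_kb bin width in kb.
#' @return data.frame with `dist_lo_kb`, `dist_hi_kb`, `mean_r2`, `n_pairs`.
#' @export
bin_decay <- function(pairs, bin_kb = 100) {
  if (!nrow(pairs)) {
    return(data.frame(dist_lo_kb = numeric(), dist_hi_kb = numeric(),
                      mean_r2 = numeric(), n_pairs = integer()))
  }
  binw <- bin_kb * 1000
  b <- floor(pairs$dist_bp / binw)
  levels <- 0:max(b)
  n <- as.integer(table(factor(b, levels = levels)))
  means <- as.numeric(tapply(pairs$r2, factor(b, levels = levels), mean))
  data.frame(dist_lo_kb = levels * bin_kb, dist_hi_kb = (levels + 1) * bin_kb,
             mean_r2 = means, n_pairs = n, stringsAsFactors = FALSE)
}

#' Distance at which mean r-squared falls to a threshold
#'
#' Linear interpolation between the midpoints of the last distance bin with
#' mean r-squared at or above the threshold and the first bin below it. If
#' the first occupied bin is already below the threshold, the crossing is
#' interpolated from an anchor at distance 0 carrying `anchor_r2`
#' (typically the adjacent-SNP-pair mean), giving a value in
#' `(0, first midpoint]`.
#'
#' @param bins a [bin_decay()] result.
#' @param r2_threshold the r-squared level (e.g. 0.3 or 0.2).
#' @param anchor_r2 optional r-squared at distance 0 used when bin 0 is
#'   already below the threshold.
#' @return distance in kb, or `NA` (with a message) when the threshold is
#'   never crossed.
#' @export
ld_extent <- function(bins, r2_threshold, anchor_r2 = NULL) {
  occ <- bins[bins$n_pairs > 0, , drop = FALSE]
  if (!nrow(occ)) stop("no occupied distance bins")
  mids <- (occ$dist_lo_kb + occ$dist_hi_kb) / 2
  means <- occ$mean_r2
  if (means[1] < r2_threshold) {
    if (is.null(anchor_r2) || anchor_r2 < r2_threshold) {
      message("mean r2 is below ", r2_threshold,
              " already in the first bin; extent undefined")
      return(NA_real_)
    }
    return((anchor_r2 - r2_threshold) / (anchor_r2 - means[1]) * mids[1])
  }
  below <- which(means < r2_threshold)
  if (!length(below)) {
    message("mean r2 never falls below ", r2_threshold, "; extent undefined")
    return(NA_real_)
  }
  fb <- below[1]
  la <- fb - 1L
  mids[la] + (means[la] - r2_threshold) / (means[la] - means[fb]) *
    (mids[fb] - mids[la])
}

#' SNPs needed to cover a genome at a given marker spacing
#'
#' `ceiling(genome_bp / spacing_bp)`: the panel size implied by requiring
#' one marker per `spacing_bp` of genome, e.g. the distance over which LD
#' stays above a target r-squared.
#'
#' @param genome_bp total genome length in bp (pig: ~2.5e9).
#' @param spacing_bp marker spacing in bp.
#' @return integer SNP count.
#' @export
snp_panel_size <- function(genome_bp, spacing_bp) {
  if (spacing_bp <= 0) stop("spacing must be positive")
  if (genome_bp <= 0) stop("genome length must be positive")
  as.integer(ceiling(genome_bp / spacing_bp))
}

#' Summary statistics of an LD scan
#'
#' Reports both readings of "adjacent SNPs within 100 kb": the mean and SD
#' of r-squared over all pairs closer than 100 kb, and over strictly
#' consecutive SNP pairs closer than 100 kb.
#'
#' @param pairs a [pairwise_r2()] result.
#' @param gm the [genotype_matrix()] the pairs came from (to identify
#'   consecutive SNPs).
#' @return list with `all_pairs_lt_100kb` and `consecutive_lt_100kb`, each
#'   `c(mean, sd, n)`.
#' @export
ld_adjacent_summary <- function(pairs, gm) {
  close <- pairs[pairs$dist_bp < 1e5, , drop = FALSE]
  v <- gm$variants
  nxt <- c(v$id[-1], NA)
  same_chr <- c(v$chrom[-1] == v$chrom[-nrow(v)], FALSE)
  consec_key <- paste(v$id, nxt)[same_chr]
  is_consec <- paste(close$id_a, close$id_b) %in% consec_key
  cons <- close[is_consec, , drop = FALSE]
  list(all_pairs_lt_100kb = c(mean = mean(close$r2), sd = stats::sd(close$r2),
                              n = nrow(close)),
       consecutive_lt_100kb = c(mean = mean(cons$r2), sd = stats::sd(cons$r2),
                                n = nrow(cons)))
}
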