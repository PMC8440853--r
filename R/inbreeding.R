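#' Autosomal length covered by the marker panel
#'
#' L_auto is the denominator of F_ROH: the total genome length covered by
#' the retained SNPs, computed as the sum over chromosomes of the inclusive
#' span `last SNP bp - first SNP bp + 1`. An override accepting a fixed bp
#' value (e.g. a nominal chip genome size) is available through `fixed_bp`
#' for cross-study comparability.
#'
#' @param gm a post-QC, autosomes-only [genotype_matrix()].
#' @param fixed_bp optional fixed total to use instead of the SNP-span sum.
#' @return list of class `autosome_span` with `l_auto_bp` and a per-chromosome
#'   data.frame `per_chrom` (`chrom`, `span_bp`).
#' @export
l_auto <- function(gm, fixed_bp = NULL) {
  chroms <- chrom_levels(gm$variants$chrom)
  spans <- vapply(chroms, function(ch) {
    p <- gm$variants$pos_bp[gm$variants$chrom == ch]
    max(p) - min(p) + 1
  }, numeric(1))
  if (any(spans == 1)) {
    warning("chromosome(s) with a single SNP contribute 1 bp to L_auto: ",
            paste(chroms[spans == 1], collapse = ", "))
  }
  total <- if (!is.null(fixed_bp)) fixed_bp else sum(spans)
  if (length(spans) && total <= 0) stop("L_auto must be positive")
  structure(list(l_auto_bp = total,
                 per_chrom = data.frame(chrom = chroms, span_bp = spans,
                                        row.names = NULL,
                                        stringsAsFactors = FALSE)),
            class = "autosome_span")
}

#' F_ROH for one individual's segments
#'
#' `F_ROH = sum(L_ROH) / L_auto`: the summed length of the individual's ROH
#' segments (optionally restricted to one length class) divided by the
#' autosomal length covered by the panel.
#'
#' @param segments segment data.frame for one individual (classified if a
#'   class filter is used).
#' @param span an [l_auto()] result.
#' @param class_filter `"total"` or one of `"1-5"`, `"5-10"`, `">10"`.
#' @return a fraction in `[0, 1]`; 0 for an empty segment list.
#' @export
f_roh <- function(segments, span, class_filter = "total") {
  stopifnot(inherits(span, "autosome_span"))
  if (!nrow(segments)) return(0)
  if (class_filter != "total") {
    if (!"length_class" %in% names(segments)) {
      segments <- classify_segments(segments)
    }
    segments <- segments[segments$length_class == class_filter, , drop = FALSE]
  }
  sum(segments$length_bp) / span$l_auto_bp
}

#' F_HOM: excess-homozygosity inbreeding coefficient
#'
#' `F_HOM = (O - E) / (L - E)` per sample, where O is the observed number of
#' homozygous genotypes, E the number expected under Hardy-Weinberg and L
#' the number of genotyped autosomal SNPs. The expected homozygosity per SNP
#' is `1 - 2 p (1 - p) * 2N/(2N - 1)` with `p` the sample-based allele
#' frequency and `N` the non-missing sample count at that SNP (the standard
#' method-of-moments small-sample correction). By default O, E and L are
#' restricted to each sample's own non-missing SNPs so the three counts
#' share one support; `per_sample_support = FALSE` instead uses the full
#' post-QC SNP count as L (and the full-panel E) for every sample.
#'
#' @param gm a post-QC [genotype_matrix()].
#' @param per_sample_support restrict O/E/L to each sample's non-missing
#'   SNPs (default) or use the all-SNP panel.
#' @return named numeric vector of per-sample coefficients; `NA` where
#'   `L == E` (degenerate, e.g. monomorphic-only support).
#' @export
f_hom <- function(gm, per_sample_support = TRUE) {
  d <- gm$dosage
  n_obs <- colSums(!is.na(d))
  p <- ifelse(n_obs > 0, colSums(d, na.rm = TRUE) / (2 * n_obs), NA_real_)
  corr <- ifelse(n_obs > 0, (2 * n_obs) / pmax(1, 2 * n_obs - 1), NA_real_)
  exp_hom <- 1 - 2 * p * (1 - p) * corr
  hom <- !is.na(d) & d != 1L
  out <- vapply(seq_len(nrow(d)), function(i) {
    obs_idx <- !is.na(d[i, ])
    if (per_sample_support) {
      O <- sum(hom[i, obs_idx])
      E <- sum(exp_hom[obs_idx])
      L <- sum(obs_idx)
    } else {
      O <- sum(hom[i, ])
      E <- sum(exp_hom, na.rm = TRUE)
      L <- ncol(d)
    }
    if (L == 0 || abs(L - E) < 1e-12) return(NA_real_)
    (O - E) / (L - E)
  }, numeric(1))
  names(out) <- gm$samples
  out
}

#' Per-individual table of genomic inbreeding coefficients
#'
#' One row per sample with F_ROH in each length class, total F_ROH and
#' F_HOM. The total is computed as the sum of the three class coefficients,
#' so the additivity `f_roh_total = f_roh_1_5 + f_roh_5_10 + f_roh_gt10`
#' holds exactly.
#'
#' @param gm a post-QC [genotype_matrix()].
#' @param segments classified segment data.frame from [detect_roh()] /
#'   [classify_segments()] (classes added if absent).
#' @param span optional [l_auto()] result (computed from `gm` if omitted).
#' @param per_sample_support passed to [f_hom()].
#' @return data.frame with columns `sample_id`, `f_roh_1_5`, `f_roh_5_10`,
#'   `f_roh_gt10`, `f_roh_total`, `f_hom`.
#' @export
inbreeding_table <- function(gm, segments, span = NULL,
                             per_sample_support = TRUE) {
  extra <- setdiff(unique(segments$sample_id), gm$samples)
  if (length(extra)) {
    stop("segments contain samples absent from the genotype matrix: ",
         paste(utils::head(extra, 3), collapse = ", "))
  }
  if (!"length_class" %in% names(segments)) segments <- classify_segments(segments)
  if (is.null(span)) span <- l_auto(gm)
  fh <- f_hom(gm, per_sample_support = per_sample_support)
  rows <- lapply(gm$samples, function(s) {
    segs <- segments[segments$sample_id == s, , drop = FALSE]
    f1 <- f_roh(segs, span, "1-5")
    f2 <- f_roh(segs, span, "5-10")
    f3 <- f_roh(segs, span, ">10")
    data.frame(sample_id = s, f_roh_1_5 = f1, f_roh_5_10 = f2,
               f_roh_gt10 = f3, f_roh_total = f1 + f2 + f3,
               f_hom = unname(fh[s]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise Pearson correlations of the inbreeding coefficients
#'
#' @param table an [inbreeding_table()] result (or any data.frame whose
#'   numeric columns are to be correlated).
#' @return symmetric correlation matrix with unit diagonal; entries
#'   involving a constant (or all-missing) column are `NA`.
#' @export
pearson_correlations <- function(table) {
  cols <- names(table)[vapply(table, is.numeric, logical(1))]
  x <- as.matrix(table[, cols, drop = FALSE])
  if (nrow(x) < 3) stop("need at least 3 samples for correlations")
  r <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
  sds <- apply(x, 2, stats::sd, na.rm = TRUE)
  const <- !is.finite(sds) | sds == 0
  r[const, ] <- NA_real_
  r[, const] <- NA_real_
  diag(r) <- 1
  r
}
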