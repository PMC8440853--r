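#' Genotype matrix container
#'
#' Holds a samples x SNPs dosage matrix together with variant and sample
#' metadata. Dosage counts copies of `allele_b` at each SNP, so each
#' non-missing entry is 0, 1 or 2; missing genotypes are `NA`. Variants are
#' kept sorted by (chromosome, position), with positions strictly increasing
#' within a chromosome; all homozygosity-based statistics downstream depend
#' only on the {hom, het, missing} state, never on which allele is counted.
#'
#' @param variants data.frame with columns `chrom` (character), `id`,
#'   `pos_bp` (1-based physical position), `allele_a`, `allele_b`.
#' @param samples character vector of sample ids.
#' @param dosage integer matrix, `length(samples)` rows x `nrow(variants)`
#'   columns, entries in `{0, 1, 2, NA}`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(variants, samples, dosage) {
  stopifnot(is.data.frame(variants))
  req <- c("chrom", "id", "pos_bp", "allele_a", "allele_b")
  miss <- setdiff(req, names(variants))
  if (length(miss)) stop("variants is missing columns: ", paste(miss, collapse = ", "))
  variants$chrom <- as.character(variants$chrom)
  variants$id <- as.character(variants$id)
  samples <- as.character(samples)
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (nrow(dosage) != length(samples) || ncol(dosage) != nrow(variants)) {
    stop(sprintf("dosage is %d x %d but there are %d samples and %d variants",
                 nrow(dosage), ncol(dosage), length(samples), nrow(variants)))
  }
  if (anyDuplicated(variants$id)) {
    stop("duplicate SNP id: ", variants$id[duplicated(variants$id)][1])
  }
  if (anyDuplicated(samples)) stop("duplicate sample ids")
  if (nrow(variants) > 0) {
    if (any(variants$pos_bp < 1)) stop("variant positions must be >= 1")
    ord <- order(chrom_rank(variants$chrom), variants$pos_bp)
    if (any(ord != seq_along(ord))) {
      variants <- variants[ord, , drop = FALSE]
      dosage <- dosage[, ord, drop = FALSE]
    }
    for (ch in unique(variants$chrom)) {
      p <- variants$pos_bp[variants$chrom == ch]
      if (any(diff(p) <= 0)) {
        stop("positions not strictly increasing on chromosome ", ch)
      }
    }
  }
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    stop("dosage entries must be 0, 1, 2 or NA")
  }
  rownames(dosage) <- samples
  colnames(dosage) <- variants$id
  rownames(variants) <- NULL
  structure(list(variants = variants, samples = samples, dosage = dosage),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants on %d chromosome(s)\n",
              length(x$samples), nrow(x$variants),
              length(unique(x$variants$chrom))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) c(length(x$samples), nrow(x$variants))

#' Number of samples / variants
#' @param gm a [genotype_matrix()].
#' @return integer count.
#' @export
n_samples <- function(gm) length(gm$samples)

#' @rdname n_samples
#' @export
n_variants <- function(gm) nrow(gm$variants)

#' Subset a genotype matrix by sample and/or variant index
#'
#' @param gm a [genotype_matrix()].
#' @param samples,variants integer or logical indices; `NULL` keeps all.
#' @return a [genotype_matrix()].
#' @export
subset_genotypes <- function(gm, samples = NULL, variants = NULL) {
  si <- if (is.null(samples)) seq_along(gm$samples) else samples
  vi <- if (is.null(variants)) seq_len(nrow(gm$variants)) else variants
  genotype_matrix(gm$variants[vi, , drop = FALSE],
                  gm$samples[si],
                  gm$dosage[si, vi, drop = FALSE])
}

# Chromosome labels in canonical order: numeric labels numerically first,
# then non-numeric labels (X, Y, MT, ...) alphabetically.
chrom_levels <- function(chrom) {
  u <- unique(as.character(chrom))
  num <- suppressWarnings(as.numeric(u))
  u[order(is.na(num), num, u)]
}

chrom_rank <- function(chrom) match(as.character(chrom), chrom_levels(chrom))

#' Autosome labels for a species with `n` autosomes (pig: 18)
#' @param n number of autosomes.
#' @return character vector `"1" ... "n"`.
#' @export
autosome_labels <- function(n = 18) as.character(seq_len(n))
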