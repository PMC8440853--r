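#' Per-SNP ROH incidence across individuals
#'
#' For every SNP, counts the individuals that have a ROH segment spanning
#' its position (`start_bp <= pos <= end_bp`); each individual is counted at
#' most once per SNP even if its segments were to overlap. The fraction is
#' the count divided by the number of individuals.
#'
#' @param segments segment data.frame from [detect_roh()].
#' @param variants variant table (post-QC map) as in [genotype_matrix()].
#' @param n_individuals number of individuals the segments were called from.
#' @return data.frame with `chrom`, `id`, `pos_bp`, `n_in_roh`, `fraction`.
#' @export
snp_incidence <- function(segments, variants, n_individuals) {
  if (n_individuals == 0) stop("n_individuals must be positive")
  counts <- integer(nrow(variants))
  for (ch in unique(segments$chrom)) {
    vidx <- which(variants$chrom == ch)
    if (!length(vidx)) next
    pos <- variants$pos_bp[vidx]
    segs <- segments[segments$chrom == ch, , drop = FALSE]
    for (s in unique(segs$sample_id)) {
      ss <- segs[segs$sample_id == s, , drop = FALSE]
      ss <- ss[order(ss$start_bp), , drop = FALSE]
      # merge defensively so an individual is never double counted
      cov <- logical(length(vidx))
      for (k in seq_len(nrow(ss))) {
        lo <- findInterval(ss$start_bp[k] - 0.5, pos) + 1L
        hi <- findInterval(ss$end_bp[k] + 0.5, pos)
        if (hi >= lo) cov[lo:hi] <- TRUE
      }
      counts[vidx] <- counts[vidx] + cov
    }
  }
  data.frame(chrom = variants$chrom, id = variants$id,
             pos_bp = variants$pos_bp, n_in_roh = counts,
             fraction = counts / n_individuals,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Top-percentile incidence threshold
#'
#' The threshold is the incidence of the SNP at rank
#' `ceiling(top_fraction * nSNPs)` from the top; SNPs with incidence greater
#' than or equal to it qualify, so ties at the threshold are all included
#' and the qualifying set may slightly exceed the nominal percentile.
#'
#' @param incidence a [snp_incidence()] result.
#' @param top_fraction fraction of SNPs to select (default top 1%).
#' @return threshold incidence fraction.
#' @export
island_threshold <- function(incidence, top_fraction = 0.01) {
  x <- incidence$fraction
  n <- length(x)
  if (n == 0) stop("no SNPs")
  if (n < 1 / top_fraction) {
    warning(sprintf("only %d SNPs for a %.3g tail; using the maximum incidence",
                    n, top_fraction))
    return(max(x))
  }
  k <- ceiling(top_fraction * n)
  sort(x, decreasing = TRUE)[k]
}

#' Merge qualifying SNPs into ROH islands
#'
#' Maximal runs of consecutive qualifying SNPs (incidence at or above the
#' threshold, no intervening non-qualifying SNP, same chromosome) become
#' islands; runs with fewer than `min_island_snps` SNPs are dropped. Island
#' coordinates are the first/last qualifying SNP positions, with inclusive
#' length `end - start + 1`. "Adjacent" imposes no base-pair gap cap by
#' default; `max_gap_bp` optionally splits runs at larger gaps.
#'
#' @param incidence a [snp_incidence()] result.
#' @param threshold qualifying incidence (from [island_threshold()]).
#' @param min_island_snps minimum qualifying SNPs per island (default 2, so
#'   isolated noisy SNPs do not form islands).
#' @param max_gap_bp optional maximum gap between consecutive qualifying
#'   SNPs (default `Inf`, i.e. off).
#' @return data.frame with `chrom`, `start_bp`, `end_bp`, `length_bp`,
#'   `n_snps`, `peak_fraction`, ordered by (chromosome, start).
#' @export
merge_islands <- function(incidence, threshold, min_island_snps = 2,
                          max_gap_bp = Inf) {
  rows <- list()
  for (ch in chrom_levels(incidence$chrom)) {
    sub <- incidence[incidence$chrom == ch, , drop = FALSE]
    qual <- which(sub$fraction >= threshold)
    if (!length(qual)) next
    brk <- c(0L, which(diff(qual) > 1L |
                         diff(sub$pos_bp[qual]) > max_gap_bp),
             length(qual))
    brk <- sort(unique(brk))
    for (r in seq_len(length(brk) - 1L)) {
      run <- qual[(brk[r] + 1L):brk[r + 1L]]
      if (length(run) < min_island_snps) next
      start <- sub$pos_bp[run[1L]]
      end <- sub$pos_bp[run[length(run)]]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start_bp = start, end_bp = end,
        length_bp = end - start + 1, n_snps = length(run),
        peak_fraction = max(sub$fraction[run]), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(chrom = character(), start_bp = numeric(),
                      end_bp = numeric(), length_bp = numeric(),
                      n_snps = integer(), peak_fraction = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(chrom_rank(out$chrom), out$start_bp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read gene/feature intervals from BED or GFF3
#'
#' Thin wrapper over `rtracklayer::import()`; coordinates come back 1-based
#' inclusive regardless of the source convention.
#'
#' @param path a BED or GFF3 file.
#' @return data.frame with `chrom`, `start`, `end`, `name`.
#' @export
read_features <- function(path) {
  gr <- rtracklayer::import(path)
  nm <- if (!is.null(gr$name)) as.character(gr$name)
        else if (!is.null(gr$Name)) as.character(gr$Name)
        else if (!is.null(gr$ID)) as.character(gr$ID)
        else paste0("feature_", seq_along(gr))
  nm[is.na(nm)] <- paste0("feature_", which(is.na(nm)))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             name = nm, row.names = NULL, stringsAsFactors = FALSE)
}

#' Annotate islands with overlapping features
#'
#' A feature is assigned to an island iff their intervals (both 1-based,
#' inclusive) overlap by at least 1 bp. Features on chromosome labels absent
#' from the island table are skipped with a warning.
#'
#' @param islands a [merge_islands()] result.
#' @param features data.frame with `chrom`, `start`, `end` and optionally
#'   `name` (e.g. from [read_features()]).
#' @return `islands` with added columns `n_features` and `features`
#'   (comma-separated names).
#' @export
annotate_islands <- function(islands, features) {
  if (!"name" %in% names(features)) {
    features$name <- paste0("feature_", seq_len(nrow(features)))
  }
  unknown <- setdiff(unique(features$chrom), unique(islands$chrom))
  if (length(unknown) && nrow(islands)) {
    skipped <- features$chrom %in% unknown
    warning(sprintf("skipping %d feature(s) on chromosome label(s) not present in islands: %s",
                    sum(skipped), paste(unknown, collapse = ", ")))
    features <- features[!skipped, , drop = FALSE]
  }
  islands$n_features <- 0L
  islands$features <- ""
  if (!nrow(islands) || !nrow(features)) return(islands)
  isl <- GenomicRanges::GRanges(islands$chrom,
                                IRanges::IRanges(islands$start_bp, islands$end_bp))
  fts <- GenomicRanges::GRanges(features$chrom,
                                IRanges::IRanges(features$start, features$end))
  hits <- GenomicRanges::findOverlaps(isl, fts)
  for (i in seq_len(nrow(islands))) {
    f <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]
    islands$n_features[i] <- length(f)
    islands$features[i] <- paste(features$name[f], collapse = ",")
  }
  islands
}
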