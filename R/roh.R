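#' Parameters of the sliding-window ROH scan
#'
#' Defaults reproduce the criteria customary for ~50K livestock arrays: a
#' 50-SNP window sliding one SNP at a time, at most 1 heterozygote and 5
#' missing calls per window, a SNP considered "in ROH" when at least 5% of
#' the windows containing it are homozygous, and final segments required to
#' be at least 1 Mb long, contain at least 50 SNPs and average no more than
#' 100 kb per SNP. `max_gap_kb` splits candidate segments at inter-SNP gaps
#' above 1 Mb so a segment never bridges an assembly gap.
#'
#' @param window_snps SNPs per sliding window.
#' @param max_het_per_window,max_missing_per_window allowed heterozygous and
#'   missing calls for a window to count as homozygous.
#' @param window_hit_threshold minimum fraction of overlapping homozygous
#'   windows for a SNP to be flagged, in (0, 1].
#' @param min_length_bp,min_snps minimum segment length and SNP count.
#' @param max_density_kb_per_snp maximum average spacing (kb per SNP) of a
#'   final segment.
#' @param max_gap_kb maximum gap (kb) between consecutive SNPs inside a
#'   segment.
#' @return a `roh_params` list.
#' @export
roh_params <- function(window_snps = 50,
                       max_het_per_window = 1,
                       max_missing_per_window = 5,
                       window_hit_threshold = 0.05,
                       min_length_bp = 1e6,
                       min_snps = 50,
                       max_density_kb_per_snp = 100,
                       max_gap_kb = 1000) {
  stopifnot(window_snps >= 1, max_het_per_window >= 0,
            max_missing_per_window >= 0,
            window_hit_threshold > 0, window_hit_threshold <= 1,
            min_length_bp >= 1, min_snps >= 0,
            max_density_kb_per_snp > 0, max_gap_kb > 0)
  structure(list(window_snps = as.integer(window_snps),
                 max_het_per_window = as.integer(max_het_per_window),
                 max_missing_per_window = as.integer(max_missing_per_window),
                 window_hit_threshold = window_hit_threshold,
                 min_length_bp = min_length_bp,
                 min_snps = as.integer(min_snps),
                 max_density_kb_per_snp = max_density_kb_per_snp,
                 max_gap_kb = max_gap_kb),
            class = "roh_params")
}

#' Per-SNP window-hit fraction for one individual
#'
#' Slides a `window_snps`-SNP window one SNP at a time along each chromosome
#' (windows never span chromosomes). A window is homozygous iff it contains
#' at most `max_het_per_window` heterozygotes and `max_missing_per_window`
#' missing calls. Each SNP's hit fraction is the number of homozygous
#' windows containing it divided by the number of windows containing it.
#' A chromosome with fewer SNPs than `window_snps` is scanned with a single
#' full-chromosome window; no other truncated windows are used.
#'
#' @param genotypes integer vector of dosages (0/1/2/NA) for one sample,
#'   aligned with `variants`.
#' @param variants variant table as in [genotype_matrix()].
#' @param params a [roh_params()].
#' @return numeric vector of hit fractions, one per SNP.
#' @export
scan_windows <- function(genotypes, variants, params = roh_params()) {
  stopifnot(length(genotypes) == nrow(variants))
  frac <- numeric(length(genotypes))
  if (!length(genotypes)) return(frac)
  for (ch in chrom_levels(variants$chrom)) {
    idx <- which(variants$chrom == ch)
    g <- genotypes[idx]
    m <- length(g)
    w <- params$window_snps
    het <- !is.na(g) & g == 1L
    mis <- is.na(g)
    if (m < w) {
      hom <- sum(het) <= params$max_het_per_window &&
        sum(mis) <= params$max_missing_per_window
      frac[idx] <- as.numeric(hom)
      next
    }
    nw <- m - w + 1L
    ch_het <- c(0L, cumsum(het))
    ch_mis <- c(0L, cumsum(mis))
    win_het <- ch_het[(w + 1L):(m + 1L)] - ch_het[1L:nw]
    win_mis <- ch_mis[(w + 1L):(m + 1L)] - ch_mis[1L:nw]
    hom <- as.integer(win_het <= params$max_het_per_window &
                        win_mis <= params$max_missing_per_window)
    ch_hom <- c(0L, cumsum(hom))
    i <- seq_len(m)
    lo <- pmax(1L, i - w + 1L)   # first window containing SNP i
    hi <- pmin(nw, i)            # last window containing SNP i
    frac[idx] <- (ch_hom[hi + 1L] - ch_hom[lo]) / (hi - lo + 1L)
  }
  frac
}

# Build segments from flagged SNP indices of one chromosome.
# Splits runs of consecutive flagged SNPs at bp gaps above max_gap, then
# applies the length / SNP-count / density criteria.
.segments_from_flags <- function(flag_idx, pos, params) {
  out <- list()
  if (!length(flag_idx)) return(out)
  run_breaks <- c(0L, which(diff(flag_idx) > 1L), length(flag_idx))
  for (r in seq_len(length(run_breaks) - 1L)) {
    run <- flag_idx[(run_breaks[r] + 1L):run_breaks[r + 1L]]
    gap_breaks <- c(0L, which(diff(pos[run]) > params$max_gap_kb * 1000),
                    length(run))
    for (s in seq_len(length(gap_breaks) - 1L)) {
      piece <- run[(gap_breaks[s] + 1L):gap_breaks[s + 1L]]
      start_bp <- pos[piece[1L]]
      end_bp <- pos[piece[length(piece)]]
      len <- end_bp - start_bp + 1
      n <- length(piece)
      if (len >= params$min_length_bp && n >= params$min_snps &&
          len / 1000 <= params$max_density_kb_per_snp * n) {
        out[[length(out) + 1L]] <- c(start_bp, end_bp, n, len)
      }
    }
  }
  out
}

#' Call ROH segments for one individual
#'
#' SNPs whose window-hit fraction (see [scan_windows()]) is at least
#' `window_hit_threshold` are flagged; maximal runs of flagged SNPs on a
#' chromosome become candidate segments, split wherever the gap between
#' consecutive flagged SNPs exceeds `max_gap_kb`. A candidate is kept iff its
#' inclusive length (`end - start + 1`) is at least `min_length_bp`, it spans
#' at least `min_snps` SNPs, and its average spacing is at most
#' `max_density_kb_per_snp` kb per SNP. Segment ends are the outermost
#' flagged SNP positions.
#'
#' @inheritParams scan_windows
#' @param sample_id id stored in the output rows.
#' @return data.frame with columns `sample_id`, `chrom`, `start_bp`,
#'   `end_bp`, `n_snps`, `length_bp` (possibly zero rows).
#' @export
call_roh_sample <- function(genotypes, variants, params = roh_params(),
                            sample_id = "sample") {
  frac <- scan_windows(genotypes, variants, params)
  flagged <- frac >= params$window_hit_threshold
  rows <- list()
  for (ch in chrom_levels(variants$chrom)) {
    idx <- which(variants$chrom == ch)
    pos <- variants$pos_bp[idx]
    segs <- .segments_from_flags(which(flagged[idx]), pos, params)
    for (s in segs) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sample_id, chrom = ch, start_bp = s[1], end_bp = s[2],
        n_snps = as.integer(s[3]), length_bp = s[4],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty_segments())
  do.call(rbind, rows)
}

empty_segments <- function() {
  data.frame(sample_id = character(), chrom = character(),
             start_bp = numeric(), end_bp = numeric(),
             n_snps = integer(), length_bp = numeric(),
             stringsAsFactors = FALSE)
}

#' Reference ROH caller by direct enumeration
#'
#' Literal re-statement of the sliding-window contract with explicit loops
#' and no incremental bookkeeping: every window is summed afresh, every
#' SNP's containing windows are enumerated one by one, and segments are
#' assembled by walking the flagged SNPs. Intended as an O(n * window)
#' cross-check for [call_roh_sample()], which must match it exactly.
#'
#' @inheritParams call_roh_sample
#' @return data.frame with the same columns as [call_roh_sample()].
#' @export
naive_roh_oracle <- function(genotypes, variants, params = roh_params(),
                             sample_id = "sample") {
  rows <- list()
  for (ch in chrom_levels(variants$chrom)) {
    idx <- which(variants$chrom == ch)
    g <- genotypes[idx]
    pos <- variants$pos_bp[idx]
    m <- length(g)
    if (m == 0) next
    w <- params$window_snps
    starts <- if (m < w) 1L else seq_len(m - w + 1L)
    wlen <- if (m < w) m else w
    hom <- logical(length(starts))
    for (k in seq_along(starts)) {
      win <- g[starts[k]:(starts[k] + wlen - 1L)]
      hom[k] <- sum(!is.na(win) & win == 1L) <= params$max_het_per_window &&
        sum(is.na(win)) <= params$max_missing_per_window
    }
    flagged <- logical(m)
    for (i in seq_len(m)) {
      containing <- which(starts <= i & starts + wlen - 1L >= i)
      flagged[i] <- mean(hom[containing]) >= params$window_hit_threshold
    }
    # walk flagged SNPs, breaking at unflagged SNPs or oversized gaps
    i <- 1L
    while (i <= m) {
      if (!flagged[i]) { i <- i + 1L; next }
      j <- i
      while (j + 1L <= m && flagged[j + 1L] &&
             pos[j + 1L] - pos[j] <= params$max_gap_kb * 1000) {
        j <- j + 1L
      }
      len <- pos[j] - pos[i] + 1
      n <- j - i + 1L
      if (len >= params$min_length_bp && n >= params$min_snps &&
          len / 1000 <= params$max_density_kb_per_snp * n) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sample_id, chrom = ch, start_bp = pos[i],
          end_bp = pos[j], n_snps = n, length_bp = len,
          stringsAsFactors = FALSE)
      }
      i <- j + 1L
    }
  }
  if (!length(rows)) return(empty_segments())
  do.call(rbind, rows)
}

#' Detect ROH segments in all individuals
#'
#' Runs [call_roh_sample()] for every sample and returns the concatenated
#' segment table in deterministic (sample, chromosome, start) order.
#'
#' @param gm a post-QC [genotype_matrix()].
#' @param params a [roh_params()].
#' @return data.frame of segments; see [call_roh_sample()].
#' @export
detect_roh <- function(gm, params = roh_params()) {
  out <- lapply(seq_along(gm$samples), function(i) {
    call_roh_sample(gm$dosage[i, ], gm$variants, params,
                    sample_id = gm$samples[i])
  })
  segs <- do.call(rbind, c(out, list(empty_segments())))
  segs <- segs[order(match(segs$sample_id, gm$samples),
                     chrom_rank(segs$chrom), segs$start_bp), , drop = FALSE]
  rownames(segs) <- NULL
  segs
}

#' Classify ROH segments by length
#'
#' Length classes are a left-closed partition of `[1 Mb, Inf)`:
#' `"1-5"` for `[1, 5)` Mb, `"5-10"` for `[5, 10)` Mb and `">10"` for
#' `>= 10` Mb, so a segment of exactly 5 Mb falls in `"5-10"`.
#'
#' @param segments segment data.frame from [detect_roh()].
#' @return the same data.frame with a `length_class` column added.
#' @export
classify_segments <- function(segments) {
  if (nrow(segments) && any(segments$length_bp < 1e6)) {
    stop("segment shorter than 1 Mb cannot be classified")
  }
  cls <- cut(segments$length_bp, breaks = c(1e6, 5e6, 1e7, Inf),
             labels = c("1-5", "5-10", ">10"), right = FALSE)
  segments$length_class <- as.character(cls)
  segments
}

roh_classes <- c("1-5", "5-10", ">10")

#' Summarize ROH segments
#'
#' @param segments classified segments (see [classify_segments()]; the class
#'   column is added if absent).
#' @param gm the post-QC [genotype_matrix()] the segments were called from
#'   (supplies the sample list and the per-chromosome SNP spans).
#' @return list of data.frames: `per_class` (count, percent of all segments,
#'   mean length in Mb, share of total ROH length in percent), `per_individual`
#'   (`n_segments`, `total_length_bp`), `per_chromosome` (`n_segments` and
#'   `coverage_fraction`, the mean over individuals of ROH bp on the
#'   chromosome divided by the chromosome SNP-span), plus scalars
#'   `n_segments_total` and `mean_length_mb`.
#' @export
summarize_roh <- function(segments, gm) {
  if (!"length_class" %in% names(segments)) segments <- classify_segments(segments)
  total_n <- nrow(segments)
  total_len <- sum(segments$length_bp)
  per_class <- do.call(rbind, lapply(roh_classes, function(cl) {
    s <- segments[segments$length_class == cl, , drop = FALSE]
    data.frame(length_class = cl, n = nrow(s),
               percent = if (total_n) 100 * nrow(s) / total_n else 0,
               mean_length_mb = if (nrow(s)) mean(s$length_bp) / 1e6 else NA_real_,
               share_total_length = if (total_len > 0)
                 100 * sum(s$length_bp) / total_len else 0,
               stringsAsFactors = FALSE)
  }))
  # zero-length rows padded in so samples without segments appear
  len_by_sample <- tapply(c(segments$length_bp, rep(0, length(gm$samples))),
                          factor(c(segments$sample_id, gm$samples),
                                 levels = gm$samples), sum)
  per_individual <- data.frame(
    sample_id = gm$samples,
    n_segments = as.integer(table(factor(segments$sample_id, levels = gm$samples))),
    total_length_bp = as.numeric(len_by_sample),
    stringsAsFactors = FALSE)
  chroms <- chrom_levels(gm$variants$chrom)
  spans <- vapply(chroms, function(ch) {
    p <- gm$variants$pos_bp[gm$variants$chrom == ch]
    max(p) - min(p) + 1
  }, numeric(1))
  per_chromosome <- do.call(rbind, lapply(seq_along(chroms), function(k) {
    ch <- chroms[k]
    s <- segments[segments$chrom == ch, , drop = FALSE]
    bp_by_ind <- tapply(c(s$length_bp, rep(0, length(gm$samples))),
                        factor(c(s$sample_id, gm$samples), levels = gm$samples),
                        sum)
    data.frame(chrom = ch, n_segments = nrow(s),
               span_bp = spans[k],
               coverage_fraction = mean(bp_by_ind / spans[k]),
               stringsAsFactors = FALSE)
  }))
  list(per_class = per_class, per_individual = per_individual,
       per_chromosome = per_chromosome, n_segments_total = total_n,
       mean_length_mb = if (total_n) total_len / total_n / 1e6 else NA_real_)
}
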