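#' Run the full ROH / inbreeding / island / LD pipeline
#'
#' Stages run in dependency order: QC, ROH detection and classification,
#' inbreeding coefficients and correlations, per-SNP incidence and islands,
#' pairwise r-squared and decay binning. When `out_dir` is given, every
#' stage output is written as TSV together with a `manifest.yaml` recording
#' all parameters, input file hashes and the package version, so a rerun
#' with identical inputs reproduces identical files. A stage failure aborts
#' with the failing stage named.
#'
#' @param gm input [genotype_matrix()] (pre-QC), or `NULL` if `ped`/`map`
#'   paths are given.
#' @param ped,map optional PLINK text paths read when `gm` is `NULL`.
#' @param qc a [qc_thresholds()].
#' @param roh a [roh_params()].
#' @param ld an [ld_params()].
#' @param island_top_fraction,min_island_snps island-calling settings.
#' @param bin_kb LD distance-bin width.
#' @param extent_thresholds r-squared levels at which to report LD extent.
#' @param genome_bp genome size used for panel-size estimates.
#' @param features optional feature data.frame (see [annotate_islands()]).
#' @param out_dir optional output directory for TSVs and the manifest.
#' @return list of class `roh_report`: `qc_report`, `segments`,
#'   `roh_summary`, `inbreeding`, `inbreeding_summary`, `correlations`,
#'   `incidence`, `island_threshold`, `islands`, `ld_bins`, `ld_summary`,
#'   `ld_extent_kb`, `panel_sizes`, `table1`, `table2`.
#' @export
run_pipeline <- function(gm = NULL, ped = NULL, map = NULL,
                         qc = qc_thresholds(), roh = roh_params(),
                         ld = ld_params(), island_top_fraction = 0.01,
                         min_island_snps = 2, bin_kb = 100,
                         extent_thresholds = c(0.3, 0.2),
                         genome_bp = 2.5e9, features = NULL,
                         out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  input_files <- c(ped = ped, map = map)
  if (is.null(gm)) {
    if (is.null(ped) || is.null(map)) stop("supply either gm or ped+map paths")
    gm <- stage("genotype_io", read_plink_text(ped, map))
  }
  qcres <- stage("qc", qc_filter(gm, qc))
  gmq <- qcres$genotypes
  if (n_samples(gmq) == 0 || n_variants(gmq) == 0) {
    stop("pipeline stage 'qc' failed: no samples or SNPs survive QC",
         call. = FALSE)
  }
  segments <- stage("roh_detection", classify_segments(detect_roh(gmq, roh)))
  roh_summary <- stage("roh_summary", summarize_roh(segments, gmq))
  inbr <- stage("inbreeding", inbreeding_table(gmq, segments))
  corr <- stage("inbreeding", pearson_correlations(inbr))
  coef_cols <- c("f_roh_1_5", "f_roh_5_10", "f_roh_gt10", "f_roh_total", "f_hom")
  inbreeding_summary <- data.frame(
    coefficient = coef_cols,
    mean = vapply(coef_cols, function(cc) mean(inbr[[cc]], na.rm = TRUE), 0),
    min = vapply(coef_cols, function(cc) min(inbr[[cc]], na.rm = TRUE), 0),
    max = vapply(coef_cols, function(cc) max(inbr[[cc]], na.rm = TRUE), 0),
    row.names = NULL, stringsAsFactors = FALSE)

  incidence <- stage("roh_islands",
                     snp_incidence(segments, gmq$variants, n_samples(gmq)))
  thr <- stage("roh_islands", island_threshold(incidence, island_top_fraction))
  islands <- stage("roh_islands",
                   merge_islands(incidence, thr, min_island_snps))
  if (!is.null(features)) {
    islands <- stage("roh_islands", annotate_islands(islands, features))
  }

  pairs <- stage("ld_decay", pairwise_r2(gmq, ld))
  bins <- stage("ld_decay", bin_decay(pairs, bin_kb))
  ld_sum <- stage("ld_decay", ld_adjacent_summary(pairs, gmq))
  anchor <- unname(ld_sum$consecutive_lt_100kb["mean"])
  if (!is.finite(anchor)) anchor <- NULL
  extents <- vapply(extent_thresholds, function(t) {
    suppressMessages(ld_extent(bins, t, anchor_r2 = anchor))
  }, numeric(1))
  names(extents) <- paste0("r2_", extent_thresholds)
  panel <- vapply(extents, function(d) {
    if (is.na(d) || d <= 0) NA_integer_ else snp_panel_size(genome_bp, d * 1000)
  }, integer(1))

  report <- structure(list(
    qc_report = qcres$report, segments = segments, roh_summary = roh_summary,
    inbreeding = inbr, inbreeding_summary = inbreeding_summary,
    correlations = corr, incidence = incidence, island_threshold = thr,
    islands = islands, ld_bins = bins, ld_summary = ld_sum,
    ld_extent_kb = extents, panel_sizes = panel,
    table1 = render_table1(roh_summary$per_class),
    table2 = render_table2(islands)), class = "roh_report")

  if (!is.null(out_dir)) {
    write_report(report, out_dir, params = list(
      qc = unclass(qc), roh = unclass(roh), ld = unclass(ld),
      island_top_fraction = island_top_fraction,
      min_island_snps = min_island_snps, bin_kb = bin_kb,
      extent_thresholds = extent_thresholds, genome_bp = genome_bp),
      input_files = input_files)
  }
  report
}

#' Write a pipeline report to TSV files plus a manifest
#'
#' @param report a `roh_report` from [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @param params parameter list recorded in the manifest.
#' @param input_files named character vector of input paths to hash.
#' @return invisibly, the output directory.
#' @export
write_report <- function(report, out_dir, params = list(),
                         input_files = character()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, name) {
    utils::write.table(x, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(data.frame(metric = names(unclass(report$qc_report)[1:8]),
                value = unlist(unclass(report$qc_report)[1:8])),
     "qc_report.tsv")
  wt(report$segments, "roh_segments.tsv")
  wt(report$roh_summary$per_class, "roh_per_class.tsv")
  wt(report$roh_summary$per_individual, "roh_per_individual.tsv")
  wt(report$roh_summary$per_chromosome, "roh_per_chromosome.tsv")
  wt(report$inbreeding, "inbreeding.tsv")
  wt(as.data.frame(report$correlations), "inbreeding_correlations.tsv")
  wt(report$incidence, "snp_incidence.tsv")
  wt(report$islands, "islands.tsv")
  wt(report$ld_bins, "ld_decay.tsv")
  wt(report$table1, "table1.tsv")
  wt(report$table2, "table2.tsv")
  hashes <- if (length(input_files)) {
    as.list(tools::md5sum(input_files[file.exists(input_files)]))
  } else list()
  manifest <- list(package = "rohscan",
                   version = as.character(utils::packageVersion("rohscan")),
                   parameters = params, input_md5 = hashes,
                   island_threshold = report$island_threshold,
                   ld_extent_kb = as.list(report$ld_extent_kb))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}

#' Length-class summary table of ROH counts and lengths
#'
#' Reproduces the standard descriptive table: one row per length class plus
#' a total row, with the segment count, the percent of all segments, the
#' mean length (Mb) and the class share of total ROH length (percent), all
#' rounded to 2 decimals. The total mean length is the count-weighted mean
#' of the class means, and the percent column cross-foots to 100.
#'
#' @param per_class data.frame with columns `length_class`, `n` and
#'   `mean_length_mb` (as produced by [summarize_roh()]; `percent` and
#'   `share_total_length` are recomputed here).
#' @return data.frame with columns `roh_class`, `n`, `percent`,
#'   `mean_length_mb`, `genome_coverage_pct`.
#' @export
render_table1 <- function(per_class) {
  stopifnot(all(c("length_class", "n", "mean_length_mb") %in% names(per_class)))
  n <- per_class$n
  total_n <- sum(n)
  class_len <- ifelse(n > 0, n * per_class$mean_length_mb, 0)
  total_len <- sum(class_len)
  if (total_n == 0) {
    out <- data.frame(roh_class = c(per_class$length_class, "Total (>1)"),
                      n = 0L, percent = 0, mean_length_mb = 0,
                      genome_coverage_pct = 0, stringsAsFactors = FALSE)
    attr(out, "note") <- "no segments detected"
    return(out)
  }
  out <- data.frame(
    roh_class = c(per_class$length_class, "Total (>1)"),
    n = c(n, total_n),
    percent = round(100 * c(n, total_n) / total_n, 2),
    mean_length_mb = round(c(per_class$mean_length_mb, total_len / total_n), 2),
    genome_coverage_pct = round(100 * c(class_len, total_len) / total_len, 2),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Island table in the conventional reporting schema
#'
#' One row per island: chromosome, inclusive start/end/length in bp, number
#' of qualifying SNPs and (when annotation was run) the overlapping-feature
#' count. The Genes column is blank when no features were supplied.
#'
#' @param islands a [merge_islands()] (optionally [annotate_islands()])
#'   result.
#' @return data.frame with columns `CHR`, `Start_bp`, `End_bp`, `Length_bp`,
#'   `SNPs`, `Genes`.
#' @export
render_table2 <- function(islands) {
  data.frame(CHR = islands$chrom, Start_bp = islands$start_bp,
             End_bp = islands$end_bp, Length_bp = islands$length_bp,
             SNPs = islands$n_snps,
             Genes = if ("n_features" %in% names(islands))
               islands$n_features else rep("", nrow(islands)),
             row.names = NULL, stringsAsFactors = FALSE)
}
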