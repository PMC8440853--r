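#' Read PLINK text genotypes (PED/MAP)
#'
#' Parses a whitespace-delimited PED/MAP pair into a [genotype_matrix()].
#' Alleles are coded per SNP in order of first observation while scanning the
#' PED column top to bottom: the first non-missing allele seen becomes
#' `allele_a`, the second distinct one `allele_b`, and dosage counts copies of
#' `allele_b` (so a homozygote for the first-observed allele is 0). A genotype
#' with either allele `"0"` is missing. Variants are sorted by (chromosome,
#' position) with dosage columns permuted to match.
#'
#' @param ped_path,map_path paths to the PED and MAP files. The MAP must have
#'   4 columns (chrom, id, cM, bp); each PED row must have `6 + 2 * nSNP`
#'   fields.
#' @return a [genotype_matrix()]. Sample ids are taken from the PED IID
#'   (second) column.
#' @export
read_plink_text <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) stop("PED file not found: ", ped_path)
  if (!file.exists(map_path)) stop("MAP file not found: ", map_path)
  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  map_fields <- strsplit(trimws(map_lines), "[ \t]+")
  if (length(map_fields) && any(lengths(map_fields) != 4L)) {
    bad <- which(lengths(map_fields) != 4L)[1]
    stop(sprintf("MAP line %d has %d fields; expected 4", bad,
                 lengths(map_fields)[bad]))
  }
  m <- length(map_fields)
  mp <- if (m) matrix(unlist(map_fields), nrow = m, byrow = TRUE) else
    matrix(character(), 0, 4)
  chrom <- mp[, 1]
  snp_id <- mp[, 2]
  pos_bp <- as.numeric(mp[, 4])
  if (anyDuplicated(snp_id)) {
    stop("duplicate SNP id in MAP: ", snp_id[duplicated(snp_id)][1])
  }

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  fields <- strsplit(trimws(ped_lines), "[ \t]+")
  expected <- 6L + 2L * m
  bad <- which(lengths(fields) != expected)
  if (length(bad)) {
    stop(sprintf("PED line %d has %d fields; expected %d", bad[1],
                 lengths(fields)[bad[1]], expected))
  }
  n <- length(fields)
  fm <- if (n) matrix(unlist(fields), nrow = n, byrow = TRUE) else
    matrix(character(), 0, expected)
  samples <- if (n) fm[, 2] else character()

  dosage <- matrix(NA_integer_, n, m)
  allele_a <- rep(NA_character_, m)
  allele_b <- rep(NA_character_, m)
  for (j in seq_len(m)) {
    x1 <- fm[, 5L + 2L * j]
    x2 <- fm[, 6L + 2L * j]
    # observation order: sample by sample, first then second allele
    seen <- as.vector(rbind(x1, x2))
    seen <- seen[seen != "0"]
    al <- unique(seen)
    if (length(al) > 2L) {
      stop(sprintf("SNP %s has >2 alleles: %s", snp_id[j],
                   paste(al, collapse = ",")))
    }
    a <- if (length(al) >= 1L) al[1] else NA_character_
    b <- if (length(al) == 2L) al[2] else NA_character_
    allele_a[j] <- a
    allele_b[j] <- b
    miss <- x1 == "0" | x2 == "0"
    d <- integer(n)
    if (!is.na(b)) d <- (x1 == b) + (x2 == b)
    d[miss] <- NA_integer_
    dosage[, j] <- d
  }
  allele_a[is.na(allele_a)] <- "0"
  allele_b[is.na(allele_b)] <- "0"
  variants <- data.frame(chrom = chrom, id = snp_id, pos_bp = pos_bp,
                         allele_a = allele_a, allele_b = allele_b,
                         stringsAsFactors = FALSE)
  genotype_matrix(variants, samples, dosage)
}

#' Write PLINK text genotypes (PED/MAP)
#'
#' Inverse of [read_plink_text()]: dosage 0 is written as `allele_a
#' allele_a`, 1 as `allele_a allele_b`, 2 as `allele_b allele_b`, missing as
#' `"0 0"`. FID is set equal to IID; PID/MID/sex are 0 and phenotype -9.
#'
#' @param gm a [genotype_matrix()].
#' @param prefix output path prefix; writes `<prefix>.ped` and `<prefix>.map`.
#' @return invisibly, the two file paths.
#' @export
write_plink_text <- function(gm, prefix) {
  v <- gm$variants
  map_path <- paste0(prefix, ".map")
  ped_path <- paste0(prefix, ".ped")
  dir <- dirname(ped_path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  writeLines(if (nrow(v)) paste(v$chrom, v$id, 0, format(v$pos_bp, scientific = FALSE, trim = TRUE)) else character(),
             map_path)
  n <- length(gm$samples)
  m <- nrow(v)
  if (m > 0 && any(gm$dosage[!is.na(gm$dosage)] > 0 & rep(v$allele_b == "0", each = n)[!is.na(gm$dosage)])) {
    stop("non-zero dosage at a SNP with no recorded allele_b")
  }
  lines <- character(n)
  for (i in seq_len(n)) {
    d <- gm$dosage[i, ]
    g <- character(m)
    if (m) {
      g[is.na(d)] <- "0 0"
      g[!is.na(d) & d == 0L] <- paste(v$allele_a, v$allele_a)[!is.na(d) & d == 0L]
      g[!is.na(d) & d == 1L] <- paste(v$allele_a, v$allele_b)[!is.na(d) & d == 1L]
      g[!is.na(d) & d == 2L] <- paste(v$allele_b, v$allele_b)[!is.na(d) & d == 2L]
    }
    lines[i] <- paste(c(gm$samples[i], gm$samples[i], "0", "0", "0", "-9", g),
                      collapse = " ")
  }
  writeLines(lines, ped_path)
  invisible(c(ped = ped_path, map = map_path))
}

#' Read PLINK 1 binary genotypes (BED/BIM/FAM)
#'
#' Decodes a SNP-major PLINK v1.0 BED file (magic bytes `0x6C 0x1B 0x01`).
#' Within each genotype byte the lowest-order 2 bits hold the first sample;
#' codes are 00 = homozygous allele-1, 01 = missing, 10 = heterozygote,
#' 11 = homozygous allele-2. Dosage counts allele-2, and the BIM allele
#' columns are taken as authoritative: column 5 becomes `allele_a`, column 6
#' `allele_b` (no re-inference from the genotypes).
#'
#' @param bed_path,bim_path,fam_path paths to the three PLINK binary files.
#' @return a [genotype_matrix()]; sample ids from the FAM IID column.
#' @export
read_plink_binary <- function(bed_path, bim_path, fam_path) {
  for (p in c(bed_path, bim_path, fam_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  fam <- utils::read.table(fam_path, colClasses = "character")
  samples <- fam[, 2]
  n <- nrow(fam)
  bim_has_rows <- file.size(bim_path) > 0 &&
    any(nzchar(trimws(readLines(bim_path))))
  if (bim_has_rows) {
    bim <- utils::read.table(bim_path, colClasses = "character")
    if (ncol(bim) != 6L) stop("BIM must have 6 columns")
  } else {
    bim <- as.data.frame(matrix(character(), 0, 6), stringsAsFactors = FALSE)
  }
  m <- nrow(bim)

  raw <- readBin(bed_path, "raw", n = file.size(bed_path))
  if (length(raw) < 3 || raw[1] != as.raw(0x6C) || raw[2] != as.raw(0x1B) ||
      raw[3] != as.raw(0x01)) {
    stop("unsupported BED format: expected SNP-major PLINK v1.0 magic bytes 0x6C 0x1B 0x01")
  }
  bps <- ceiling(n / 4)  # bytes per SNP
  if (length(raw) - 3L != bps * m) {
    stop(sprintf("BED file truncated or inconsistent: %d data bytes, expected %d (ceil(%d/4) x %d SNPs)",
                 length(raw) - 3L, bps * m, n, m))
  }
  dosage <- matrix(NA_integer_, n, m)
  if (m > 0 && n > 0) {
    b <- as.integer(raw[-(1:3)])
    dim(b) <- c(bps, m)
    code_map <- c(0L, NA_integer_, 1L, 2L)  # 00, 01, 10, 11
    full <- matrix(0L, 4L * bps, m)
    shift <- 1L
    for (s in 1:4) {
      full[seq(s, by = 4L, length.out = bps), ] <- (b %/% shift) %% 4L
      shift <- shift * 4L
    }
    dosage <- matrix(code_map[full[seq_len(n), , drop = FALSE] + 1L], n, m)
  }
  variants <- data.frame(chrom = bim[, 1], id = bim[, 2],
                         pos_bp = as.numeric(bim[, 4]),
                         allele_a = bim[, 5], allele_b = bim[, 6],
                         stringsAsFactors = FALSE)
  genotype_matrix(variants, samples, dosage)
}

#' Write PLINK 1 binary genotypes (BED/BIM/FAM)
#'
#' Inverse of [read_plink_binary()]; used mainly to build binary fixtures in
#' code. Writes SNP-major BED v1.0.
#'
#' @param gm a [genotype_matrix()].
#' @param prefix output path prefix; writes `<prefix>.bed/.bim/.fam`.
#' @return invisibly, the three file paths.
#' @export
write_plink_binary <- function(gm, prefix) {
  v <- gm$variants
  n <- length(gm$samples)
  m <- nrow(v)
  bed_path <- paste0(prefix, ".bed")
  bim_path <- paste0(prefix, ".bim")
  fam_path <- paste0(prefix, ".fam")
  writeLines(paste(gm$samples, gm$samples, "0", "0", "0", "-9"), fam_path)
  writeLines(if (m) paste(v$chrom, v$id, 0,
                          format(v$pos_bp, scientific = FALSE, trim = TRUE),
                          v$allele_a, v$allele_b) else character(), bim_path)
  bps <- ceiling(n / 4)
  out <- raw(3 + bps * m)
  out[1:3] <- as.raw(c(0x6C, 0x1B, 0x01))
  if (m > 0 && n > 0) {
    # dosage -> 2-bit code: 0 -> 00, NA -> 01, 1 -> 10, 2 -> 11
    code <- matrix(0L, 4L * bps, m)
    d <- gm$dosage
    cd <- matrix(0L, n, m)
    cd[is.na(d)] <- 1L
    cd[!is.na(d) & d == 1L] <- 2L
    cd[!is.na(d) & d == 2L] <- 3L
    code[seq_len(n), ] <- cd
    shift <- c(1L, 4L, 16L, 64L)
    bytes <- matrix(0L, bps, m)
    for (s in 1:4) {
      bytes <- bytes + code[seq(s, by = 4L, length.out = bps), , drop = FALSE] * shift[s]
    }
    out[-(1:3)] <- as.raw(bytes)
  }
  writeBin(out, bed_path)
  invisible(c(bed = bed_path, bim = bim_path, fam = fam_path))
}
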