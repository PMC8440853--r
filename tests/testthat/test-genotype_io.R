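test_that("PED parsing codes dosage against the second-observed allele", {
  tmp <- withr::local_tempdir()
  writeLines(c("f1 s1 0 0 0 -9 A A",
               "f2 s2 0 0 0 -9 A G"), file.path(tmp, "x.ped"))
  writeLines("1 snp1 0 100", file.path(tmp, "x.map"))
  gm <- read_plink_text(file.path(tmp, "x.ped"), file.path(tmp, "x.map"))
  expect_equal(gm$samples, c("s1", "s2"))
  expect_equal(gm$variants$allele_a, "A")
  expect_equal(gm$variants$allele_b, "G")
  # homozygote for the first-observed allele -> 0
  expect_equal(unname(gm$dosage[, 1]), c(0L, 1L))
})

test_that("PED missing and malformed genotypes are handled", {
  tmp <- withr::local_tempdir()
  writeLines(c("f1 s1 0 0 0 -9 0 0 C C",
               "f2 s2 0 0 0 -9 A G C T"), file.path(tmp, "x.ped"))
  writeLines(c("1 snp1 0 100", "1 snp2 0 200"), file.path(tmp, "x.map"))
  gm <- read_plink_text(file.path(tmp, "x.ped"), file.path(tmp, "x.map"))
  expect_true(is.na(gm$dosage["s1", "snp1"]))

  writeLines(c("f1 s1 0 0 0 -9 A A"), file.path(tmp, "bad.ped"))
  writeLines(c("1 snp1 0 100", "1 snp2 0 200"), file.path(tmp, "bad.map"))
  expect_error(read_plink_text(file.path(tmp, "bad.ped"),
                               file.path(tmp, "bad.map")),
               "PED line 1")

  writeLines(c("f1 s1 0 0 0 -9 A A", "f2 s2 0 0 0 -9 C G"),
             file.path(tmp, "tri.ped"))
  writeLines("1 snp1 0 100", file.path(tmp, "tri.map"))
  expect_error(read_plink_text(file.path(tmp, "tri.ped"),
                               file.path(tmp, "tri.map")), "snp1")

  writeLines(c("f1 s1 0 0 0 -9 A A G G"), file.path(tmp, "dup.ped"))
  writeLines(c("1 snp1 0 100", "1 snp1 0 200"), file.path(tmp, "dup.map"))
  expect_error(read_plink_text(file.path(tmp, "dup.ped"),
                               file.path(tmp, "dup.map")), "duplicate")
})

test_that("text round-trip is the identity on variants, samples and dosage", {
  gm <- random_gm(n = 5, m = 20, seed = 1)
  tmp <- withr::local_tempdir()
  write_plink_text(gm, file.path(tmp, "rt"))
  gm2 <- read_plink_text(file.path(tmp, "rt.ped"), file.path(tmp, "rt.map"))
  expect_equal(gm2$samples, gm$samples)
  expect_equal(gm2$variants$id, gm$variants$id)
  expect_equal(gm2$variants$pos_bp, gm$variants$pos_bp)
  # allele labels may be re-observed in a different order where the
  # first-observed allele differs; homozygosity state must be identical
  # and dosage must match up to allele relabelling per SNP
  same <- gm2$variants$allele_b == gm$variants$allele_b
  d1 <- gm$dosage; d2 <- gm2$dosage
  d2[, !same] <- 2L - d2[, !same]
  expect_equal(d2, d1)
})

test_that("variants arrive sorted by chromosome and position", {
  tmp <- withr::local_tempdir()
  writeLines("f1 s1 0 0 0 -9 A G C C T T", file.path(tmp, "x.ped"))
  writeLines(c("2 snpA 0 500", "1 snpB 0 900", "1 snpC 0 100"),
             file.path(tmp, "x.map"))
  gm <- read_plink_text(file.path(tmp, "x.ped"), file.path(tmp, "x.map"))
  expect_equal(gm$variants$id, c("snpC", "snpB", "snpA"))
  expect_equal(unname(gm$dosage[1, ]), c(0L, 0L, 1L))
})

test_that("BED decoding follows the 2-bit PLINK 1 spec", {
  tmp <- withr::local_tempdir()
  writeLines(sprintf("fam%d s%d 0 0 0 -9", 1:4, 1:4), file.path(tmp, "b.fam"))
  writeLines("1 snp1 0 100 A B", file.path(tmp, "b.bim"))
  writeBin(as.raw(c(0x6C, 0x1B, 0x01, 0xE4)), file.path(tmp, "b.bed"))
  gm <- read_plink_binary(file.path(tmp, "b.bed"), file.path(tmp, "b.bim"),
                          file.path(tmp, "b.fam"))
  # byte 0b11_10_01_00: samples in order get 00, 01, 10, 11
  expect_equal(unname(gm$dosage[, 1]), c(0L, NA, 1L, 2L))
  expect_equal(gm$variants$allele_a, "A")
  expect_equal(gm$variants$allele_b, "B")
})

test_that("BED errors: bad magic, truncation; empty BED is fine", {
  tmp <- withr::local_tempdir()
  writeLines("fam1 s1 0 0 0 -9", file.path(tmp, "e.fam"))
  writeLines("1 snp1 0 100 A B", file.path(tmp, "e.bim"))
  writeBin(as.raw(c(0x00, 0x1B, 0x01, 0xE4)), file.path(tmp, "e.bed"))
  expect_error(read_plink_binary(file.path(tmp, "e.bed"),
                                 file.path(tmp, "e.bim"),
                                 file.path(tmp, "e.fam")), "magic")
  writeBin(as.raw(c(0x6C, 0x1B, 0x01)), file.path(tmp, "e.bed"))
  expect_error(read_plink_binary(file.path(tmp, "e.bed"),
                                 file.path(tmp, "e.bim"),
                                 file.path(tmp, "e.fam")), "truncated")
  writeLines(character(), file.path(tmp, "e.bim"))
  gm <- read_plink_binary(file.path(tmp, "e.bed"), file.path(tmp, "e.bim"),
                          file.path(tmp, "e.fam"))
  expect_equal(dim(gm), c(1L, 0L))
})

test_that("binary and text readers agree on the same data", {
  gm <- random_gm(n = 6, m = 15, seed = 42)
  tmp <- withr::local_tempdir()
  write_plink_binary(gm, file.path(tmp, "x"))
  write_plink_text(gm, file.path(tmp, "x"))
  gb <- read_plink_binary(file.path(tmp, "x.bed"), file.path(tmp, "x.bim"),
                          file.path(tmp, "x.fam"))
  expect_equal(gb$dosage, gm$dosage)
  gt <- read_plink_text(file.path(tmp, "x.ped"), file.path(tmp, "x.map"))
  # same homozygosity state everywhere (text coding may flip alleles)
  expect_equal(is.na(gt$dosage), is.na(gb$dosage))
  expect_equal(gt$dosage == 1L, gb$dosage == 1L)
})

test_that("allele frequencies, MAF and call rate match hand counts", {
  gm <- make_gm(matrix(c(0, 1, 2, 2), ncol = 1))
  af <- allele_frequencies(gm)
  expect_equal(af$freq_b, 0.625)
  expect_equal(af$maf, 0.375)
  expect_equal(af$call_rate, 1)

  gm2 <- make_gm(matrix(c(2, 2, 2, 2), ncol = 1))
  expect_equal(allele_frequencies(gm2)$maf, 0)

  gm3 <- make_gm(matrix(c(NA, NA, 0, 1), nrow = 2))
  af3 <- allele_frequencies(gm3)
  expect_true(is.na(af3$maf[1]))
  expect_equal(af3$call_rate, c(0, 1))
  expect_true(all(af3$maf >= 0 & af3$maf <= 0.5, na.rm = TRUE))
})

test_that("heterozygosity: Ho and He behave as defined", {
  gm <- make_gm(matrix(1L, nrow = 4, ncol = 3))
  h <- heterozygosity(gm)
  expect_equal(h$ho_mean, 1)
  gm2 <- make_gm(matrix(c(0, 0, 2, 2), ncol = 1))  # p = 0.5
  expect_equal(heterozygosity(gm2)$he_mean, 0.5)
  # all-missing SNP excluded from both averages
  gm3 <- make_gm(cbind(c(1, 1, 1, 1), NA))
  h3 <- heterozygosity(gm3)
  expect_equal(h3$ho_mean, 1)
  expect_true(all(h3$he <= 0.5, na.rm = TRUE))
})

test_that("qc_filter applies thresholds in order and reconciles counts", {
  set.seed(3)
  # 20 samples x 13 SNPs: 12 autosomal + 1 X; one low-call-rate sample, one
  # low-call-rate SNP, one monomorphic SNP
  n <- 20
  d <- matrix(rbinom(n * 13, 2, 0.4), n, 13)
  d[20, 5:8] <- NA          # sample 20 call rate 8/12 = 0.67 -> removed
  d[1:3, 2] <- NA           # snp2 call rate on retained 19 = 16/19 -> removed
  d[, 3] <- 0L              # monomorphic -> maf 0 removed
  gm <- make_gm(d, chrom = c(rep("1", 12), "X"),
                pos = c((1:12) * 1e3, 1e3))
  res <- qc_filter(gm, qc_thresholds())
  r <- res$report
  expect_equal(r$n_snps_removed_nonautosomal, 1)
  expect_equal(r$n_samples_removed_callrate, 1)
  expect_equal(r$n_snps_removed_callrate, 1)
  expect_true(r$n_snps_removed_maf >= 1)
  expect_equal(r$n_snps_input,
               r$n_snps_removed_nonautosomal + r$n_snps_removed_callrate +
                 r$n_snps_removed_maf + r$n_snps_retained)
  expect_equal(r$n_samples_input,
               r$n_samples_removed_callrate + r$n_samples_retained)
  # post-conditions by direct recomputation
  af <- allele_frequencies(res$genotypes)
  expect_true(all(af$maf > 0.01))
  expect_true(all(af$call_rate >= 0.9))
  # idempotence
  res2 <- qc_filter(res$genotypes, qc_thresholds())
  expect_equal(res2$genotypes$dosage, res$genotypes$dosage)
  expect_equal(res2$report$n_snps_retained, r$n_snps_retained)
  expect_equal(res2$report$n_samples_retained, r$n_samples_retained)
})

test_that("MAF exactly at the threshold is removed (strict inequality)", {
  # 50 samples, maf exactly 0.01: 1 copy of B in 100 alleles
  d <- matrix(0L, 50, 2)
  d[1, 1] <- 1L                         # maf 0.01 -> removed
  d[1:10, 2] <- 1L                      # maf 0.1 -> kept
  gm <- make_gm(d)
  res <- qc_filter(gm, qc_thresholds())
  expect_equal(res$genotypes$variants$id, "snp002")
  expect_equal(res$report$n_snps_removed_maf, 1)
})
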