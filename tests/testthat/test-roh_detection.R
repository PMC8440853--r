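hom_variants <- function(m, by = 20000, chrom = "1") {
  data.frame(chrom = chrom, id = sprintf("s%04d", 1:m),
             pos_bp = seq(1, by = by, length.out = m),
             allele_a = "A", allele_b = "B", stringsAsFactors = FALSE)
}

test_that("window-hit fractions: all-homozygous and alternating extremes", {
  v <- hom_variants(100)
  expect_equal(scan_windows(rep(0L, 100), v), rep(1, 100))
  # strictly alternating het/hom: every 50-SNP window holds >= 25 hets
  g <- rep(c(1L, 0L), 50)
  expect_equal(scan_windows(g, v), rep(0, 100))
})

test_that("hit fractions around an isolated heterozygote match enumeration", {
  v <- hom_variants(100)
  g <- rep(2L, 100)
  g[50] <- 1L
  frac <- scan_windows(g, v, roh_params())
  # independent exhaustive enumeration of the 51 window positions
  expected <- numeric(100)
  hom <- vapply(1:51, function(s) sum(g[s:(s + 49)] == 1L) <= 1, logical(1))
  for (i in 1:100) {
    win <- intersect(1:51, (i - 49):i)
    expected[i] <- mean(hom[win])
  }
  expect_equal(frac, expected)
  # one het is within the allowance, so every window is still homozygous
  expect_equal(frac, rep(1, 100))
})

test_that("a short chromosome uses one full-chromosome window", {
  v <- hom_variants(30)
  expect_equal(scan_windows(rep(0L, 30), v, roh_params()), rep(1, 30))
  g <- rep(0L, 30); g[5] <- g[10] <- 1L  # 2 hets > allowance of 1
  expect_equal(scan_windows(g, v, roh_params()), rep(0, 30))
})

test_that("segment calling honours length, SNP-count and density criteria", {
  # 120 homozygous SNPs spanning ~2 Mb
  v <- hom_variants(120, by = 16800)
  seg <- call_roh_sample(rep(0L, 120), v, roh_params(), "a")
  expect_equal(nrow(seg), 1)
  expect_equal(seg$n_snps, 120L)
  expect_equal(seg$length_bp, 119 * 16800 + 1)
  expect_gt(seg$length_bp, 1.9e6)
  # same run compressed to ~0.9 Mb: below the 1 Mb minimum
  v2 <- hom_variants(120, by = 7560)
  expect_equal(nrow(call_roh_sample(rep(0L, 120), v2, roh_params(), "a")), 0)
  # 120 SNPs spanning 13 Mb: density 108 kb/SNP > 100 -> rejected
  v3 <- hom_variants(120, by = 110000)
  expect_equal(nrow(call_roh_sample(rep(0L, 120), v3, roh_params(), "a")), 0)
})

test_that("oversized gaps split candidate segments", {
  pos <- c(seq(1, by = 20000, length.out = 60),
           seq(1 + 59 * 20000 + 2e6, by = 20000, length.out = 60))
  v <- hom_variants(120); v$pos_bp <- pos
  segs <- call_roh_sample(rep(0L, 120), v, roh_params(), "a")
  expect_equal(nrow(segs), 2)
  expect_true(all(segs$n_snps == 60))
  expect_true(all(segs$length_bp < 1.2e6 + 1))
})

test_that("windows never span chromosomes", {
  v <- rbind(hom_variants(60, chrom = "1"), hom_variants(60, chrom = "2"))
  v$id <- sprintf("s%04d", 1:120)
  g <- rep(0L, 120)
  segs <- call_roh_sample(g, v, roh_params(), "a")
  expect_equal(sort(unique(segs$chrom)), c("1", "2"))
  expect_equal(nrow(segs), 2)
})

test_that("fast caller equals the enumeration oracle on random instances", {
  for (seed in 0:59) {
    inst <- random_roh_instance(seed)
    fast <- call_roh_sample(inst$genotypes, inst$variants, inst$params, "x")
    slow <- naive_roh_oracle(inst$genotypes, inst$variants, inst$params, "x")
    expect_equal(fast, slow, info = paste("seed", seed))
  }
})

test_that("raising minimum criteria is monotone in segment count", {
  for (seed in c(2, 11, 23)) {
    inst <- random_roh_instance(seed)
    p <- inst$params
    n0 <- nrow(call_roh_sample(inst$genotypes, inst$variants, p))
    p_len <- p; p_len$min_length_bp <- p$min_length_bp * 2
    p_snp <- p; p_snp$min_snps <- p$min_snps + 5L
    expect_lte(nrow(call_roh_sample(inst$genotypes, inst$variants, p_len)), n0)
    expect_lte(nrow(call_roh_sample(inst$genotypes, inst$variants, p_snp)), n0)
    p_het <- p; p_het$max_het_per_window <- p$max_het_per_window + 1L
    expect_gte(nrow(call_roh_sample(inst$genotypes, inst$variants, p_het)), n0)
  }
})

test_that("segments are sorted and non-overlapping within sample/chromosome", {
  sim <- simulate_population(sim_config(n_chromosomes = 4,
                                        snps_per_chromosome = 800,
                                        n_individuals = 20, target_f = 0.15,
                                        seed = 11))
  segs <- detect_roh(sim$genotypes)
  expect_gt(nrow(segs), 0)
  by_sc <- split(segs, paste(segs$sample_id, segs$chrom))
  for (s in by_sc) {
    if (nrow(s) < 2) next
    expect_true(all(diff(s$start_bp) > 0))
    expect_true(all(s$start_bp[-1] > s$end_bp[-nrow(s)]))
  }
  # two identical samples give identical segment sets
  gm <- sim$genotypes
  gm2 <- genotype_matrix(gm$variants, c("a", "b"),
                         gm$dosage[c(1, 1), , drop = FALSE])
  s2 <- detect_roh(gm2)
  sa <- s2[s2$sample_id == "a", -1]; sb <- s2[s2$sample_id == "b", -1]
  rownames(sa) <- rownames(sb) <- NULL
  expect_equal(sa, sb)
})

test_that("planted clean tracts are recovered with tight boundaries", {
  # zero het error, no missingness, tracts >= 2.5 Mb (>= 50 SNPs at 50 kb)
  set.seed(99)
  m <- 2000
  v <- hom_variants(m, by = 50000)
  p <- runif(m, 0.05, 0.5)
  g <- rbinom(m, 2, p)
  tracts <- rbind(c(20e6, 24e6), c(60e6, 63e6))
  for (k in 1:2) {
    ix <- which(v$pos_bp >= tracts[k, 1] & v$pos_bp <= tracts[k, 2])
    g[ix] <- 2L * rbinom(length(ix), 1, p[ix])
  }
  segs <- call_roh_sample(g, v, roh_params(), "x")
  expect_equal(nrow(segs), 2)
  spacing <- 50000
  for (k in 1:2) {
    ov <- segs[segs$start_bp <= tracts[k, 2] & segs$end_bp >= tracts[k, 1], ]
    expect_equal(nrow(ov), 1)
    # every planted-tract SNP is inside the recovered segment
    ix <- which(v$pos_bp >= tracts[k, 1] & v$pos_bp <= tracts[k, 2])
    expect_lte(ov$start_bp, v$pos_bp[ix[1]])
    expect_gte(ov$end_bp, v$pos_bp[ix[length(ix)]])
  }
})

test_that("length classes partition [1 Mb, Inf) with left-closed bounds", {
  segs <- data.frame(sample_id = "a", chrom = "1",
                     start_bp = 1, end_bp = 1,
                     n_snps = 50L,
                     length_bp = c(3.49e6, 5e6, 1e7, 16.32e6, 1e6, 4.999999e6),
                     stringsAsFactors = FALSE)
  cl <- classify_segments(segs)$length_class
  expect_equal(cl, c("1-5", "5-10", ">10", ">10", "1-5", "1-5"))
  segs$length_bp[1] <- 0.9e6
  expect_error(classify_segments(segs), "1 Mb")
})

test_that("summaries cross-foot: shares sum to 100 and coverage is sane", {
  sim <- simulate_population(sim_config(n_chromosomes = 4,
                                        snps_per_chromosome = 800,
                                        n_individuals = 30, target_f = 0.12,
                                        seed = 5))
  segs <- classify_segments(detect_roh(sim$genotypes))
  sm <- summarize_roh(segs, sim$genotypes)
  expect_equal(sum(sm$per_class$n), nrow(segs))
  expect_equal(sum(sm$per_class$percent), 100, tolerance = 1e-4)
  expect_equal(sum(sm$per_class$share_total_length), 100, tolerance = 1e-4)
  expect_true(all(sm$per_chromosome$coverage_fraction >= 0 &
                    sm$per_chromosome$coverage_fraction <= 1))
  expect_equal(sum(sm$per_individual$n_segments), nrow(segs))
  # single individual, single 2 Mb segment on a 100 Mb span: coverage 0.02
  v <- hom_variants(101, by = 1e6)  # span 100,000,001 -> use exact span
  gm1 <- make_gm(matrix(0L, 1, 101), pos = v$pos_bp)
  seg1 <- data.frame(sample_id = "s1", chrom = "1", start_bp = 1e6,
                     end_bp = 3e6 - 1, n_snps = 50L, length_bp = 2e6,
                     length_class = "1-5", stringsAsFactors = FALSE)
  sm1 <- summarize_roh(seg1, gm1)
  expect_equal(sm1$per_chromosome$coverage_fraction, 2e6 / (100e6 + 1))
})
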