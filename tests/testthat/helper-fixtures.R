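# Shared fixture builders. Everything is generated in code; nothing binary
# is stored.

# Minimal genotype matrix from a dosage matrix (samples x SNPs).
make_gm <- function(dosage, pos = NULL, chrom = NULL, ids = NULL) {
  dosage <- as.matrix(dosage)
  m <- ncol(dosage)
  if (is.null(pos)) pos <- seq_len(m) * 1000
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(ids)) ids <- sprintf("snp%03d", seq_len(m))
  v <- data.frame(chrom = chrom, id = ids, pos_bp = pos,
                  allele_a = "A", allele_b = "B", stringsAsFactors = FALSE)
  genotype_matrix(v, sprintf("s%d", seq_len(nrow(dosage))), dosage)
}

# Random small genotype matrix used for round-trip tests.
random_gm <- function(n = 5, m = 20, seed = 1, missing_rate = 0.1) {
  set.seed(seed)
  p <- runif(m, 0.1, 0.9)
  d <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
  d[runif(n * m) < missing_rate] <- NA
  chrom <- as.character(rep(1:2, length.out = m))
  pos <- numeric(m)
  for (ch in unique(chrom)) {
    ix <- which(chrom == ch)
    pos[ix] <- cumsum(sample(1000:5000, length(ix), replace = TRUE))
  }
  make_gm(d, pos = pos, chrom = chrom)
}

# Random ROH-scan instance for oracle-equivalence tests: a handful of
# chromosomes with variable heterozygosity/missingness and randomized scan
# parameters, so flag/gap/length/density edge cases all occur.
random_roh_instance <- function(seed) {
  set.seed(seed)
  n_chrom <- sample(1:3, 1)
  chrom <- character(0); pos <- numeric(0); g <- integer(0)
  for (ch in seq_len(n_chrom)) {
    m <- sample(30:70, 1)
    sp <- pmax(1, round(rexp(m, 1 / 30000)))
    h <- runif(1, 0, 0.35)
    mis <- runif(1, 0, 0.15)
    gc <- ifelse(runif(m) < h, 1L, sample(c(0L, 2L), m, replace = TRUE))
    gc[runif(m) < mis] <- NA
    chrom <- c(chrom, rep(as.character(ch), m))
    pos <- c(pos, cumsum(sp))
    g <- c(g, gc)
  }
  v <- data.frame(chrom = chrom, id = sprintf("s%04d", seq_along(g)),
                  pos_bp = pos, allele_a = "A", allele_b = "B",
                  stringsAsFactors = FALSE)
  params <- roh_params(
    window_snps = sample(5:25, 1),
    max_het_per_window = sample(0:2, 1),
    max_missing_per_window = sample(0:3, 1),
    window_hit_threshold = runif(1, 0.02, 0.5),
    min_length_bp = sample(c(1e5, 3e5, 6e5, 1e6), 1),
    min_snps = sample(5:25, 1),
    max_density_kb_per_snp = sample(c(50, 100, 200), 1),
    max_gap_kb = sample(c(100, 300, 1000), 1))
  list(genotypes = g, variants = v, params = params)
}
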