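# Independent oracles and fixture builders shared across the suite.
# Oracles are deliberately written in a different style (explicit loops,
# no shared helpers) from the package code they check.

# mean pairwise Hamming distance at one site from haplotype alleles
brute_site_pi <- function(alleles) {
  n <- length(alleles)
  if (n < 2) return(0)
  tot <- 0
  for (i in 1:(n - 1))
    for (j in (i + 1):n)
      tot <- tot + as.integer(alleles[i] != alleles[j])
  tot / (n * (n - 1) / 2)
}

# Tajima (1989) D, transcribed independently of the package
oracle_tajima_d <- function(pi_sum, S, n) {
  a1 <- 0; a2 <- 0
  for (i in 1:(n - 1)) {
    a1 <- a1 + 1 / i
    a2 <- a2 + 1 / i^2
  }
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n * n + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / (a1 * a1)
  e1 <- c1 / a1
  e2 <- c2 / (a1 * a1 + a2)
  (pi_sum - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Weir & Cockerham (1984) two-population theta-hat, per-site loop
oracle_wc_fst <- function(n1, p1, h1, n2, p2, h2) {
  num <- 0; den <- 0
  for (s in seq_along(n1)) {
    r <- 2
    nbar <- (n1[s] + n2[s]) / r
    if (nbar <= 1) next
    nc <- (r * nbar - (n1[s]^2 + n2[s]^2) / (r * nbar)) / (r - 1)
    if (nc <= 0) next
    pbar <- (n1[s] * p1[s] + n2[s] * p2[s]) / (r * nbar)
    s2 <- (n1[s] * (p1[s] - pbar)^2 + n2[s] * (p2[s] - pbar)^2) /
      ((r - 1) * nbar)
    hbar <- (n1[s] * h1[s] + n2[s] * h2[s]) / (r * nbar)
    a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                        (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}

# Welch two-sample t from the printed formulas
oracle_welch <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# small random genotype matrix with two populations and optional missing
rand_gm <- function(n_samp = 8, n_sites = 40, miss = 0, seed = 1,
                    pops = NULL, chrom_length = 1e5) {
  set.seed(seed)
  g <- matrix(sample(0:2, n_samp * n_sites, replace = TRUE), n_samp)
  if (miss > 0) g[sample(length(g), round(miss * length(g)))] <- NA
  rownames(g) <- sprintf("s%02d", seq_len(n_samp))
  if (is.null(pops))
    pops <- setNames(rep(c("A", "B"), length.out = n_samp), rownames(g))
  genotype_matrix(g, sort(sample(0:(chrom_length - 1), n_sites)),
                  "chr1", chrom_length, pops)
}

# toy VCF with controllable records
write_toy_vcf <- function(path, records, chrom_length = 1000) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=chr1,length=%d>", chrom_length),
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
           "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"m\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1")
  writeLines(c(hdr, records), path)
}

toy_rec <- function(pos, ref, alt, qual = 60, dp = 300, mq = 60,
                    gt = "0/1") {
  sprintf("chr1\t%d\t.\t%s\t%s\t%s\tPASS\tDP=%d;MQ=%s\tGT\t%s",
          pos, ref, alt, qual, dp, mq, gt)
}

# genotype matrix built directly from a genotype-by-site matrix
gm_from <- function(g, pops, positions = NULL, chrom_length = 1e5) {
  g <- as.matrix(g)
  rownames(g) <- names(pops)
  if (is.null(positions)) positions <- seq_len(ncol(g)) * 10L
  genotype_matrix(g, positions, "chr1", chrom_length, pops)
}
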