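test_that("per-site diversity equals brute-force mean pairwise difference", {
  # two diploids, both heterozygous: m = 4 alleles, k = 2 -> 2*2/C(4,2)
  nd <- nucleotide_diversity(
    gm_from(matrix(1L, 2, 1), setNames(rep("P", 2), c("s1", "s2"))), "P")
  expect_equal(nd$pi_sum, 2 / 3)
  # additivity: 10 identical sites, per-bp over a 100-kb window
  nd10 <- nucleotide_diversity(
    gm_from(matrix(1L, 2, 10), setNames(rep("P", 2), c("s1", "s2"))), "P")
  expect_equal(nd10$pi_sum, 20 / 3)
  expect_equal(nd10$pi_sum / 1e5, 6.667e-5, tolerance = 1e-4)
  # random sites vs enumeration over haplotype pairs
  set.seed(31)
  for (rep in 1:50) {
    n_hap <- sample(4:20, 1)
    k <- sample(0:n_hap, 1)
    alleles <- sample(c(rep(1L, k), rep(0L, n_hap - k)))
    m <- n_hap
    expect_equal(sweepscan:::.site_pi(m, k), brute_site_pi(alleles))
  }
  # monomorphic site contributes zero
  expect_equal(sweepscan:::.site_pi(10, 0), 0)
  expect_error(nucleotide_diversity(rand_gm(), "NOPE"), "NOPE")
})

test_that("Watterson's theta is S over a1", {
  expect_equal(wattersons_theta(7, 2), 7)
  expect_equal(wattersons_theta(5, 10), 5 / sum(1 / (1:9)))
  expect_equal(wattersons_theta(0, 10), 0)
  expect_error(wattersons_theta(5, 1), "n")
})

test_that("Tajima's D matches an independent transcription to 1e-10", {
  # numerator zero when pi equals S/a1
  a1 <- sum(1 / (1:9))
  expect_equal(tajimas_d(5 / a1, 5, 10), 0)
  expect_true(is.na(tajimas_d(3, 0, 10)))
  expect_true(is.na(tajimas_d(3, 5, 3)))
  set.seed(7)
  for (i in 1:200) {
    n <- sample(4:40, 1)
    S <- sample(1:100, 1)
    pi_sum <- runif(1, 0, S)
    expect_equal(tajimas_d(pi_sum, S, n), oracle_tajima_d(pi_sum, S, n),
                 tolerance = 1e-10)
  }
  # spot value from the grid
  expect_equal(tajimas_d(5, 10, 10), oracle_tajima_d(5, 10, 10),
               tolerance = 1e-10)
})

test_that("Hudson F_ST behaves on fixed differences and identity", {
  m <- rep(200L, 5)
  expect_equal(hudson_fst(m, m, m, rep(0L, 5)), 1)  # p1=1, p2=0
  # identical frequencies: numerator <= 0, reported raw
  expect_lte(hudson_fst(rep(20L, 10), rep(10L, 10),
                        rep(20L, 10), rep(10L, 10)), 0)
  # hand-summed two-site ratio-of-sums oracle
  p1 <- c(10, 5) / 20; p2 <- c(2, 15) / 20
  num <- (p1 - p2)^2 - p1 * (1 - p1) / 19 - p2 * (1 - p2) / 19
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  expect_equal(hudson_fst(c(20, 20), c(10, 5), c(20, 20), c(2, 15)),
               sum(num) / sum(den))
  expect_true(is.na(hudson_fst(integer(0), integer(0), integer(0),
                               integer(0))))
})

test_that("WC-1984 F_ST matches a second transcription to 1e-12", {
  set.seed(12)
  n1 <- sample(5:20, 50, TRUE); n2 <- sample(5:20, 50, TRUE)
  k1 <- vapply(n1, function(n) sample(0:(2 * n), 1), integer(1))
  k2 <- vapply(n2, function(n) sample(0:(2 * n), 1), integer(1))
  h1 <- vapply(n1, function(n) sample(0:n, 1), integer(1)) / n1
  h2 <- vapply(n2, function(n) sample(0:n, 1), integer(1)) / n2
  p1 <- k1 / (2 * n1); p2 <- k2 / (2 * n2)
  expect_equal(wc_fst(n1, p1, h1, n2, p2, h2),
               oracle_wc_fst(n1, p1, h1, n2, p2, h2), tolerance = 1e-12)
  # near zero for identical frequencies, -> 1 for fixed differences
  nn <- rep(500L, 20)
  expect_equal(wc_fst(nn, rep(.5, 20), rep(.5, 20),
                      nn, rep(.5, 20), rep(.5, 20)), 0,
               tolerance = 0.05)
  expect_equal(wc_fst(nn, rep(1, 20), rep(0, 20),
                      nn, rep(0, 20), rep(0, 20)), 1, tolerance = 1e-2)
})

test_that("window grid follows the sliding rule", {
  w <- make_windows(120000, 1e5, 1e4)
  expect_equal(nrow(w), 12L)
  expect_equal(w$start, seq(0L, 110000L, by = 10000L))
  expect_equal(w$end, pmin(w$start + 1e5, 120000L))
  # step == window tiles without overlap
  w2 <- make_windows(95000, 1e4, 1e4)
  expect_equal(w2$start, seq(0L, 90000L, 1e4))
  expect_equal(w2$end[10], 95000L)       # trailing truncation
  expect_error(make_windows(1e5, 1e4, 2e4))
})

test_that("windowed statistics count and normalize correctly", {
  gm <- rand_gm(n_samp = 10, n_sites = 60, seed = 3, chrom_length = 2e5)
  gm$positions <- sort(sample(0:49999, 60))   # SNPs only in [0, 50k)
  w <- windowed_stats(gm, high = "A", low = "B", window = 1e4,
                      step = 1e4)
  expect_true(all(w$n_snps[w$start >= 5e4] == 0))
  expect_true(all(w$pi_high[w$start >= 5e4] == 0))
  # interior SNPs fall in exactly window/step = 10 sliding windows
  gm2 <- rand_gm(n_samp = 10, n_sites = 50, seed = 4, chrom_length = 1e6)
  gm2$positions <- sort(sample(300000:600000, 50))
  ws <- windowed_stats(gm2, high = "A", low = "B")
  expect_equal(sum(ws$n_snps), 10L * 50L)
})

test_that("window statistics are label-symmetric", {
  gm <- rand_gm(n_samp = 12, n_sites = 100, miss = 0.05, seed = 5)
  wab <- windowed_stats(gm, high = "A", low = "B", window = 2e4,
                        step = 2e4)
  wba <- windowed_stats(gm, high = "B", low = "A", window = 2e4,
                        step = 2e4)
  expect_equal(wab$fst, wba$fst)
  ok <- !is.na(wab$pi_ratio) & !is.na(wba$pi_ratio)
  expect_equal(wab$pi_ratio[ok], 1 / wba$pi_ratio[ok])
  expect_equal(wab$d_diff, -wba$d_diff)
  # sample order invariance
  perm <- sample(nrow(gm$geno))
  gmp <- genotype_matrix(gm$geno[perm, ], gm$positions, gm$chrom,
                         gm$chrom_length, gm$pops)
  wp <- windowed_stats(gmp, high = "A", low = "B", window = 2e4,
                       step = 2e4)
  expect_equal(wp$fst, wab$fst)
  expect_equal(wp$pi_high, wab$pi_high)
})
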