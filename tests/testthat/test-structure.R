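test_that("allele-sharing distance follows per-site enumeration", {
  pops <- setNames(rep("P", 2), c("a", "b"))
  d <- allele_sharing_distance(gm_from(rbind(c(0L, 1L, 2L, 2L),
                                             c(0L, 1L, 0L, 2L)), pops))
  expect_equal(d["a", "b"], 0.25)         # mean of (0, 0, 1, 0)/... shares
  # identical samples at distance 0; opposite homozygotes at 1
  d0 <- allele_sharing_distance(gm_from(rbind(c(0L, 2L), c(0L, 2L)), pops))
  expect_equal(d0["a", "b"], 0)
  d1 <- allele_sharing_distance(gm_from(rbind(c(0L, 2L), c(2L, 0L)), pops))
  expect_equal(d1["a", "b"], 1)
  # pairwise-complete over missing genotypes
  dm <- allele_sharing_distance(gm_from(rbind(c(0L, NA, 2L),
                                              c(0L, 1L, 0L)), pops))
  expect_equal(dm["a", "b"], mean(c(0, 1)))
  dnone <- allele_sharing_distance(gm_from(rbind(c(NA, NA), c(1L, 1L)),
                                           pops))
  expect_true(is.na(dnone["a", "b"]))
  # invariance to sample order (up to relabeling)
  gm <- rand_gm(n_samp = 6, n_sites = 30, miss = 0.1, seed = 13)
  d <- allele_sharing_distance(gm)
  perm <- c(3, 1, 6, 2, 5, 4)
  gp <- genotype_matrix(gm$geno[perm, ], gm$positions, gm$chrom,
                        gm$chrom_length, gm$pops)
  dp <- allele_sharing_distance(gp)
  expect_equal(dp[rownames(d), colnames(d)], d)
})

test_that("three-taxon NJ uses the three-point formulas", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  res <- neighbor_joining(d)
  tr <- res$tree
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl["A"]), (3 + 4 - 5) / 2)
  expect_equal(unname(bl["B"]), (3 + 5 - 4) / 2)
  expect_equal(unname(bl["C"]), (4 + 5 - 3) / 2)
  expect_error(neighbor_joining(d[1:2, 1:2]), "3 taxa")
  d_bad <- d; d_bad[1, 2] <- 9
  expect_error(neighbor_joining(d_bad), "symmetric")
})

test_that("NJ recovers known and random additive trees exactly", {
  ref <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:1):0);")
  D <- ape::cophenetic.phylo(ref)
  res <- neighbor_joining(D)
  expect_equal(ape::dist.topo(ape::unroot(ref), res$tree), 0,
               ignore_attr = TRUE)
  expect_equal(ape::cophenetic.phylo(res$tree)[rownames(D), colnames(D)],
               D, tolerance = 1e-9)
  set.seed(77)
  for (i in 1:20) {
    nt <- sample(5:10, 1)
    tr <- ape::rtree(nt, rooted = FALSE)
    D <- ape::cophenetic.phylo(tr)
    res <- neighbor_joining(D)
    expect_equal(ape::dist.topo(tr, res$tree), 0, ignore_attr = TRUE)
    expect_lt(max(abs(ape::cophenetic.phylo(res$tree)[rownames(D),
                                                      colnames(D)] - D)),
              1e-9)
    # independent cross-check against ape's NJ
    expect_equal(ape::dist.topo(res$tree, ape::nj(D)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("NJ breaks ultrametric ties lexicographically and round-trips", {
  d <- matrix(1, 4, 4) - diag(4)
  dimnames(d) <- list(c("C", "A", "D", "B"), c("C", "A", "D", "B"))
  res <- neighbor_joining(d)
  # first join is the lexicographically smallest pair (A, B)
  expect_match(res$newick, "\\(A:[0-9.eE+-]+,B:")
  # newick round-trip preserves topology and lengths
  tmp <- tempfile(fileext = ".nwk")
  ape::write.tree(res$tree, tmp)
  back <- ape::read.tree(tmp)
  expect_equal(ape::dist.topo(back, res$tree), 0, ignore_attr = TRUE)
  expect_equal(sort(back$edge.length), sort(res$tree$edge.length))
})

test_that("PCA separates clusters and reports valid variance fractions", {
  pops <- setNames(rep(c("A", "B"), each = 4), sprintf("s%d", 1:8))
  g <- rbind(matrix(0L, 4, 30), matrix(2L, 4, 30))
  g[, 1] <- c(0L, 1L, 0L, 0L, 2L, 2L, 2L, 1L)   # mild within-cluster noise
  gm <- gm_from(g, pops)
  p <- genotype_pca(gm, 3)
  x <- p$coords[, 1]
  expect_true(max(x[pops == "A"]) < min(x[pops == "B"]) ||
                max(x[pops == "B"]) < min(x[pops == "A"]))
  expect_lt(p$explained[2], 0.05)
  expect_lte(sum(p$explained), 1 + 1e-12)
  expect_true(all(p$explained >= 0))
  # sign-invariance under sample permutation
  perm <- sample(8)
  gp <- genotype_matrix(gm$geno[perm, ], gm$positions, gm$chrom,
                        gm$chrom_length, gm$pops)
  pp <- genotype_pca(gp, 3)
  expect_equal(abs(pp$coords[rownames(p$coords), 1]), abs(x),
               tolerance = 1e-8)
  expect_warning(genotype_pca(gm_from(rbind(c(0L, 1L), c(2L, 1L)),
                                      pops[1:2]), 5), "components")
})

test_that("gene trees reflect local haplotype structure", {
  sw <- sweep_spec("HIGH", 4e5, 5e5, f = 1)
  gm <- suppressMessages(simulate_genotypes(
    sim_config(seed = 29, chrom_length = 1e6, sweep = sw)))
  gene <- data.frame(start = 410000, end = 490000, gene_id = "swept")
  sub <- subset_sites(gm, gm$positions >= gene$start &
                        gm$positions < gene$end)
  d <- allele_sharing_distance(sub)
  hi <- names(gm$pops)[gm$pops == "HIGH"]
  expect_true(all(d[hi, hi] == 0))        # complete sweep: identical
  res <- gene_tree(gm, gene)
  expect_s3_class(res$tree, "phylo")
  # single-SNP gene distances lie in {0, 0.5, 1}
  one <- subset_sites(gm, 1)
  d1 <- allele_sharing_distance(one)
  expect_true(all(d1[upper.tri(d1)] %in% c(0, 0.5, 1)))
  expect_error(gene_tree(gm, data.frame(start = 0, end = 1,
                                        gene_id = "empty")), "empty")
})
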