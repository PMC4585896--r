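mk_windows <- function(fst, ratio, start = NULL, width = 1e5) {
  n <- length(fst)
  if (is.null(start)) start <- (seq_len(n) - 1L) * width
  data.frame(chrom = "chr1", start = start, end = start + width,
             span = width, n_snps = 10L, fst = fst, pi_ratio = ratio)
}

test_that("joint outliers select the top tail of both statistics", {
  v <- (1:100) / 100
  w <- mk_windows(v, v)
  jo <- joint_outliers(w, q = 0.05)
  expect_equal(sort(jo$selected$fst), v[96:100])
  expect_equal(jo$t_fst, unname(quantile(v, 0.95)))
  expect_equal(jo$t_ratio, unname(quantile(v, 0.95)))
  # conjunction: a window high in only one statistic is not selected
  w2 <- mk_windows(c(v, 2), c(v, 0.01))
  jo2 <- joint_outliers(w2, q = 0.05)
  expect_false(2 %in% jo2$selected$fst)
})

test_that("threshold ties are selected inclusively", {
  w <- mk_windows(rep(0.3, 50), rep(1.2, 50))
  jo <- joint_outliers(w, q = 0.05)
  expect_equal(nrow(jo$selected), 50L)    # all equal the quantile
  expect_error(joint_outliers(mk_windows(NA_real_, NA_real_)), "defined")
})

test_that("undefined windows are excluded from thresholds but reported", {
  v <- (1:40) / 40
  w <- mk_windows(c(v, NA), c(v, NA))
  jo <- joint_outliers(w, q = 0.1)
  expect_equal(jo$n_defined, 40L)
  expect_equal(jo$t_fst, unname(quantile(v, 0.9)))
})

test_that("region merging equals interval union", {
  w <- mk_windows(c(0.5, 0.6), c(2, 3), start = c(0, 1e4))
  r <- merge_regions(w)
  expect_equal(nrow(r), 1L)
  expect_equal(c(r$start, r$end), c(0, 110000))
  expect_equal(r$max_fst, 0.6)
  w2 <- mk_windows(c(0.5, 0.6), c(2, 3), start = c(0, 2e6))
  expect_equal(nrow(merge_regions(w2)), 2L)
  # abutting windows (gap 0 bp) stay separate
  w3 <- mk_windows(c(0.5, 0.6), c(2, 3), start = c(0, 1e5))
  expect_equal(nrow(merge_regions(w3)), 2L)
  # random patterns vs brute-force union over bp
  set.seed(9)
  for (rep in 1:10) {
    st <- sort(sample(0:60, 8)) * 1e4
    w <- mk_windows(runif(8), runif(8) + 1, start = st, width = 3e4)
    r <- merge_regions(w)
    covered <- sort(unique(unlist(
      lapply(1:8, function(i) seq(st[i], st[i] + 3e4 - 1, by = 1e3)))))
    merged_cov <- sort(unique(unlist(
      lapply(seq_len(nrow(r)),
             function(i) seq(r$start[i], r$end[i] - 1, by = 1e3)))))
    expect_equal(merged_cov, covered)
    expect_equal(sum(r$end - r$start),
                 length(covered) * 1e3)     # no double counting
    expect_true(all(r$start[-1] >= r$end[-nrow(r)]))
  }
})

test_that("gene assignment uses half-open overlap and set semantics", {
  regions <- merge_regions(mk_windows(c(0.5, 0.7), c(2, 2),
                                      start = c(0, 3e5)))
  genes <- data.frame(
    chrom = "chr1",
    start = c(100000, 310000, 150000, 90000),
    end = c(100500, 320000, 160000, 400001),
    gene_id = c("abut", "inside", "between", "spanning"))
  ann <- annotate_regions(regions, genes)
  # gene starting exactly at region end does not overlap
  expect_false("abut" %in% ann$genes)
  expect_true("inside" %in% ann$genes)
  expect_false("between" %in% ann$genes)
  # gene spanning both regions counted once
  expect_equal(sum(ann$genes == "spanning"), 1L)
  # brute-force all-pairs check on a 50-gene fixture
  set.seed(4)
  g50 <- data.frame(chrom = "chr1", start = sort(sample(0:70, 50)) * 2e4,
                    gene_id = sprintf("g%02d", 1:50))
  g50$end <- g50$start + 15000
  ann50 <- annotate_regions(regions, g50)
  brute <- unique(unlist(lapply(seq_len(nrow(regions)), function(i)
    g50$gene_id[g50$start < regions$end[i] & g50$end > regions$start[i]])))
  expect_setequal(ann50$genes, brute)
  expect_warning(annotate_regions(regions,
                                  transform(genes, chrom = "chrX")),
                 "chromosome")
})

test_that("targeted windows follow the 10-kb grid over the gene body", {
  gm <- rand_gm(n_samp = 10, n_sites = 200, seed = 6, chrom_length = 1e5)
  genes <- data.frame(chrom = "chr1", start = 13000, end = 38000,
                      gene_id = "g1")
  tg <- targeted_gene_stats(gm, genes, high = "A", low = "B")
  # 10-kb grid windows overlapping [13000, 38000): starts 10k, 20k, 30k
  expect_equal(tg$gene_stats$n_windows, 3L)
  ov <- tg$windows$start < 38000 & tg$windows$end > 13000
  expect_equal(sort(tg$windows$start[ov]), c(10000L, 20000L, 30000L))
  # gene with no SNPs gets an NA row
  gm2 <- subset_sites(gm, gm$positions >= 50000)
  tg2 <- targeted_gene_stats(gm2, genes, high = "A", low = "B")
  expect_true(is.na(tg2$gene_stats$mean_fst))
})

test_that("complete-sweep genes have zero focal diversity in their windows", {
  sw <- sweep_spec("HIGH", 4e5, 5e5, f = 1)
  gm <- suppressMessages(simulate_genotypes(
    sim_config(seed = 23, chrom_length = 1e6, sweep = sw)))
  genes <- data.frame(chrom = "chr1", start = 420000, end = 460000,
                      gene_id = "swept")
  tg <- targeted_gene_stats(gm, genes)
  ov <- tg$windows$start < 460000 & tg$windows$end > 420000
  expect_true(all(tg$windows$pi_high[ov] == 0))
  expect_true(all(is.na(tg$windows$pi_ratio[ov])))
  expect_true(is.na(tg$gene_stats$mean_pi_ratio))
})

test_that("Welch contrast matches the formula oracle and handles degeneracy", {
  x <- c(2.3, 1.9, 2.8, 3.1, 2.2, 2.6, 1.8, 2.9, 3.3, 2.1)
  y <- c(1.1, 0.9, 1.4, 1.2, 0.8, 1.3, 1.0, 1.5, 0.7, 1.2)
  got <- background_ttest(x, y)
  want <- oracle_welch(x, y)
  expect_equal(got$t, want$t, tolerance = 1e-12)
  expect_equal(got$df, want$df, tolerance = 1e-12)
  expect_equal(got$p, want$p, tolerance = 1e-12)
  # identical constant groups
  same <- background_ttest(rep(2, 4), rep(2, 5))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # constant but different -> degenerate separation
  degen <- background_ttest(rep(2, 4), rep(0, 4))
  expect_true(degen$degenerate)
  expect_equal(degen$p, 0)
  # strong separation with jitter
  sep <- background_ttest(c(2, 2, 2, 2) + 1e-6 * (1:4),
                          c(0, 0, 0, 0) + 1e-6 * (1:4))
  expect_lt(sep$p, 1e-6)
  expect_error(background_ttest(1, c(1, 2)), "at least 2")
})

test_that("binomial enrichment reproduces closed forms and BH", {
  sets <- data.frame(gene_id = sprintf("g%02d", 1:40),
                     category = rep(c("c1", "c2"), each = 20))
  bg <- sets$gene_id
  # all 10 selected genes in c1 (p0 = 0.5): P(X >= 10) = 2^-10
  res <- binomial_enrichment(sprintf("g%02d", 1:10), bg, sets)
  expect_equal(res$p_raw[res$category == "c1"], 2^-10)
  # k = 0 -> p = 1
  expect_equal(res$p_raw[res$category == "c2"], 1)
  # category equal to the whole background: p0 = 1 -> p = 1
  sets_all <- data.frame(gene_id = bg, category = "all")
  res_all <- binomial_enrichment(sprintf("g%02d", 1:10), bg, sets_all)
  expect_equal(res_all$p_raw, 1)
  expect_error(binomial_enrichment("nope", bg, sets), "subset")
  # empty selection -> all p = 1
  sets8 <- data.frame(gene_id = sprintf("g%02d", 1:8),
                      category = sprintf("k%d", 1:8))
  r8 <- binomial_enrichment(character(0), sets8$gene_id, sets8)
  expect_equal(r8$p_raw, rep(1, 8))
  # q-values equal a direct BH implementation, invariant to category order
  bh <- function(p) {
    n <- length(p); o <- order(p, decreasing = TRUE)
    pmin(1, cummin(n / (n:1) * p[o]))[order(o)]
  }
  set.seed(14)
  sets_r <- data.frame(gene_id = sprintf("g%02d", 1:40),
                       category = sample(sprintf("k%d", 1:6), 40, TRUE))
  sel <- sample(bg, 12)
  rr <- binomial_enrichment(sel, bg, sets_r)
  expect_equal(rr$q, bh(rr$p_raw))
  perm <- sets_r[sample(nrow(sets_r)), ]
  rp <- binomial_enrichment(sel, bg, perm)
  expect_equal(rp$q[match(rr$category, rp$category)], rr$q)
})
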