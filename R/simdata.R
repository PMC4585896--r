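#' Simulation configuration
#'
#' Parameters of the synthetic three-population divergence model: one
#' highland population (`HIGH`) and two lowland populations (`LOW1`,
#' `LOW2`), related by a clean two-split history with no migration.  `HIGH`
#' and `LOW1` merge (backwards in time) at `t_split_recent` generations,
#' and their ancestor merges with `LOW2` at `t_split_deep`.  Ancestral
#' populations take the effective size of the receiving population.
#'
#' Recombination is modelled as free recombination between independent
#' non-recombining blocks of `block_length` bp; each block coalesces under
#' its own genealogy, which gives sliding-window statistics realistic
#' between-window variation without simulating a full ancestral
#' recombination graph.
#'
#' @param seed integer RNG seed; the generator is fully deterministic given
#'   the config.
#' @param chrom_length chromosome length, bp.
#' @param n_dip named integer vector of diploid sample sizes per
#'   population.  The default (11, 11, 10) mirrors a typical small
#'   resequencing panel of one highland and two lowland groups.
#' @param Ne diploid effective size, scalar or named per-population vector.
#' @param t_split_recent,t_split_deep split times in generations
#'   (`t_split_deep > t_split_recent > 0`).
#' @param mu per-bp per-generation mutation rate.  Default `2.78e-9`.
#' @param block_length independent-block length, bp.
#' @param generation_time generations are the simulator's native time unit;
#'   this factor (years per generation, default 1.5) is only used by
#'   [years_to_generations()].
#' @param sweep optional [sweep_spec()] applied after simulation.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       chrom_length = 5e6,
                       n_dip = c(HIGH = 11L, LOW1 = 11L, LOW2 = 10L),
                       Ne = 1e4,
                       t_split_recent = 5000,
                       t_split_deep = 20000,
                       mu = 2.78e-9,
                       block_length = 1e4,
                       generation_time = 1.5,
                       sweep = NULL) {
  if (is.null(names(n_dip)) || any(!nzchar(names(n_dip))))
    stop("invalid config field 'n_dip': must be a named vector")
  if (any(n_dip < 2)) stop("invalid config field 'n_dip': need >= 2 diploids")
  if (length(Ne) == 1L) Ne <- stats::setNames(rep(Ne, length(n_dip)),
                                              names(n_dip))
  if (!all(names(n_dip) %in% names(Ne)))
    stop("invalid config field 'Ne': must name every population")
  if (any(Ne <= 0)) stop("invalid config field 'Ne': must be positive")
  if (!(t_split_deep > t_split_recent && t_split_recent > 0))
    stop("invalid config field 't_split_*': need t_split_deep > t_split_recent > 0")
  if (mu < 0) stop("invalid config field 'mu': must be >= 0")
  if (chrom_length < 1) stop("invalid config field 'chrom_length': must be >= 1")
  if (block_length < 1) stop("invalid config field 'block_length'")
  if (!is.null(sweep) && !inherits(sweep, "sweep_spec"))
    stop("invalid config field 'sweep': use sweep_spec()")
  structure(list(seed = as.integer(seed), chrom_length = as.integer(chrom_length),
                 n_dip = n_dip, Ne = Ne[names(n_dip)],
                 t_split_recent = t_split_recent, t_split_deep = t_split_deep,
                 mu = mu, block_length = as.integer(block_length),
                 generation_time = generation_time, sweep = sweep),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", format(x$chrom_length, big.mark = ","), "bp;",
      paste(sprintf("%s=%d", names(x$n_dip), x$n_dip), collapse = " "),
      sprintf("diploids; mu=%g; splits %g/%g gen; seed %d\n",
              x$mu, x$t_split_recent, x$t_split_deep, x$seed))
  if (!is.null(x$sweep))
    cat(sprintf("sweep: %s [%d,%d) f=%g\n", x$sweep$target_pop,
                x$sweep$start, x$sweep$end, x$sweep$f))
  invisible(x)
}

#' Convert years to generations
#' @param years time in years.
#' @param generation_time years per generation (default 1.5).
#' @return time in generations.
#' @export
years_to_generations <- function(years, generation_time = 1.5) {
  years / generation_time
}

#' Sweep specification
#'
#' A phenomenological hard-sweep footprint: inside `[start, end)` a
#' fraction `f` of the target population's haplotypes is replaced by a
#' single resident core haplotype, producing locally reduced diversity and
#' elevated differentiation -- the signal pattern a sweep scan detects.
#'
#' @param target_pop population label carrying the sweep.
#' @param start,end 0-based half-open interval, bp.
#' @param f fraction of haplotypes replaced, in (0, 1].
#' @return an object of class `sweep_spec`.
#' @export
sweep_spec <- function(target_pop, start, end, f = 0.9) {
  if (!(f > 0 && f <= 1)) stop("sweep strength f must be in (0, 1]")
  if (!(start >= 0 && start < end)) stop("need 0 <= start < end")
  structure(list(target_pop = target_pop, start = as.integer(start),
                 end = as.integer(end), f = f), class = "sweep_spec")
}

# Structured Kingman coalescent for one non-recombining block.
# pop_ids: integer population index per haploid lineage (1..P);
# Ne: diploid sizes per population; merges: list of (time, from, into),
# sorted by time.  Returns parent pointers and node times (generations);
# leaves are nodes 1..n with time 0, internal nodes are created in time
# order so a parent always has a higher index than its children.
.sim_block_tree <- function(pop_ids, Ne, merges) {
  n <- length(pop_ids)
  n_pop <- length(Ne)
  parent <- integer(2L * n - 1L)
  node_time <- numeric(2L * n - 1L)
  active <- seq_len(n)
  act_pop <- pop_ids
  t <- 0
  nxt <- n + 1L
  mi <- 1L
  while (length(active) > 1L) {
    k <- tabulate(act_pop, nbins = n_pop)
    rate_p <- k * (k - 1) / 2 / (2 * Ne)
    tot <- sum(rate_p)
    dt <- if (tot > 0) stats::rexp(1L, tot) else Inf
    if (mi <= length(merges) && t + dt > merges[[mi]]$time) {
      t <- merges[[mi]]$time
      act_pop[act_pop == merges[[mi]]$from] <- merges[[mi]]$into
      mi <- mi + 1L
      next
    }
    if (!is.finite(dt))
      stop("coalescent stalled: disconnected demography")
    t <- t + dt
    p <- sample.int(n_pop, 1L, prob = rate_p)
    idx <- which(act_pop == p)
    pair <- idx[sample.int(length(idx), 2L)]
    parent[active[pair]] <- nxt
    node_time[nxt] <- t
    active <- c(active[-pair], nxt)
    act_pop <- c(act_pop[-pair], p)
    nxt <- nxt + 1L
  }
  list(parent = parent, time = node_time, n = n, root = nxt - 1L)
}

# Drop infinite-sites mutations on a block genealogy.  Returns a 0/1
# haplotype matrix (n x n_mut) plus 0-based positions within the block.
.mutate_block <- function(tree, mu, block_start, block_len) {
  n <- tree$n
  root <- tree$root
  nb <- root - 1L                          # non-root nodes carry branches
  blen <- tree$time[tree$parent[seq_len(nb)]] - tree$time[seq_len(nb)]
  nmut <- stats::rpois(nb, mu * block_len * blen)
  tot <- sum(nmut)
  if (tot == 0L)
    return(list(hap = matrix(0L, n, 0L), pos = integer(0)))
  tot <- min(tot, block_len)               # infinite-sites, finite block
  # leaves below each node, accumulated child-to-parent (children always
  # have lower indices)
  desc <- vector("list", root)
  for (v in seq_len(n)) desc[[v]] <- v
  for (v in seq_len(nb)) {
    p <- tree$parent[v]
    desc[[p]] <- c(desc[[p]], desc[[v]])
  }
  branch_of <- rep.int(seq_len(nb), nmut)[seq_len(tot)]
  hap <- matrix(0L, n, tot)
  for (j in seq_len(tot)) hap[desc[[branch_of[j]]], j] <- 1L
  pos <- block_start + sort(sample.int(block_len, tot)) - 1L
  # mutations get positions in drawn (arbitrary) branch order; order
  # columns by position
  list(hap = hap, pos = pos)
}

#' Simulate genotypes under the three-population divergence model
#'
#' Runs an independent-block structured coalescent under the demography in
#' `config`, drops infinite-sites mutations, pairs haplotypes into
#' diploids, and (optionally) plants the configured sweep.  Deterministic
#' given the config (which includes the seed).
#'
#' @param config a [sim_config()].
#' @param vcf optional path; when given, the result is also written as VCF
#'   4.2 via [write_vcf()].
#' @return a [genotype_matrix()] with haplotypes stored.
#' @export
simulate_genotypes <- function(config, vcf = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  pops <- names(config$n_dip)
  n_hap <- 2L * config$n_dip
  pop_ids <- rep(seq_along(pops), n_hap)
  merges <- .default_merges(config)
  starts <- seq(0L, config$chrom_length - 1L, by = config$block_length)
  hap_blocks <- vector("list", length(starts))
  pos_blocks <- vector("list", length(starts))
  for (b in seq_along(starts)) {
    blen <- min(config$block_length, config$chrom_length - starts[b])
    tree <- .sim_block_tree(pop_ids, config$Ne, merges)
    mb <- .mutate_block(tree, config$mu, starts[b], blen)
    hap_blocks[[b]] <- mb$hap
    pos_blocks[[b]] <- mb$pos
  }
  hap <- do.call(cbind, hap_blocks)
  pos <- unlist(pos_blocks)
  samples <- unlist(lapply(seq_along(pops), function(i)
    sprintf("%s_%02d", pops[i], seq_len(config$n_dip[i]))))
  geno <- hap[seq(1L, nrow(hap), by = 2L), , drop = FALSE] +
    hap[seq(2L, nrow(hap), by = 2L), , drop = FALSE]
  rownames(geno) <- samples
  gm <- genotype_matrix(geno, pos, "chr1", config$chrom_length,
                        stats::setNames(rep(pops, config$n_dip), samples),
                        haplo = hap)
  if (!is.null(config$sweep))
    gm <- plant_sweep(gm, config$sweep, seed = config$seed + 1L)
  if (!is.null(vcf)) write_vcf(gm, vcf)
  gm
}

# demography helper: HIGH joins LOW1 at the recent split, their ancestor
# joins LOW2 at the deep split; for other population sets, pops join the
# last population sequentially at the two split times.
.default_merges <- function(config) {
  pops <- names(config$n_dip)
  if (identical(sort(pops), sort(c("HIGH", "LOW1", "LOW2")))) {
    list(list(time = config$t_split_recent, from = match("HIGH", pops),
              into = match("LOW1", pops)),
         list(time = config$t_split_deep, from = match("LOW1", pops),
              into = match("LOW2", pops)))
  } else if (length(pops) == 1L) {
    list()
  } else {
    times <- seq(config$t_split_recent, config$t_split_deep,
                 length.out = length(pops) - 1L)
    lapply(seq_len(length(pops) - 1L), function(i)
      list(time = times[i], from = i, into = length(pops)))
  }
}

#' Plant a hard-sweep footprint into a genotype matrix
#'
#' Inside the sweep interval a fraction `f` of the target population's
#' haplotypes is overwritten with one randomly chosen resident haplotype
#' (the "core" haplotype).  Sites left monomorphic across all samples are
#' dropped, with a message giving the count.
#'
#' @param gm a [genotype_matrix()] carrying haplotypes.
#' @param sweep a [sweep_spec()].
#' @param seed RNG seed for the choice of core and replaced haplotypes.
#' @return the modified `genotype_matrix`.
#' @export
plant_sweep <- function(gm, sweep, seed = 1L) {
  stopifnot(inherits(sweep, "sweep_spec"))
  if (is.null(gm$haplo))
    stop("plant_sweep needs stored haplotypes")
  if (!sweep$target_pop %in% gm$pops)
    stop("target population not present: ", sweep$target_pop)
  if (sweep$end > gm$chrom_length)
    stop("sweep interval exceeds chromosome length")
  set.seed(seed)
  samp <- which(gm$pops == sweep$target_pop)
  haps <- sort(c(2L * samp - 1L, 2L * samp))
  in_iv <- gm$positions >= sweep$start & gm$positions < sweep$end
  n_rep <- ceiling(sweep$f * length(haps))
  core <- haps[sample.int(length(haps), 1L)]
  repl <- haps[sample.int(length(haps), n_rep)]
  gm$haplo[repl, in_iv] <- rep(gm$haplo[core, in_iv, drop = FALSE],
                               each = length(repl))
  geno <- gm$haplo[seq(1L, nrow(gm$haplo), 2L), , drop = FALSE] +
    gm$haplo[seq(2L, nrow(gm$haplo), 2L), , drop = FALSE]
  dimnames(geno) <- dimnames(gm$geno)
  gm$geno <- geno
  mono <- colSums(gm$haplo) %in% c(0L, nrow(gm$haplo))
  if (any(mono))
    message(sum(mono), " site(s) monomorphic after sweep planting; dropped")
  subset_sites(gm, !mono)
}

#' Plan of read-pair defect classes for FASTQ simulation
#'
#' @param n_clean,n_highN,n_adapter,n_lowqual,n_dup non-negative counts of
#'   read pairs per class; the duplicate class consists of `n_dup`
#'   byte-identical copies of one designated pair, the first copy being
#'   the kept original (truth class `dup_original`).
#' @param adapter_seq adapter nucleotide sequence embedded in the adapter
#'   class.
#' @return an object of class `read_defect_plan`.
#' @export
read_defect_plan <- function(n_clean = 0L, n_highN = 0L, n_adapter = 0L,
                             n_lowqual = 0L, n_dup = 0L,
                             adapter_seq = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA") {
  counts <- c(n_clean, n_highN, n_adapter, n_lowqual, n_dup)
  if (any(counts < 0)) stop("defect counts must be >= 0")
  structure(list(n_clean = n_clean, n_highN = n_highN,
                 n_adapter = n_adapter, n_lowqual = n_lowqual,
                 n_dup = n_dup, adapter_seq = adapter_seq),
            class = "read_defect_plan")
}

.rand_seq <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

#' Simulate paired-end FASTQ files with planted defects
#'
#' Emits 100-bp paired reads of five classes -- clean; >= 10% N; > 10 nt of
#' adapter sequence embedded; > 50% of bases below phred 5; exact duplicate
#' pairs -- plus a truth TSV labelling every pair, so read-QC filters can
#' be checked against planted truth exactly.
#'
#' @param plan a [read_defect_plan()].
#' @param prefix output path prefix; writes `<prefix>_1.fastq`,
#'   `<prefix>_2.fastq` and `<prefix>_truth.tsv`.
#' @param seed RNG seed.
#' @param read_len read length, bp (default 100).
#' @return invisibly, a list with the three paths and the truth data frame.
#' @export
simulate_fastq <- function(plan, prefix, seed = 1L, read_len = 100L) {
  stopifnot(inherits(plan, "read_defect_plan"))
  set.seed(seed)
  ids <- character(0); s1 <- character(0); s2 <- character(0)
  q1 <- character(0); q2 <- character(0); cls <- character(0)
  # random sequences, rejecting chance adapter matches so planted classes
  # stay exactly the truth
  rand_ok <- function(n) {
    out <- .rand_seq(n, read_len)
    for (i in seq_len(n)) {
      tries <- 0L
      while (fails_adapter(out[i], plan$adapter_seq)) {
        out[i] <- .rand_seq(1L, read_len)
        if ((tries <- tries + 1L) > 100L)
          stop("cannot draw an adapter-free random read")
      }
    }
    out
  }
  good_q <- function(n) vapply(seq_len(n), function(i)
    paste(rawToChar(as.raw(33L + sample(30:40, read_len, TRUE))),
          collapse = ""), character(1))
  add <- function(n, class, f1, f2, fq1 = good_q, fq2 = good_q) {
    if (n == 0) return()
    ids <<- c(ids, sprintf("%s_%d", class, seq_len(n)))
    s1 <<- c(s1, f1(n)); s2 <<- c(s2, f2(n))
    q1 <<- c(q1, fq1(n)); q2 <<- c(q2, fq2(n))
    cls <<- c(cls, rep(class, n))
  }
  add(plan$n_clean, "clean", rand_ok, rand_ok)
  # >= 10% N in mate 1
  n_needed <- ceiling(0.10 * read_len)
  add(plan$n_highN, "highN",
      function(n) vapply(rand_ok(n), function(s) {
        at <- sample.int(read_len, n_needed)
        v <- strsplit(s, "")[[1]]; v[at] <- "N"
        paste(v, collapse = "")
      }, character(1), USE.NAMES = FALSE),
      rand_ok)
  # adapter: embed a (>10 nt) adapter prefix into mate 1
  ad_len <- min(15L, nchar(plan$adapter_seq))
  if (plan$n_adapter > 0 && ad_len <= 10L)
    stop("adapter_seq too short to plant a >10 nt match")
  add(plan$n_adapter, "adapter",
      function(n) vapply(rand_ok(n), function(s) {
        at <- sample.int(read_len - ad_len + 1L, 1L)
        paste0(substr(s, 1, at - 1), substr(plan$adapter_seq, 1, ad_len),
               substr(s, at + ad_len, read_len))
      }, character(1), USE.NAMES = FALSE),
      rand_ok)
  # low quality: > 50% of mate-1 bases at phred 2
  n_low <- floor(0.5 * read_len) + 1L
  add(plan$n_lowqual, "lowqual", rand_ok, rand_ok,
      fq1 = function(n) vapply(seq_len(n), function(i) {
        q <- 33L + sample(30:40, read_len, TRUE)
        q[sample.int(read_len, n_low)] <- 33L + 2L
        rawToChar(as.raw(q))
      }, character(1)))
  # duplicate class: n_dup byte-identical copies of one designated pair;
  # the first occurrence is the kept original
  if (plan$n_dup > 0) {
    d1 <- rand_ok(1L); d2 <- rand_ok(1L)
    dq1 <- good_q(1L); dq2 <- good_q(1L)
    add(plan$n_dup, "duplicate",
        function(n) rep(d1, n), function(n) rep(d2, n),
        fq1 = function(n) rep(dq1, n), fq2 = function(n) rep(dq2, n))
    cls[which(cls == "duplicate")[1]] <- "dup_original"
  }
  fq_lines <- function(id, s, q, mate)
    as.vector(rbind(sprintf("@%s/%d", id, mate), s, "+", q))
  p1 <- paste0(prefix, "_1.fastq"); p2 <- paste0(prefix, "_2.fastq")
  pt <- paste0(prefix, "_truth.tsv")
  writeLines(if (length(ids)) fq_lines(ids, s1, q1, 1L) else character(0), p1)
  writeLines(if (length(ids)) fq_lines(ids, s2, q2, 2L) else character(0), p2)
  truth <- data.frame(id = ids, class = cls, stringsAsFactors = FALSE)
  utils::write.table(truth, pt, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(fastq1 = p1, fastq2 = p2, truth_path = pt, truth = truth))
}

#' Generate a synthetic gene annotation and gene-set table
#'
#' Places `n_genes` non-overlapping gene intervals on the chromosome,
#' guarantees at least one gene inside the sweep interval when a sweep is
#' given, assigns each gene to one of `n_categories` synthetic pathway
#' categories, and writes a BED6 file plus a gene->category TSV and a
#' truth table flagging sweep genes.
#'
#' @param chrom_length chromosome length, bp.
#' @param n_genes number of genes (>= 1).
#' @param sweep optional [sweep_spec()].
#' @param seed RNG seed.
#' @param gene_length gene length, bp.
#' @param n_categories number of synthetic categories.
#' @param chrom chromosome name.
#' @param bed,genesets,truth optional output paths; written when given.
#' @return a list with `genes` (data frame: chrom, start, end, gene_id,
#'   in_sweep), and `gene_sets` (data frame: gene_id, category).
#' @export
make_annotation <- function(chrom_length, n_genes, sweep = NULL, seed = 1L,
                            gene_length = 2e4, n_categories = 5L,
                            chrom = "chr1", bed = NULL, genesets = NULL,
                            truth = NULL) {
  if (n_genes < 1) stop("n_genes must be >= 1")
  set.seed(seed)
  n_slots <- floor(chrom_length / gene_length)
  if (n_slots < n_genes)
    stop("genes cannot fit without overlap: ", n_genes, " genes of ",
         gene_length, " bp on ", chrom_length, " bp")
  slots <- sort(sample.int(n_slots, n_genes)) - 1L
  starts <- slots * as.integer(gene_length)
  ends <- starts + as.integer(gene_length)
  if (!is.null(sweep)) {
    # ensure at least one gene fully inside the sweep interval
    hit <- starts < sweep$end & ends > sweep$start
    inside_slot <- floor(sweep$start / gene_length) + 1L
    inside_start <- (inside_slot - 1L) * as.integer(gene_length)
    if (inside_start < sweep$start) {
      inside_slot <- inside_slot + 1L
      inside_start <- inside_start + as.integer(gene_length)
    }
    if (inside_start + gene_length > sweep$end)
      stop("sweep interval too short to contain a gene")
    if (!any(starts >= sweep$start & ends <= sweep$end)) {
      drop <- if (any(!hit)) which(!hit)[1] else 1L
      starts[drop] <- inside_start
      ends[drop] <- inside_start + as.integer(gene_length)
      ord <- order(starts)
      starts <- starts[ord]; ends <- ends[ord]
    }
  }
  starts <- as.integer(starts)
  ends <- as.integer(ends)
  gene_id <- sprintf("gene%03d", seq_len(n_genes))
  in_sweep <- if (is.null(sweep)) rep(FALSE, n_genes) else
    starts < sweep$end & ends > sweep$start
  genes <- data.frame(chrom = chrom, start = starts, end = ends,
                      gene_id = gene_id, in_sweep = in_sweep,
                      stringsAsFactors = FALSE)
  gene_sets <- data.frame(
    gene_id = gene_id,
    category = sprintf("pathway%02d", sample.int(n_categories, n_genes,
                                                 replace = TRUE)),
    stringsAsFactors = FALSE)
  if (!is.null(bed))
    utils::write.table(
      data.frame(genes$chrom, genes$start, genes$end, genes$gene_id, 0L, "+"),
      bed, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (!is.null(genesets))
    utils::write.table(gene_sets, genesets, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(truth))
    utils::write.table(genes, truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  list(genes = genes, gene_sets = gene_sets)
}
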