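#' Pipeline configuration
#'
#' Bundles input paths and stage parameters for [run_pipeline()].  Stages
#' whose inputs are absent are skipped (a VCF-only run skips read QC).
#'
#' @param out_dir output directory (created if missing).
#' @param vcf genotype VCF path (biallelic diploid SNPs).
#' @param pops sample-to-population TSV path (see [read_pop_map()]), or a
#'   named character vector.
#' @param fastq1,fastq2 optional paired FASTQ for the read-QC stage.
#' @param adapter adapter sequence for read QC.
#' @param genes optional BED/GFF3 gene annotation.
#' @param gene_sets optional gene->category TSV for enrichment.
#' @param high,low focal and (pooled) reference population labels.
#' @param window,step scan window and step, bp.
#' @param q outlier fraction per statistic.
#' @param maf,callrate analysis-set thresholds.
#' @param fst F_ST estimator, "hudson" or "wc".
#' @param site_filter apply [site_filter()] to the VCF first?
#' @param seed top-level seed recorded in the log (analysis stages are
#'   deterministic; the seed also derives per-stage seeds for any
#'   stochastic stage).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, vcf = NULL, pops = NULL,
                            fastq1 = NULL, fastq2 = NULL,
                            adapter = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA",
                            genes = NULL, gene_sets = NULL,
                            high = "HIGH", low = c("LOW1", "LOW2"),
                            window = 1e5, step = 1e4, q = 0.05,
                            maf = 0.1, callrate = 0.9,
                            fst = c("hudson", "wc"),
                            site_filter = TRUE, seed = 1L) {
  fst <- match.arg(fst)
  for (p in c(vcf, fastq1, fastq2, genes, gene_sets,
              if (is.character(pops) && length(pops) == 1L) pops))
    if (!file.exists(p)) stop("input file does not exist: ", p)
  if (!(q > 0 && q <= 1)) stop("q must be in (0, 1]")
  structure(list(out_dir = out_dir, vcf = vcf, pops = pops,
                 fastq1 = fastq1, fastq2 = fastq2, adapter = adapter,
                 genes = genes, gene_sets = gene_sets, high = high,
                 low = low, window = window, step = step, q = q,
                 maf = maf, callrate = callrate, fst = fst,
                 site_filter = site_filter, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the selection-scan pipeline
#'
#' Sequences the stages read QC -> VCF site filter -> analysis-set filter
#' -> windowed statistics -> joint outlier scan -> region merging -> gene
#' annotation -> targeted gene statistics -> structure (NJ tree, PCA) ->
#' gene-set enrichment, writing each stage's artifact into the output
#' directory along with `summary.tsv` (per-stage counts) and `log.txt`
#' (seed and full parameter set).  Stages communicate via files in
#' standard formats, so each stage is independently inspectable.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list of in-memory stage results (`qc`, `filter`,
#'   `gm`, `windows`, `outliers`, `regions`, `genes`, `gene_stats`,
#'   `tree`, `pca`, `enrichment`, `summary`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  art <- function(f) file.path(config$out_dir, f)
  summary_rows <- list()
  note <- function(stage, key, value)
    summary_rows[[length(summary_rows) + 1L]] <<-
      data.frame(stage = stage, key = key, value = as.character(value))
  cfg_flat <- config[!vapply(config, is.null, logical(1))]
  writeLines(c(sprintf("seed\t%d", config$seed),
               vapply(names(cfg_flat), function(k)
                 sprintf("%s\t%s", k,
                         paste(format(cfg_flat[[k]]), collapse = ",")),
                 character(1))),
             art("log.txt"))
  res <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if (!is.null(config$fastq1)) {
    res$qc <- stage("readqc", run_readqc(config$fastq1, config$fastq2,
                                         config$adapter,
                                         out_prefix = art("qc")))
    note("readqc", "input_pairs", res$qc$n_input_pairs)
    note("readqc", "kept_pairs", res$qc$n_kept_pairs)
    note("readqc", "retained_fraction",
         sprintf("%.4f", res$qc$retained_fraction))
  }

  if (is.null(config$vcf)) {
    summary <- do.call(rbind, summary_rows)
    utils::write.table(summary, art("summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    res$summary <- summary
    return(invisible(res))
  }

  pops <- if (is.character(config$pops) && length(config$pops) == 1L)
    read_pop_map(config$pops) else config$pops
  vcf_in <- config$vcf
  if (isTRUE(config$site_filter)) {
    res$filter <- stage("site_filter",
                        site_filter(vcf_in, out = art("filtered.vcf")))
    for (k in names(res$filter$counts))
      note("site_filter", k, res$filter$counts[[k]])
    vcf_in <- art("filtered.vcf")
  }
  gm <- stage("analysis_set", {
    g <- read_vcf_genotypes(vcf_in, pops)
    analysis_set_filter(g, maf = config$maf, callrate = config$callrate)
  })
  for (k in names(attr(gm, "counts")))
    note("analysis_set", k, attr(gm, "counts")[[k]])
  res$gm <- gm

  res$windows <- stage("windowed_stats",
                       windowed_stats(gm, high = config$high,
                                      low = config$low,
                                      window = config$window,
                                      step = config$step,
                                      fst = config$fst))
  utils::write.table(res$windows, art("windows.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  note("scan", "windows", nrow(res$windows))

  res$outliers <- stage("joint_outliers",
                        joint_outliers(res$windows, q = config$q))
  writeLines(c(sprintf("t_fst\t%.6g", res$outliers$t_fst),
               sprintf("t_pi_ratio\t%.6g", res$outliers$t_ratio)),
             art("thresholds.txt"))
  utils::write.table(res$outliers$selected, art("selected_windows.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  note("scan", "selected_windows", nrow(res$outliers$selected))
  note("scan", "t_fst", sprintf("%.6g", res$outliers$t_fst))
  note("scan", "t_pi_ratio", sprintf("%.6g", res$outliers$t_ratio))

  res$regions <- stage("merge_regions",
                       merge_regions(res$outliers$selected))
  utils::write.table(
    data.frame(res$regions$chrom, res$regions$start, res$regions$end,
               sprintf("region%03d", seq_len(nrow(res$regions)))),
    art("regions.bed"), sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  note("scan", "regions", nrow(res$regions))

  if (!is.null(config$genes)) {
    genes <- stage("annotate", read_genes(config$genes))
    ann <- stage("annotate", annotate_regions(res$regions, genes))
    res$regions <- ann$regions
    res$genes <- ann$genes
    writeLines(ann$genes, art("selected_genes.txt"))
    note("annotate", "selected_genes", length(ann$genes))
    tg <- stage("targeted", targeted_gene_stats(
      gm, genes[genes$gene_id %in% ann$genes, , drop = FALSE],
      high = config$high, low = config$low, fst = config$fst))
    res$gene_stats <- tg$gene_stats
    utils::write.table(tg$gene_stats, art("targeted_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
    if (!is.null(config$gene_sets) && length(ann$genes)) {
      sets <- stage("enrichment", read_gene_sets(config$gene_sets))
      res$enrichment <- stage("enrichment",
                              binomial_enrichment(ann$genes,
                                                  genes$gene_id, sets))
      utils::write.table(res$enrichment, art("enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      note("enrichment", "categories", nrow(res$enrichment))
      note("enrichment", "significant", sum(res$enrichment$significant))
    }
  }

  res$tree <- stage("structure", {
    nj <- neighbor_joining(allele_sharing_distance(gm))
    writeLines(nj$newick, art("tree.nwk"))
    nj
  })
  res$pca <- stage("structure", {
    pca <- genotype_pca(gm, n_components = min(10L, nrow(gm$geno) - 1L))
    utils::write.table(
      data.frame(sample = rownames(pca$coords), population = pca$pops,
                 pca$coords, check.names = FALSE),
      art("pca.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    pca
  })
  note("structure", "pc1_explained",
       sprintf("%.4f", res$pca$explained[1]))

  summary <- do.call(rbind, summary_rows)
  utils::write.table(summary, art("summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  res$summary <- summary
  invisible(res)
}
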