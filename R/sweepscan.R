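#' Joint top-quantile outlier windows
#'
#' Computes the empirical `1 - q` quantile (linear interpolation, type 7)
#' of `fst` and of `pi_ratio` over windows where both are defined, and
#' selects windows with `fst >= t_fst` AND `pi_ratio >= t_ratio`
#' (inclusive, so threshold ties are selected).  The two thresholds are
#' the data-set analogues of the fixed cutoffs a scan on real data would
#' report.
#'
#' @param windows a `window_stats` data frame (see [windowed_stats()]).
#' @param q outlier fraction per statistic (default 0.05).
#' @return a list: `selected` (subset of `windows`), `t_fst`, `t_ratio`,
#'   `n_defined`.
#' @export
joint_outliers <- function(windows, q = 0.05) {
  ok <- !is.na(windows$fst) & !is.na(windows$pi_ratio)
  if (!any(ok)) stop("no window has both fst and pi_ratio defined")
  if (sum(ok) < 20)
    warning("fewer than 20 defined windows; quantile thresholds unstable")
  t_fst <- stats::quantile(windows$fst[ok], 1 - q, type = 7, names = FALSE)
  t_ratio <- stats::quantile(windows$pi_ratio[ok], 1 - q, type = 7,
                             names = FALSE)
  sel <- ok & windows$fst >= t_fst & windows$pi_ratio >= t_ratio
  list(selected = windows[sel, , drop = FALSE], t_fst = t_fst,
       t_ratio = t_ratio, n_defined = sum(ok))
}

#' Merge selected windows into sweep regions
#'
#' Overlapping selected windows (sharing >= 1 bp under half-open
#' coordinates; abutting windows are not merged) are combined into
#' maximal disjoint regions, recording per-region window counts and
#' maxima of the two scan statistics.
#'
#' @param selected data frame of selected windows (needs chrom, start,
#'   end, fst, pi_ratio).
#' @return a `sweep_regions` data frame: chrom, start, end, n_windows,
#'   max_fst, max_pi_ratio.
#' @export
merge_regions <- function(selected) {
  if (nrow(selected) == 0) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_windows = integer(0),
                      max_fst = numeric(0), max_pi_ratio = numeric(0))
    class(out) <- c("sweep_regions", "data.frame")
    return(out)
  }
  sel <- selected[order(selected$chrom, selected$start, selected$end), ]
  grp <- integer(nrow(sel))
  g <- 1L
  grp[1] <- g
  cur_end <- sel$end[1]
  for (i in seq_len(nrow(sel))[-1]) {
    if (sel$chrom[i] != sel$chrom[i - 1] || sel$start[i] >= cur_end) {
      g <- g + 1L
      cur_end <- sel$end[i]
    } else {
      cur_end <- max(cur_end, sel$end[i])
    }
    grp[i] <- g
  }
  out <- do.call(rbind, lapply(split(sel, grp), function(d)
    data.frame(chrom = d$chrom[1], start = min(d$start), end = max(d$end),
               n_windows = nrow(d), max_fst = max(d$fst),
               max_pi_ratio = max(d$pi_ratio), stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  class(out) <- c("sweep_regions", "data.frame")
  out
}

#' Read a gene annotation (BED or GFF3)
#'
#' Uses rtracklayer to import the annotation and returns a 0-based
#' half-open gene table.  For GFF3, `gene` features are used (falling back
#' to all features when none are typed `gene`), named by their `ID` or
#' `Name` attribute.
#'
#' @param path BED or GFF3 file.
#' @return data frame: chrom, start, end, gene_id.
#' @export
read_genes <- function(path) {
  gr <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gr)
  if ("type" %in% names(md) && any(md$type == "gene"))
    gr <- gr[md$type == "gene"]
  md <- S4Vectors::mcols(gr)
  id <- if ("name" %in% names(md)) md$name
        else if ("ID" %in% names(md)) md$ID
        else if ("Name" %in% names(md)) md$Name
        else sprintf("gene%03d", seq_along(gr))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             gene_id = as.character(id), stringsAsFactors = FALSE)
}

#' Read a gene-set membership table
#' @param path TSV with columns gene_id, category (header optional).
#' @return data frame: gene_id, category.
#' @export
read_gene_sets <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df)[1:2] <- c("gene_id", "category")
  if (identical(tolower(df$gene_id[1]), "gene_id")) df <- df[-1, ]
  df[, c("gene_id", "category")]
}

#' Annotate sweep regions with overlapping genes
#'
#' A gene is assigned to a region when the two intervals share at least
#' 1 bp under half-open coordinates (a gene starting exactly at a region's
#' end does not overlap).  A gene spanning several regions enters the
#' selected gene set once.
#'
#' @param regions a `sweep_regions` data frame (see [merge_regions()]).
#' @param genes gene table (see [read_genes()]).
#' @return a list: `regions` (with a `gene_ids` comma-separated column),
#'   `genes` (character vector, the selected gene set).
#' @export
annotate_regions <- function(regions, genes) {
  if (nrow(regions) && !any(genes$chrom %in% regions$chrom))
    warning("no gene shares a chromosome name with the regions")
  gene_ids <- character(nrow(regions))
  hit <- character(0)
  for (i in seq_len(nrow(regions))) {
    ov <- genes$chrom == regions$chrom[i] &
      genes$start < regions$end[i] & genes$end > regions$start[i]
    gene_ids[i] <- paste(genes$gene_id[ov], collapse = ",")
    hit <- c(hit, genes$gene_id[ov])
  }
  regions$gene_ids <- gene_ids
  list(regions = regions, genes = unique(hit))
}

#' Targeted per-gene statistics against the genome background
#'
#' Runs a higher-resolution (default 10-kb tiling) window analysis and,
#' for each gene, averages `fst`, `pi_ratio` and `d_diff` over the grid
#' windows overlapping the gene body (half-open overlap).
#'
#' @param gm a [genotype_matrix()].
#' @param genes gene table (chrom, start, end, gene_id).
#' @param high,low population labels as in [windowed_stats()].
#' @param window,step fine window and step size, bp (default 10-kb
#'   tiling).
#' @param fst F_ST estimator.
#' @return a list: `gene_stats` (per gene: gene_id, n_windows, mean_fst,
#'   mean_pi_ratio, mean_d_diff), `windows` (the fine `window_stats`).
#' @export
targeted_gene_stats <- function(gm, genes, high = "HIGH",
                                low = c("LOW1", "LOW2"), window = 1e4,
                                step = 1e4, fst = c("hudson", "wc")) {
  win <- windowed_stats(gm, high = high, low = low, window = window,
                        step = step, fst = fst)
  gs <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    ov <- win$chrom == genes$chrom[i] & win$start < genes$end[i] &
      win$end > genes$start[i]
    w <- win[ov, , drop = FALSE]
    data.frame(gene_id = genes$gene_id[i], n_windows = sum(ov),
               mean_fst = if (any(!is.na(w$fst)))
                 mean(w$fst, na.rm = TRUE) else NA_real_,
               mean_pi_ratio = if (any(!is.na(w$pi_ratio)))
                 mean(w$pi_ratio, na.rm = TRUE) else NA_real_,
               mean_d_diff = if (any(!is.na(w$d_diff)))
                 mean(w$d_diff, na.rm = TRUE) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(gene_stats = gs, windows = win)
}

#' Welch two-sample t-test of candidate values against the background
#'
#' Thin wrapper around [stats::t.test()] (two-sided, unequal variances)
#' with explicit degenerate-case handling: when both groups have zero
#' variance, returns `t = 0, p = 1` for equal means and a `degenerate`
#' flag with `p = 0` for unequal means.
#'
#' @param candidate,background numeric vectors (each >= 2 finite values).
#' @return list: `t`, `df`, `p`, `degenerate`.
#' @export
background_ttest <- function(candidate, background) {
  candidate <- candidate[is.finite(candidate)]
  background <- background[is.finite(background)]
  if (length(candidate) < 2 || length(background) < 2)
    stop("both groups need at least 2 finite values")
  if (stats::var(candidate) == 0 && stats::var(background) == 0) {
    if (mean(candidate) == mean(background))
      return(list(t = 0, df = NA_real_, p = 1, degenerate = TRUE))
    return(list(t = sign(mean(candidate) - mean(background)) * Inf,
                df = NA_real_, p = 0, degenerate = TRUE))
  }
  tt <- stats::t.test(candidate, background, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, degenerate = FALSE)
}

#' Binomial gene-set enrichment with FDR control
#'
#' For each category, tests whether the selected gene set contains more
#' category members than expected from the background: with `n` selected
#' genes, `K` of `N` background genes in the category and `k` selected
#' genes in the category, the raw p-value is the upper-tail binomial
#' probability `P(X >= k)` for `X ~ Bin(n, K/N)`; q-values are
#' Benjamini-Hochberg adjusted across categories.
#'
#' @param selected character vector of selected gene ids (must be a
#'   subset of `background`).
#' @param background character vector of all gene ids (the universe).
#' @param gene_sets data frame with columns gene_id, category.
#' @param alpha significance level on q (default 0.05).
#' @return data frame: category, k, n, K, N, p_raw, q, significant.
#' @export
binomial_enrichment <- function(selected, background, gene_sets,
                                alpha = 0.05) {
  selected <- unique(selected)
  background <- unique(background)
  if (!all(selected %in% background))
    stop("selected gene set must be a subset of the background")
  gene_sets <- gene_sets[gene_sets$gene_id %in% background, , drop = FALSE]
  cats <- sort(unique(gene_sets$category))
  n <- length(selected)
  N <- length(background)
  res <- do.call(rbind, lapply(cats, function(cat) {
    members <- gene_sets$gene_id[gene_sets$category == cat]
    K <- length(unique(members))
    k <- length(intersect(selected, members))
    p0 <- K / N
    p <- if (n == 0 || k == 0) 1
         else stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
    data.frame(category = cat, k = k, n = n, K = K, N = N, p_raw = p,
               stringsAsFactors = FALSE)
  }))
  res$q <- stats::p.adjust(res$p_raw, method = "BH")
  res$significant <- res$q < alpha
  res
}
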