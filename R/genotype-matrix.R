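#' Genotype matrix container
#'
#' The central data structure of the package: diploid genotypes for a set of
#' samples at biallelic SNPs on one chromosome, together with population
#' labels.  Genotypes are coded as alternate-allele counts (0, 1, 2) with
#' `NA` for missing.  Positions are 0-based and strictly increasing;
#' half-open interval conventions (BED-style) are used throughout the
#' package.  Simulated matrices may additionally carry the underlying
#' haplotypes (a 0/1 matrix with two rows per sample, in sample order),
#' which the sweep-planting step operates on.
#'
#' @param geno integer matrix, samples x sites, values 0/1/2/NA.
#' @param positions integer vector of 0-based site positions, strictly
#'   increasing, same length as `ncol(geno)`.
#' @param chrom chromosome name.
#' @param chrom_length chromosome length in bp.
#' @param pops named character vector mapping sample id -> population label;
#'   names must cover `rownames(geno)`.
#' @param haplo optional 0/1 haplotype matrix with `2 * nrow(geno)` rows
#'   (rows `2i-1`, `2i` belong to sample `i`).
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, positions, chrom, chrom_length, pops,
                            haplo = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  positions <- as.integer(positions)
  if (length(positions) != ncol(geno))
    stop("length(positions) must equal ncol(geno)")
  if (length(positions) > 1 && any(diff(positions) <= 0))
    stop("positions must be strictly increasing")
  if (is.null(rownames(geno)))
    stop("geno must have sample ids as rownames")
  if (!all(rownames(geno) %in% names(pops)))
    stop("pops must label every sample")
  if (any(positions < 0) || (length(positions) &&
                             max(positions) >= chrom_length))
    stop("positions must lie in [0, chrom_length)")
  if (!is.null(haplo)) {
    haplo <- as.matrix(haplo)
    storage.mode(haplo) <- "integer"
    if (nrow(haplo) != 2L * nrow(geno) || ncol(haplo) != ncol(geno))
      stop("haplo must be 2*nsamples x nsites")
  }
  structure(
    list(geno = geno, positions = positions, chrom = as.character(chrom),
         chrom_length = as.integer(chrom_length),
         pops = pops[rownames(geno)], haplo = haplo),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs on %s (%s bp)\n",
              nrow(x$geno), ncol(x$geno), x$chrom,
              format(x$chrom_length, big.mark = ",")))
  tab <- table(x$pops)
  cat("populations:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  if (!is.null(x$haplo)) cat("haplotypes: stored\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

#' Subset a genotype matrix to a set of site indices
#'
#' @param gm a [genotype_matrix()].
#' @param sites integer or logical index into the site dimension.
#' @return a `genotype_matrix` restricted to those sites.
#' @export
subset_sites <- function(gm, sites) {
  genotype_matrix(gm$geno[, sites, drop = FALSE], gm$positions[sites],
                  gm$chrom, gm$chrom_length, gm$pops,
                  haplo = if (!is.null(gm$haplo))
                    gm$haplo[, sites, drop = FALSE])
}

#' Sample indices belonging to a set of populations
#' @param gm a [genotype_matrix()].
#' @param pops character vector of population labels.
#' @return integer vector of sample (row) indices.
#' @export
pop_index <- function(gm, pops) {
  bad <- setdiff(pops, unique(gm$pops))
  if (length(bad))
    stop("unknown population(s): ", paste(bad, collapse = ", "))
  which(gm$pops %in% pops)
}

# per-site allele summaries for a sample subset: called allele count m,
# alt count k, het count, called diploid count
.site_counts <- function(gm, idx) {
  g <- gm$geno[idx, , drop = FALSE]
  called <- colSums(!is.na(g))
  k <- colSums(g, na.rm = TRUE)
  het <- colSums(g == 1L, na.rm = TRUE)
  list(m = 2L * called, k = k, het = het, called = called)
}

#' Read a two-column sample-to-population map
#'
#' Expects a TSV with sample id in column 1 and population label in column
#' 2, no header (a `sample<TAB>population` header line is tolerated).
#'
#' @param path path to the TSV file.
#' @return named character vector mapping sample -> population.
#' @export
read_pop_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("sample", "population"))
  if (identical(tolower(df$sample[1]), "sample")) df <- df[-1, ]
  stats::setNames(df$population, df$sample)
}

#' Write a genotype matrix as VCF 4.2
#'
#' Emits one record per SNP with `GT` genotypes and constant (or per-site)
#' `QUAL`, `INFO/DP` and `INFO/MQ` values, so that the site-filter stage can
#' be exercised on simulated data.  Positions are written 1-based per the
#' VCF standard.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path (plain text; use a `.vcf` extension).
#' @param qual,dp,mq scalar or per-site numeric vectors for the QUAL column
#'   and the INFO DP/MQ fields.
#' @param ref,alt optional per-site allele vectors; defaults are drawn
#'   deterministically from the site index.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path, qual = 60, dp = 300, mq = 60,
                      ref = NULL, alt = NULL) {
  ns <- ncol(gm$geno)
  bases <- c("A", "C", "G", "T")
  if (is.null(ref)) ref <- bases[(gm$positions %% 4L) + 1L]
  if (is.null(alt)) alt <- bases[((gm$positions %/% 4L + 1L) %% 4L) + 1L]
  alt[alt == ref] <- bases[(match(ref[alt == ref], bases) %% 4L) + 1L]
  qual <- rep_len(format(qual, trim = TRUE), ns)
  dp <- rep_len(as.integer(dp), ns)
  mq <- rep_len(format(mq, trim = TRUE), ns)
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", gm$chrom, gm$chrom_length),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(gm$geno)), collapse = "\t"))
  gt <- c("0/0", "0/1", "1/1")[gm$geno + 1L]
  gt[is.na(gt)] <- "./."
  gt <- matrix(gt, nrow = nrow(gm$geno))
  recs <- if (ns) {
    vapply(seq_len(ns), function(j) {
      paste(c(gm$chrom, gm$positions[j] + 1L, ".", ref[j], alt[j], qual[j],
              "PASS", sprintf("DP=%d;MQ=%s", dp[j], mq[j]), "GT", gt[, j]),
            collapse = "\t")
    }, character(1))
  } else character(0)
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Read biallelic SNP genotypes from a VCF into a genotype matrix
#'
#' Non-SNP and multiallelic records are dropped (with a message).  Requires
#' a population map covering all samples in the VCF.
#'
#' @param path VCF path (plain or gzipped).
#' @param pops named character vector (see [read_pop_map()]).
#' @param chrom_length optional; if missing, taken from the `##contig`
#'   header or, failing that, `max(position) + 1`.
#' @return a [genotype_matrix()].
#' @export
read_vcf_genotypes <- function(path, pops, chrom_length = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (nrow(fix) == 0) stop("VCF contains no records")
  snp <- nchar(fix[, "REF"]) == 1L & nchar(fix[, "ALT"]) == 1L &
    !grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(!snp))
    message(sum(!snp), " non-SNP/multiallelic record(s) dropped")
  gt <- vcfR::extract.gt(v[snp, ], element = "GT")
  code <- function(x) {
    x <- gsub("|", "/", x, fixed = TRUE)
    out <- rep(NA_integer_, length(x))
    out[x == "0/0"] <- 0L
    out[x %in% c("0/1", "1/0")] <- 1L
    out[x == "1/1"] <- 2L
    out
  }
  geno <- t(matrix(code(as.vector(gt)), nrow = nrow(gt), ncol = ncol(gt)))
  dimnames(geno) <- list(colnames(gt), NULL)
  pos <- as.integer(fix[snp, "POS"]) - 1L
  chrom <- fix[snp, "CHROM"][1]
  if (is.null(chrom_length)) {
    m <- regmatches(v@meta, regexpr("##contig=<ID=[^,>]+,length=[0-9]+",
                                    v@meta))
    chrom_length <- if (length(m))
      as.integer(sub(".*length=", "", m[1])) else max(pos) + 1L
  }
  ord <- order(pos)
  genotype_matrix(geno[, ord, drop = FALSE], pos[ord], chrom, chrom_length,
                  pops)
}
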