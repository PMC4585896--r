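#' Site-level VCF filters
#'
#' Applies the post-calling site filters to a VCF: keeps biallelic SNPs
#' with (a) summed coverage depth between `min_depth` and `max_depth`,
#' (b) RMS mapping quality >= `min_mq`, (e) variant quality >=
#' `min_qual`, (c) distance to the nearest other SNP >= `min_snp_gap` bp
#' and (d) distance to the nearest gap (indel record) >= `min_indel_gap`
#' bp.  Rule (c) is symmetric: both members of a too-close SNP pair are
#' removed.  Indel records inform rule (d) but are themselves removed from
#' the output; multiallelic SNP records are dropped as non-biallelic.
#'
#' A site may fail several rules; all failures are counted, and each
#' removed SNP is additionally attributed to its first failing rule in the
#' order depth, MQ, QUAL, SNP spacing, gap distance.
#'
#' @param vcf input VCF path (plain or gzipped).
#' @param out optional path; when given, the surviving records are written
#'   as a VCF (input header preserved).
#' @param min_depth,max_depth inclusive bounds on INFO/DP.
#' @param min_mq minimum INFO/MQ (RMS mapping quality), inclusive.
#' @param min_qual minimum QUAL, inclusive.
#' @param min_snp_gap minimum distance between adjacent SNPs, bp.
#' @param min_indel_gap minimum distance from a SNP to an indel's affected
#'   reference interval, bp.
#' @return a list: `keep` (logical over SNP records in input order),
#'   `sites` (data frame of the surviving SNPs), `counts` (named vector:
#'   input records, snps, indels, multiallelic, per-rule failure counts,
#'   per-rule first-failure attributions, kept).
#' @export
site_filter <- function(vcf, out = NULL, min_depth = 4, max_depth = 1000,
                        min_mq = 20, min_qual = 30, min_snp_gap = 5,
                        min_indel_gap = 5) {
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  if (any(unlist(tapply(pos, chrom, function(p) diff(p) < 0))))
    stop("VCF records must be sorted by position within chromosome")
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  snp <- !multi & nchar(ref) == 1L & nchar(alt) == 1L
  indel <- !multi & !snp & (nchar(ref) != nchar(alt))
  dp <- suppressWarnings(as.numeric(vcfR::extract.info(v, "DP")))
  mq <- suppressWarnings(as.numeric(vcfR::extract.info(v, "MQ")))
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))

  fail_depth <- snp & (is.na(dp) | dp < min_depth | dp > max_depth)
  fail_mq <- snp & (is.na(mq) | mq < min_mq)
  fail_qual <- snp & (is.na(qual) | qual < min_qual)

  # rule (c): spacing among all called SNPs, per chromosome, symmetric
  fail_space <- rep(FALSE, length(pos))
  # rule (d): distance to nearest indel reference interval [pos0, pos0+len)
  fail_gap <- rep(FALSE, length(pos))
  for (ch in unique(chrom)) {
    si <- which(snp & chrom == ch)
    if (length(si) > 1) {
      d <- diff(pos[si])
      too_close <- d < min_snp_gap
      bad <- unique(c(si[c(too_close, FALSE)], si[c(FALSE, too_close)]))
      fail_space[bad] <- TRUE
    }
    ii <- which(indel & chrom == ch)
    if (length(ii) && length(si)) {
      a <- pos[ii] - 1L                         # 0-based interval start
      b <- a + nchar(ref[ii])                   # half-open end
      for (s in si) {
        s0 <- pos[s] - 1L
        dist <- pmax(0L, pmax(a - s0, s0 - b + 1L))
        if (any(dist < min_indel_gap)) fail_gap[s] <- TRUE
      }
    }
  }
  any_fail <- fail_depth | fail_mq | fail_qual | fail_space | fail_gap
  keep <- snp & !any_fail
  first <- function(...) {
    f <- cbind(...)
    att <- rep(NA_integer_, nrow(f))
    for (j in rev(seq_len(ncol(f)))) att[f[, j]] <- j
    att
  }
  att <- first(fail_depth, fail_mq, fail_qual, fail_space, fail_gap)
  counts <- c(
    input = length(pos), snps = sum(snp), indels = sum(indel),
    multiallelic = sum(multi),
    fail_depth = sum(fail_depth), fail_mq = sum(fail_mq),
    fail_qual = sum(fail_qual), fail_snp_gap = sum(fail_space),
    fail_indel_gap = sum(fail_gap),
    attr_depth = sum(att == 1L, na.rm = TRUE),
    attr_mq = sum(att == 2L, na.rm = TRUE),
    attr_qual = sum(att == 3L, na.rm = TRUE),
    attr_snp_gap = sum(att == 4L, na.rm = TRUE),
    attr_indel_gap = sum(att == 5L, na.rm = TRUE),
    kept = sum(keep))
  if (!is.null(out)) {
    lines <- readLines(if (grepl("\\.gz$", vcf)) gzfile(vcf) else vcf)
    hdr <- grepl("^#", lines)
    writeLines(c(lines[hdr], lines[!hdr][keep]), out)
  }
  sites <- data.frame(chrom = chrom[keep], pos = pos[keep],
                      ref = ref[keep], alt = alt[keep], qual = qual[keep],
                      dp = dp[keep], mq = mq[keep],
                      stringsAsFactors = FALSE)
  list(keep = keep, sites = sites, counts = counts)
}

#' Analysis-set genotype filters
#'
#' Reduces a genotype matrix to the analysis set used for structure and
#' selection scans: drops sites with minor allele frequency <= `maf`
#' (computed over called alleles, all samples pooled), call rate <=
#' `callrate` (strictly more than `callrate` of individuals must be
#' genotyped), and sites monomorphic within the sample set (all called
#' genotypes identical, regardless of the reference allele).  Idempotent.
#'
#' @param gm a [genotype_matrix()].
#' @param maf MAF threshold; sites with MAF <= `maf` are removed.
#' @param callrate call-rate threshold; sites with called fraction <=
#'   `callrate` are removed.
#' @return the filtered `genotype_matrix`, with a `counts` attribute
#'   (input, fail_maf, fail_callrate, fail_monomorphic, kept; failure
#'   counts overlap).
#' @export
analysis_set_filter <- function(gm, maf = 0.1, callrate = 0.9) {
  ns <- nrow(gm$geno)
  if (ns == 0) stop("genotype matrix has zero samples")
  called <- colSums(!is.na(gm$geno))
  k <- colSums(gm$geno, na.rm = TRUE)
  m <- 2L * called
  maf_v <- ifelse(m > 0, pmin(k, m - k) / m, 0)
  mono <- vapply(seq_len(ncol(gm$geno)), function(j) {
    g <- gm$geno[, j]
    g <- g[!is.na(g)]
    length(g) == 0L || all(g == g[1])
  }, logical(1))
  fail_maf <- maf_v <= maf
  fail_cr <- called / ns <= callrate
  drop <- fail_maf | fail_cr | mono | m == 0L
  out <- subset_sites(gm, !drop)
  attr(out, "counts") <- c(input = ncol(gm$geno),
                           fail_maf = sum(fail_maf),
                           fail_callrate = sum(fail_cr),
                           fail_monomorphic = sum(mono),
                           kept = sum(!drop))
  out
}
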