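#' Read-level quality filters
#'
#' Four filters applied to 100-bp paired-end reads before mapping:
#' (a) too many uncalled bases, (b) adapter contamination, (c) low base
#' quality, (d) PCR duplicates.  A pair is discarded when either mate
#' fails (a)-(c) or when the pair is an exact duplicate of an earlier kept
#' pair; each pair is attributed to the first failing criterion in the
#' order a, b, c, d.
#'
#' @name readqc
NULL

#' Does a read fail the uncalled-base filter?
#'
#' True when >= 10% of the bases are `N` (boundary inclusive).
#'
#' @param seq nucleotide string (alphabet A/C/G/T/N).
#' @return logical.
#' @export
fails_high_n <- function(seq) {
  stopifnot(nchar(seq) > 0)
  n_count <- nchar(seq) - nchar(gsub("N", "", seq, fixed = TRUE))
  n_count / nchar(seq) >= 0.10
}

#' Does a read fail the adapter-contamination filter?
#'
#' True when some ungapped alignment of a substring of the adapter to the
#' read aligns more than 10 nt (matched bases) with a mismatch fraction
#' of at most 10% of the alignment length, so an exact 10-nt match does
#' not qualify but an 11-nt exact match or a 20-nt stretch with two
#' mismatches does.  All relative offsets of adapter against read
#' (including partial overlaps) and all alignment lengths are examined;
#' `N` bases count as mismatches.
#'
#' @param seq read sequence.
#' @param adapter adapter sequence; must be non-empty.
#' @return logical.
#' @export
fails_adapter <- function(seq, adapter) {
  if (is.null(adapter) || !nzchar(adapter))
    stop("adapter sequence must be non-empty")
  r <- strsplit(seq, "")[[1]]
  a <- strsplit(adapter, "")[[1]]
  lr <- length(r); la <- length(a)
  if (lr < 11L || la < 11L) return(FALSE)
  # shift = (read position of adapter base 1) - 1, may be negative
  for (shift in (-la + 11L):(lr - 11L)) {
    rs <- max(1L, 1L + shift); re <- min(lr, la + shift)
    ov <- re - rs + 1L
    if (ov < 11L) next
    mism <- r[rs:re] != a[(rs - shift):(re - shift)]
    cm <- c(0L, cumsum(mism))
    for (len in 11:ov) {
      # mism/len <= 0.10 and matched nt (len - mism) > 10
      allowed <- min(floor(len / 10), len - 11L)
      if (min(cm[(len + 1L):(ov + 1L)] - cm[1:(ov - len + 1L)]) <= allowed)
        return(TRUE)
    }
  }
  FALSE
}

#' Does a read fail the base-quality filter?
#'
#' True when > 50% of bases have phred quality < 5 (phred+33 encoding;
#' boundary exclusive).
#'
#' @param qual phred+33 quality string.
#' @return logical.
#' @export
fails_low_qual <- function(qual) {
  q <- utf8ToInt(qual) - 33L
  if (any(q < 0 | q > 93))
    stop("malformed quality string (expect phred+33)")
  mean(q < 5L) > 0.5
}

# read one FASTQ file (plain or gz) into id/seq/qual vectors
.read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  list(id = names(x), seq = as.character(x),
       qual = as.character(S4Vectors::mcols(x)$qualities))
}

.write_fastq <- function(id, seq, qual, path) {
  x <- Biostrings::DNAStringSet(seq)
  names(x) <- id
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(qual))
  invisible(path)
}

#' Run paired-end read QC
#'
#' Streams both mate files in order, applies the four filters (see
#' [readqc]) and writes the surviving pairs plus a QC report.  Duplicates
#' are pairs whose two mate sequences exactly equal those of a previously
#' kept pair (qualities ignored); the first occurrence is kept.
#'
#' @param fastq1,fastq2 mate FASTQ paths (plain or gzipped).
#' @param adapter adapter sequence used by the adapter filter.
#' @param out_prefix optional path prefix; when given, kept pairs are
#'   written to `<out_prefix>_1.fastq` / `<out_prefix>_2.fastq`.
#' @return a `qc_report` list: `n_input_pairs`, `n_kept_pairs`, per-class
#'   discard counts (`n_highN`, `n_adapter`, `n_lowqual`, `n_duplicate`),
#'   `retained_fraction`, and `class` (per-pair attribution, in input
#'   order: "kept", "highN", "adapter", "lowqual", "duplicate").
#' @export
run_readqc <- function(fastq1, fastq2, adapter, out_prefix = NULL) {
  r1 <- .read_fastq(fastq1)
  r2 <- .read_fastq(fastq2)
  n <- length(r1$id)
  if (length(r2$id) != n)
    stop("desynchronized mate files: ", n, " vs ", length(r2$id),
         " records")
  cls <- rep("kept", n)
  if (n > 0) {
    for (i in seq_len(n)) {
      if (fails_high_n(r1$seq[i]) || fails_high_n(r2$seq[i]))
        cls[i] <- "highN"
      else if (fails_adapter(r1$seq[i], adapter) ||
               fails_adapter(r2$seq[i], adapter))
        cls[i] <- "adapter"
      else if (fails_low_qual(r1$qual[i]) || fails_low_qual(r2$qual[i]))
        cls[i] <- "lowqual"
    }
    pass <- cls == "kept"
    key <- paste(r1$seq, r2$seq, sep = "|")
    dup <- pass & duplicated(key[pass])[match(seq_len(n), which(pass))]
    dup[is.na(dup)] <- FALSE
    cls[dup] <- "duplicate"
  }
  kept <- cls == "kept"
  if (!is.null(out_prefix)) {
    .write_fastq(r1$id[kept], r1$seq[kept], r1$qual[kept],
                 paste0(out_prefix, "_1.fastq"))
    .write_fastq(r2$id[kept], r2$seq[kept], r2$qual[kept],
                 paste0(out_prefix, "_2.fastq"))
  }
  structure(list(
    n_input_pairs = n,
    n_kept_pairs = sum(kept),
    n_highN = sum(cls == "highN"),
    n_adapter = sum(cls == "adapter"),
    n_lowqual = sum(cls == "lowqual"),
    n_duplicate = sum(cls == "duplicate"),
    retained_fraction = if (n > 0) sum(kept) / n else NA_real_,
    class = cls), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    "read QC: %d pairs in, %d kept (%.2f%%)\n",
    x$n_input_pairs, x$n_kept_pairs, 100 * x$retained_fraction))
  cat(sprintf("discarded: highN=%d adapter=%d lowqual=%d duplicate=%d\n",
              x$n_highN, x$n_adapter, x$n_lowqual, x$n_duplicate))
  invisible(x)
}
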