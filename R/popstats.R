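#' Tajima's D normalizing constants
#'
#' The standard constants for a sample of `n` sequences:
#' `a1 = sum(1/i)`, `a2 = sum(1/i^2)` for `i` in `1..n-1`,
#' `b1 = (n+1)/(3(n-1))`, `b2 = 2(n^2+n+3)/(9n(n-1))`,
#' `c1 = b1 - 1/a1`, `c2 = b2 - (n+2)/(a1 n) + a2/a1^2`,
#' `e1 = c1/a1`, `e2 = c2/(a1^2 + a2)`.
#'
#' @param n number of sequences (haploid sample size), >= 2.
#' @return named list with a1, a2, b1, b2, c1, c2, e1, e2.
#' @export
tajima_constants <- function(n) {
  if (n < 2) stop("n must be >= 2")
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

# per-site pi: average pairwise difference k(m-k)/C(m,2); 0 where m < 2
.site_pi <- function(m, k) {
  out <- numeric(length(m))
  ok <- m >= 2
  out[ok] <- 2 * k[ok] * (m[ok] - k[ok]) / (m[ok] * (m[ok] - 1))
  out
}

#' Nucleotide diversity over a site set
#'
#' Per-site pi is `k(m-k)/C(m,2)` with `m` the called allele count and `k`
#' the alternate-allele count -- the mean pairwise Hamming distance among
#' sampled haplotypes at that site.  Returns the sum over sites; divide by
#' the window span for per-bp diversity.  Sites with fewer than 2 called
#' alleles contribute 0.
#'
#' @param gm a [genotype_matrix()].
#' @param pop population label (or vector of labels, pooled).
#' @param sites optional site index (default: all).
#' @return named list: `pi_sum`, `n_sites`, `n_low` (sites with m < 2).
#' @export
nucleotide_diversity <- function(gm, pop, sites = NULL) {
  idx <- pop_index(gm, pop)
  sc <- .site_counts(gm, idx)
  j <- if (is.null(sites)) seq_along(sc$m) else sites
  m <- sc$m[j]; k <- sc$k[j]
  list(pi_sum = sum(.site_pi(m, k)), n_sites = length(j),
       n_low = sum(m < 2))
}

#' Watterson's theta
#'
#' `theta_W = S / a1(n)` with `S` the number of segregating sites.
#'
#' @param S segregating-site count.
#' @param n haploid sample size, >= 2.
#' @return theta_W (same scale as S; divide by span for per-bp).
#' @export
wattersons_theta <- function(S, n) {
  if (n < 2) stop("n must be >= 2")
  S / tajima_constants(n)$a1
}

#' Tajima's D
#'
#' `D = (pi_sum - S/a1) / sqrt(e1 S + e2 S (S-1))`.  Returns `NA` when
#' undefined (S = 0, n < 4, or non-positive variance).
#'
#' @param pi_sum summed pairwise diversity over the same sites as `S`.
#' @param S number of segregating sites.
#' @param n haploid sample size.
#' @return Tajima's D, or `NA_real_` when undefined.
#' @export
tajimas_d <- function(pi_sum, S, n) {
  if (is.na(S) || is.na(n) || S < 1 || n < 4) return(NA_real_)
  cst <- tajima_constants(n)
  v <- cst$e1 * S + cst$e2 * S * (S - 1)
  if (v <= 0) return(NA_real_)
  (pi_sum - S / cst$a1) / sqrt(v)
}

#' Hudson's F_ST (ratio of sums)
#'
#' Per site, numerator `(p1-p2)^2 - p1(1-p1)/(m1-1) - p2(1-p2)/(m2-1)` and
#' denominator `p1(1-p2) + p2(1-p1)`; the estimate is the ratio of sums
#' over sites.  Sites where either population has fewer than 2 called
#' alleles are skipped.  Negative estimates are reported raw.
#'
#' @param m1,k1,m2,k2 per-site called allele counts and alternate-allele
#'   counts for the two populations.
#' @return F_ST estimate, or `NA_real_` when the summed denominator is 0
#'   or no site is usable.
#' @export
hudson_fst <- function(m1, k1, m2, k2) {
  ok <- m1 >= 2 & m2 >= 2
  if (!any(ok)) return(NA_real_)
  p1 <- k1[ok] / m1[ok]; p2 <- k2[ok] / m2[ok]
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (m1[ok] - 1) -
    p2 * (1 - p2) / (m2[ok] - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sden <- sum(den)
  if (sden == 0) return(NA_real_)
  sum(num) / sden
}

#' Weir & Cockerham (1984) F_ST (ratio of sums)
#'
#' Two-population theta-hat from the a, b, c variance components computed
#' from per-population diploid sample sizes, allele frequencies and
#' heterozygote frequencies; the estimate is `sum(a) / sum(a+b+c)` over
#' sites.  Negative estimates are reported raw.
#'
#' @param n1,n2 per-site called diploid counts per population.
#' @param p1,p2 per-site alternate-allele frequencies.
#' @param h1,h2 per-site heterozygote frequencies (het diploids / called
#'   diploids).
#' @return F_ST estimate, or `NA_real_` when undefined.
#' @export
wc_fst <- function(n1, p1, h1, n2, p2, h2) {
  ok <- n1 >= 1 & n2 >= 1 & (n1 + n2) >= 2
  if (!any(ok)) return(NA_real_)
  n1 <- n1[ok]; n2 <- n2[ok]; p1 <- p1[ok]; p2 <- p2[ok]
  h1 <- h1[ok]; h2 <- h2[ok]
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 -
       (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  use <- nbar > 1 & nc > 0
  den <- sum(a[use] + b[use] + cc[use])
  if (!any(use) || den == 0) return(NA_real_)
  sum(a[use]) / den
}

#' Sliding-window grid
#'
#' Windows start at 0, `step`, `2*step`, ... while the start lies before
#' `chrom_length`; each window ends at `min(start + window, chrom_length)`
#' (trailing windows are truncated).  Coordinates 0-based half-open.
#'
#' @param chrom_length chromosome length, bp.
#' @param window window size, bp.
#' @param step step size, bp; `window >= step >= 1`.
#' @return data frame with `start`, `end`, `span`.
#' @export
make_windows <- function(chrom_length, window = 1e5, step = 1e4) {
  stopifnot(window >= step, step >= 1)
  starts <- seq(0L, as.integer(chrom_length) - 1L, by = as.integer(step))
  ends <- pmin(starts + as.integer(window), as.integer(chrom_length))
  data.frame(start = starts, end = ends, span = ends - starts)
}

#' Windowed selection-scan statistics
#'
#' For each sliding window computes, for the focal (`high`) population and
#' the pooled reference (`low`) populations: per-bp nucleotide diversity,
#' per-bp Watterson's theta, Tajima's D, the chosen F_ST estimator between
#' the two groups, the diversity ratio `pi_low / pi_high` and the Tajima's
#' D difference `D_low - D_high`.  The haploid sample size used for
#' Tajima's D in a window is the mean called allele count over the
#' window's SNPs, rounded down.  Windows with no SNPs get zero diversity
#' and `NA` for ratio-type statistics.
#'
#' @param gm a [genotype_matrix()] (normally after
#'   [analysis_set_filter()]).
#' @param high focal population label.
#' @param low reference population label(s), pooled.
#' @param window,step window and step size, bp.
#' @param fst F_ST estimator, `"hudson"` (default) or `"wc"`.
#' @return a `window_stats` data frame: chrom, start, end, span, n_snps,
#'   pi_high, pi_low, theta_w_high, theta_w_low, d_high, d_low, fst,
#'   pi_ratio, d_diff.
#' @export
windowed_stats <- function(gm, high = "HIGH", low = c("LOW1", "LOW2"),
                           window = 1e5, step = 1e4,
                           fst = c("hudson", "wc")) {
  fst <- match.arg(fst)
  hi <- pop_index(gm, high)
  lo <- pop_index(gm, low)
  ch <- .site_counts(gm, hi)
  cl <- .site_counts(gm, lo)
  pi_h <- .site_pi(ch$m, ch$k)
  pi_l <- .site_pi(cl$m, cl$k)
  win <- make_windows(gm$chrom_length, window, step)
  pos <- gm$positions
  res <- lapply(seq_len(nrow(win)), function(w) {
    j1 <- findInterval(win$start[w] - 0.5, pos) + 1L
    j2 <- findInterval(win$end[w] - 0.5, pos)
    span <- win$span[w]
    if (j2 < j1) {
      return(data.frame(n_snps = 0L, pi_high = 0, pi_low = 0,
                        theta_w_high = 0, theta_w_low = 0,
                        d_high = NA_real_, d_low = NA_real_,
                        fst = NA_real_, pi_ratio = NA_real_,
                        d_diff = NA_real_))
    }
    j <- j1:j2
    stat1 <- function(m, k, piv) {
      S <- sum(k[j] > 0 & k[j] < m[j])
      n_eff <- floor(mean(m[j]))
      pis <- sum(piv[j])
      d <- tajimas_d(pis, S, n_eff)
      tw <- if (n_eff >= 2) wattersons_theta(S, n_eff) else NA_real_
      c(pi = pis / span, tw = tw / span, d = d)
    }
    sh <- stat1(ch$m, ch$k, pi_h)
    sl <- stat1(cl$m, cl$k, pi_l)
    f <- if (fst == "hudson") {
      hudson_fst(ch$m[j], ch$k[j], cl$m[j], cl$k[j])
    } else {
      wc_fst(ch$called[j], ifelse(ch$m[j] > 0, ch$k[j] / ch$m[j], 0),
             ifelse(ch$called[j] > 0, ch$het[j] / ch$called[j], 0),
             cl$called[j], ifelse(cl$m[j] > 0, cl$k[j] / cl$m[j], 0),
             ifelse(cl$called[j] > 0, cl$het[j] / cl$called[j], 0))
    }
    data.frame(n_snps = length(j), pi_high = sh[["pi"]],
               pi_low = sl[["pi"]],
               theta_w_high = sh[["tw"]], theta_w_low = sl[["tw"]],
               d_high = sh[["d"]], d_low = sl[["d"]], fst = f,
               pi_ratio = if (sh[["pi"]] > 0) sl[["pi"]] / sh[["pi"]]
                          else NA_real_,
               d_diff = sl[["d"]] - sh[["d"]])
  })
  out <- cbind(data.frame(chrom = gm$chrom, start = win$start,
                          end = win$end, span = win$span),
               do.call(rbind, res))
  class(out) <- c("window_stats", "data.frame")
  attr(out, "high") <- high
  attr(out, "low") <- low
  attr(out, "fst_estimator") <- fst
  out
}

#' @export
print.window_stats <- function(x, ...) {
  cat(sprintf(
    "window_stats: %d windows (%s vs %s pooled; %s F_ST); %d with SNPs\n",
    nrow(x), attr(x, "high"), paste(attr(x, "low"), collapse = "+"),
    attr(x, "fst_estimator"), sum(x$n_snps > 0)))
  NextMethod()
}

#' Scatter plot of the joint scan statistics
#'
#' Plots per-window `pi_ratio` against `fst` with the top-quantile
#' thresholds, the standard visualization of a joint outlier scan.
#'
#' @param x a `window_stats` data frame.
#' @param thresholds optional output of [joint_outliers()]; when given the
#'   thresholds are drawn and selected windows highlighted.
#' @param ... passed to [plot()].
#' @export
plot_scan <- function(x, thresholds = NULL, ...) {
  ok <- !is.na(x$fst) & !is.na(x$pi_ratio)
  plot(x$fst[ok], x$pi_ratio[ok], xlab = expression(F[ST]),
       ylab = expression(theta[pi] ~ "ratio (low/high)"),
       pch = 16, cex = 0.5, col = "grey40", ...)
  if (!is.null(thresholds)) {
    abline(v = thresholds$t_fst, h = thresholds$t_ratio, lty = 2,
           col = "red3")
    sel <- ok & x$fst >= thresholds$t_fst & x$pi_ratio >= thresholds$t_ratio
    points(x$fst[sel], x$pi_ratio[sel], pch = 16, cex = 0.6,
           col = "blue3")
  }
  invisible(x)
}
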