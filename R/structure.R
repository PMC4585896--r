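#' Allele-sharing genetic distance
#'
#' `d(i, j) = 1 - IBS(i, j)` where IBS is the mean, over sites where both
#' samples are called, of the shared-allele fraction
#' `1 - |g_i - g_j| / 2` with genotypes coded 0/1/2.  The standard SNP
#' distance for neighbor-joining on genotype panels.
#'
#' @param gm a [genotype_matrix()] with >= 2 samples.
#' @return a symmetric `dist`-compatible matrix with sample ids; pairs
#'   with zero co-called sites get `NA`.
#' @export
allele_sharing_distance <- function(gm) {
  g <- gm$geno
  ns <- nrow(g)
  if (ns < 2) stop("need at least 2 samples")
  d <- matrix(0, ns, ns, dimnames = list(rownames(g), rownames(g)))
  for (i in seq_len(ns - 1)) {
    gi <- g[i, ]
    for (j in (i + 1):ns) {
      gj <- g[j, ]
      ok <- !is.na(gi) & !is.na(gj)
      d[i, j] <- d[j, i] <- if (any(ok))
        mean(abs(gi[ok] - gj[ok]) / 2) else NA_real_
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Classic agglomerative NJ: repeatedly joins the pair minimizing
#' `Q(i, j) = (r - 2) d(i, j) - R_i - R_j` (with `R_i` the row sum over
#' the `r` current clusters), assigning branch lengths
#' `b_i = d(i, j)/2 + (R_i - R_j) / (2 (r - 2))`, until three clusters
#' remain, which are resolved by the three-point formulas around a
#' trifurcating root.  Q-ties are broken deterministically by the
#' lexicographically smallest pair of cluster labels.  Branch lengths may
#' be negative; `clamp = TRUE` clips them to zero for display.
#'
#' @param d symmetric distance matrix with labelled rows/columns, >= 3
#'   taxa.
#' @param clamp clip negative branch lengths to 0 (default `FALSE`).
#' @return a list: `tree` (an [ape::read.tree()] `phylo` object) and
#'   `newick` (the Newick string).
#' @export
neighbor_joining <- function(d, clamp = FALSE) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("need at least 3 taxa")
  if (any(is.na(d))) stop("distance matrix contains NA")
  if (max(abs(d - t(d))) > 1e-12 || any(diag(d) != 0))
    stop("distance matrix must be symmetric with zero diagonal")
  labs <- rownames(d)
  if (is.null(labs)) labs <- paste0("t", seq_len(nrow(d)))
  fmt <- function(x) sprintf("%.15g", if (clamp) max(x, 0) else x)
  nwk <- labs                     # growing newick substring per cluster
  key <- labs                     # tie-break key: smallest member label
  while (nrow(d) > 3) {
    r <- nrow(d)
    R <- rowSums(d)
    Q <- (r - 2) * d - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    kk <- paste(pmin(key[cand[, 1]], key[cand[, 2]]),
                pmax(key[cand[, 1]], key[cand[, 2]]))
    pick <- cand[order(kk)[1], ]
    i <- pick[1]; j <- pick[2]
    bi <- d[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    bj <- d[i, j] - bi
    new_nwk <- sprintf("(%s:%s,%s:%s)", nwk[i], fmt(bi), nwk[j], fmt(bj))
    new_key <- min(key[i], key[j])
    dn <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dn[keep]),
                c(dn[keep], 0))
    nwk <- c(nwk[keep], new_nwk)
    key <- c(key[keep], new_key)
    rownames(d2) <- colnames(d2) <- NULL
    d <- d2
  }
  b1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  b2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  b3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  newick <- sprintf("(%s:%s,%s:%s,%s:%s);", nwk[1], fmt(b1), nwk[2],
                    fmt(b2), nwk[3], fmt(b3))
  list(tree = ape::read.tree(text = newick), newick = newick)
}

#' Genotype principal component analysis
#'
#' Patterson-style PCA on the genotype matrix: each site is centred by
#' twice its alternate-allele frequency and scaled by
#' `sqrt(p (1 - p))`; missing genotypes are mean-imputed; monomorphic
#' sites are dropped.  The sample covariance matrix is
#' eigendecomposed and coordinates plus explained-variance fractions are
#' reported.
#'
#' @param gm a [genotype_matrix()] with >= 2 samples and >= 1 polymorphic
#'   site.
#' @param n_components number of components to report.
#' @return a `genotype_pca` list: `coords` (samples x components),
#'   `eigenvalues`, `explained` (fractions of total variance), `pops`.
#' @export
genotype_pca <- function(gm, n_components = 10L) {
  g <- gm$geno
  if (nrow(g) < 2) stop("need at least 2 samples")
  called <- colSums(!is.na(g))
  p <- ifelse(called > 0, colSums(g, na.rm = TRUE) / (2 * called), 0)
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic site")
  g <- g[, poly, drop = FALSE]
  p <- p[poly]
  x <- sweep(g, 2, 2 * p)
  x[is.na(x)] <- 0
  x <- sweep(x, 2, sqrt(p * (1 - p)), "/")
  n_max <- min(nrow(g) - 1L, ncol(g))
  if (n_components > n_max) {
    warning("reducing components to ", n_max)
    n_components <- n_max
  }
  cv <- tcrossprod(x) / ncol(x)
  eg <- eigen(cv, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  coords <- eg$vectors[, seq_len(n_components), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(n_components)]), n_components)
  dimnames(coords) <- list(rownames(gm$geno),
                           paste0("PC", seq_len(n_components)))
  structure(list(coords = coords, eigenvalues = ev[seq_len(n_components)],
                 explained = ev[seq_len(n_components)] / sum(ev),
                 pops = gm$pops), class = "genotype_pca")
}

#' @export
print.genotype_pca <- function(x, ...) {
  cat("genotype_pca:", nrow(x$coords), "samples;",
      paste(sprintf("PC%d %.2f%%", seq_along(x$explained),
                    100 * x$explained), collapse = ", "), "\n")
  invisible(x)
}

#' Neighbor-joining tree for one gene
#'
#' Restricts the genotype matrix to a gene's SNPs (half-open interval)
#' and composes [allele_sharing_distance()] with [neighbor_joining()].
#'
#' @param gm a [genotype_matrix()].
#' @param gene one-row gene record (needs start, end, gene_id) or a
#'   numeric `c(start, end)`.
#' @param clamp passed to [neighbor_joining()].
#' @return as [neighbor_joining()].
#' @export
gene_tree <- function(gm, gene, clamp = FALSE) {
  if (is.numeric(gene)) gene <- data.frame(start = gene[1], end = gene[2],
                                           gene_id = "gene")
  j <- gm$positions >= gene$start & gm$positions < gene$end
  if (!any(j)) stop("gene has no SNPs: ", gene$gene_id)
  neighbor_joining(allele_sharing_distance(subset_sites(gm, j)),
                   clamp = clamp)
}
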