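#' Genotype principal component analysis
#'
#' PCA of a samples-by-variants dosage matrix with the allele-frequency
#' scaling standard in population genomics: each site is centered by
#' twice its allele frequency and scaled by the binomial standard
#' deviation `sqrt(2 p (1 - p))`. Monomorphic sites and sites with more
#' missingness than `max_missing` are dropped (counts recorded as
#' attributes); remaining missing genotypes are mean-imputed for this
#' analysis only.
#'
#' @param gm a [genotype_matrix()] with >= 2 samples and >= 1 polymorphic
#'   site.
#' @param k number of components to return; must be < number of samples.
#' @param max_missing maximum tolerated per-site missing fraction.
#' @return an object of class `pca_result`: list with `scores`
#'   (samples x k), `explained_variance` (length k, non-increasing) and
#'   `n_sites_used`.
#' @export
genotype_pca <- function(gm, k = 2, max_missing = 0.2) {
  stopifnot(inherits(gm, "genotype_matrix"))
  n <- nrow(gm$geno)
  if (n < 2) stop("need >= 2 samples", call. = FALSE)
  if (k >= n) stop("`k` must be smaller than the number of samples",
                   call. = FALSE)
  g <- gm$geno
  miss_frac <- colMeans(is.na(g))
  ok_miss <- miss_frac <= max_missing
  p <- colMeans(g, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  use <- ok_miss & poly
  if (!any(use)) stop("no polymorphic site passes the missingness filter",
                      call. = FALSE)
  g <- g[, use, drop = FALSE]
  p <- p[use]
  x <- sweep(g, 2, 2 * p)
  x[is.na(x)] <- 0                       # mean imputation after centering
  x <- sweep(x, 2, sqrt(2 * p * (1 - p)), "/")
  k_eff <- min(k, ncol(x))   # rank cannot exceed the site count
  sv <- svd(x, nu = k_eff, nv = 0)
  scores <- matrix(0, n, k)
  scores[, seq_len(k_eff)] <- sv$u %*% diag(sv$d[seq_len(k_eff)],
                                            nrow = k_eff)
  rownames(scores) <- gm$sample_ids
  colnames(scores) <- paste0("PC", seq_len(k))
  ev <- rep(0, k)
  ev[seq_len(min(k, length(sv$d)))] <-
    (sv$d^2 / sum(sv$d^2))[seq_len(min(k, length(sv$d)))]
  structure(list(scores = scores,
                 explained_variance = ev,
                 n_sites_used = ncol(g)),
            class = "pca_result",
            n_dropped_monomorphic = sum(!poly),
            n_dropped_missing = sum(poly & !ok_miss))
}

#' @export
print.pca_result <- function(x, ...) {
  cat("Genotype PCA on", x$n_sites_used, "sites\n")
  cat("  explained variance:",
      paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = ", "),
      "\n")
  invisible(x)
}

#' Identity-by-state dissimilarity matrix
#'
#' Pairwise dissimilarity `d(a, b) = 1 - mean(1 - |g_a - g_b| / 2)` over
#' the sites where both samples are genotyped (pairwise-complete). The
#' per-site term is the proportion of shared alleles, so d is 0 for
#' identical genotypes and 1 for opposite homozygotes at every site.
#'
#' @param gm a [genotype_matrix()] with >= 2 samples.
#' @return symmetric matrix of class `c("ibs_dissimilarity", "matrix")`
#'   with zero diagonal and values in `[0, 1]`.
#' @export
ibs_dissimilarity <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  g <- gm$geno
  n <- nrow(g)
  if (n < 2) stop("need >= 2 samples", call. = FALSE)
  d <- matrix(0, n, n, dimnames = list(gm$sample_ids, gm$sample_ids))
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    both <- !is.na(g[a, ]) & !is.na(g[b, ])
    if (!any(both))
      stop("samples ", gm$sample_ids[a], " and ", gm$sample_ids[b],
           " share no genotyped site", call. = FALSE)
    ibs <- 1 - abs(g[a, both] - g[b, both]) / 2
    d[a, b] <- d[b, a] <- 1 - mean(ibs)
  }
  class(d) <- c("ibs_dissimilarity", class(d))
  d
}

#' Average-linkage clustering with a fixed-height cut
#'
#' Builds an agglomerative average-linkage (UPGMA) tree from a pairwise
#' dissimilarity matrix, cuts it at the given height, and serializes the
#' dendrogram as newick text with merge heights as branch lengths.
#'
#' @param d symmetric dissimilarity matrix (e.g. [ibs_dissimilarity()]).
#' @param height cut height (>= 0) in dissimilarity units.
#' @return list with `labels` (named integer group memberships),
#'   `n_groups`, `hclust` (the stats::hclust object) and `newick`.
#' @export
hclust_cut <- function(d, height = 1.0) {
  if (height < 0) stop("`height` must be >= 0", call. = FALSE)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  labels <- stats::cutree(hc, h = height)
  list(labels = labels, n_groups = length(unique(labels)), hclust = hc,
       newick = ape::write.tree(ape::as.phylo(hc)))
}
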