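#' Chromosome partition specification
#'
#' Names a set of chromosomes (e.g. total / autosomes / Z) together with
#' the callable sequence length used to normalize per-site statistics.
#'
#' @param name partition label.
#' @param chroms character vector of chromosome labels in the partition.
#' @param effective_length callable length in bp (> 0) for per-site
#'   normalization.
#' @return an object of class `partition_spec`.
#' @export
partition_spec <- function(name, chroms, effective_length) {
  if (length(chroms) == 0) stop("`chroms` must be non-empty", call. = FALSE)
  if (effective_length <= 0) stop("`effective_length` must be > 0",
                                  call. = FALSE)
  structure(list(name = name, chroms = chroms,
                 effective_length = effective_length),
            class = "partition_spec")
}

# Variant index for a partition, validating the chromosome set.
partition_index <- function(gm, partition) {
  if (is.null(partition)) return(seq_along(gm$chrom))
  unknown <- setdiff(partition$chroms, unique(gm$chrom))
  if (length(unknown) == length(partition$chroms) && ncol(gm$geno) > 0)
    stop("partition '", partition$name,
         "' references no chromosome present in the data", call. = FALSE)
  which(gm$chrom %in% partition$chroms)
}

#' Number of segregating sites
#'
#' Counts variants (within a chromosome partition, within a sample
#' subset) that carry at least one copy of each allele among non-missing
#' genotypes — i.e. columns polymorphic in the selected samples. Sites
#' monomorphic within the subset, or entirely missing, are not counted.
#'
#' @param gm a [genotype_matrix()].
#' @param partition optional [partition_spec()]; default all variants.
#' @param group optional sample subset: sample ids or group labels.
#' @return integer count.
#' @export
segregating_sites <- function(gm, partition = NULL, group = NULL) {
  idx <- partition_index(gm, partition)
  rows <- resolve_samples(gm, group)
  g <- gm$geno[rows, idx, drop = FALSE]
  ac <- colSums(g, na.rm = TRUE)
  an <- colSums(!is.na(g)) * 2L
  sum(ac > 0 & ac < an)
}

#' Watterson's per-site theta
#'
#' `theta_W = S / (a * L)` with `a = sum(1/(1:(n-1)))` the (n-1)-th
#' harmonic number, `n` the number of sequences (haplotypes for nuclear
#' data, individuals for mitochondrial data) and `L` the sequence length
#' in bp.
#'
#' @param S number of segregating sites.
#' @param n number of sequences (>= 2).
#' @param L sequence length, bp (> 0).
#' @return per-site estimate of the population mutation rate.
#' @examples
#' round(watterson_theta(87, 12, 16769), 5)  # 0.00172
#' @export
watterson_theta <- function(S, n, L) {
  if (n < 2) stop("`n` must be >= 2", call. = FALSE)
  if (L <= 0) stop("`L` must be > 0", call. = FALSE)
  if (S < 0) stop("`S` must be >= 0", call. = FALSE)
  S / (sum(1 / seq_len(n - 1)) * L)
}

#' Nucleotide diversity (pi) from a genotype matrix
#'
#' Per-site average pairwise difference between the allele copies of the
#' selected samples:
#' `pi = sum_v 2 * j_v * (m_v - j_v) / (m_v * (m_v - 1)) / L`,
#' where at variant v, `j_v` is the alternate-allele count and `m_v` the
#' number of non-missing allele copies (missingness reduces `m` locally;
#' sites are not dropped). The value is symmetric in the allele labels.
#'
#' @param gm a [genotype_matrix()].
#' @param L callable length in bp used for normalization.
#' @param partition optional [partition_spec()].
#' @param group optional sample subset.
#' @return per-site diversity estimate.
#' @export
nucleotide_diversity <- function(gm, L, partition = NULL, group = NULL) {
  if (L <= 0) stop("`L` must be > 0", call. = FALSE)
  idx <- partition_index(gm, partition)
  rows <- resolve_samples(gm, group)
  g <- gm$geno[rows, idx, drop = FALSE]
  if (ncol(g) > 0 && all(is.na(g)))
    stop("all genotypes missing in the selection", call. = FALSE)
  j <- colSums(g, na.rm = TRUE)
  m <- colSums(!is.na(g)) * 2
  ok <- m >= 2
  sum(2 * j[ok] * (m[ok] - j[ok]) / (m[ok] * (m[ok] - 1))) / L
}

#' Diversity summary table
#'
#' Computes, for each partition and for each sample group (plus the
#' pooled "all" group), the classic resequencing summary: segregating
#' sites S, the length-normalized proportion s = S / effective_length,
#' nucleotide diversity pi, and per-site Watterson's theta. For nuclear
#' genotype data the Watterson sample size is the haplotype count
#' `2 * n_samples`.
#'
#' @param gm a [genotype_matrix()].
#' @param partitions list of [partition_spec()] objects.
#' @param groups optional character vector of group labels present in
#'   `gm$sample_group`; the pooled set is always reported as `"all"`.
#' @return data frame of class `diversity_summary` with one row per
#'   (partition x group).
#' @export
diversity_summary <- function(gm, partitions, groups = NULL) {
  if (inherits(partitions, "partition_spec")) partitions <- list(partitions)
  if (!is.null(groups)) {
    known <- unique(gm$sample_group)
    bad <- setdiff(groups, known)
    if (length(bad)) stop("unknown group label: ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  grps <- c(list(all = NULL), stats::setNames(as.list(groups), groups))
  rows <- list()
  for (p in partitions) {
    for (gname in names(grps)) {
      sel <- grps[[gname]]
      n_samp <- length(resolve_samples(gm, sel))
      S <- segregating_sites(gm, p, sel)
      pi <- nucleotide_diversity(gm, p$effective_length, p, sel)
      th <- watterson_theta(S, 2L * n_samp, p$effective_length)
      rows[[length(rows) + 1L]] <- data.frame(
        partition = p$name, group = gname, n_sequences = 2L * n_samp,
        S = S, s = S / p$effective_length, pi = pi, theta_w = th,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("diversity_summary", "data.frame")
  out
}

#' @export
print.diversity_summary <- function(x, digits = 4, ...) {
  y <- as.data.frame(x)
  y$s <- signif(y$s, digits); y$pi <- signif(y$pi, digits)
  y$theta_w <- signif(y$theta_w, digits)
  print(y, row.names = FALSE)
  invisible(x)
}
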