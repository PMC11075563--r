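#' Construct a genotype matrix object
#'
#' The central container for diploid biallelic genotypes: a samples-by-
#' variants matrix of alternate-allele dosages (0, 1, 2 or `NA` for
#' missing) plus per-variant chromosome, position and depth annotations.
#'
#' @param geno integer matrix, samples in rows, variants in columns,
#'   values in `{0, 1, 2, NA}`.
#' @param chrom character vector of per-variant chromosome labels.
#' @param pos integer vector of 1-based positions, strictly increasing
#'   within each chromosome.
#' @param dp numeric vector of per-variant depth of coverage (DP), or
#'   `NULL`.
#' @param sample_ids character vector of sample labels.
#' @param sample_group optional factor/character of per-sample group
#'   labels (e.g. `"historical"` / `"contemporary"`).
#' @return an object of class `genotype_matrix`.
#' @examples
#' g <- genotype_matrix(matrix(c(0, 1, 2, 0), 2), chrom = c("A1", "A1"),
#'                      pos = c(10, 20), sample_ids = c("s1", "s2"))
#' g
#' @export
genotype_matrix <- function(geno, chrom, pos, dp = NULL,
                            sample_ids = rownames(geno),
                            sample_group = NULL) {
  geno <- as.matrix(geno)
  nv <- ncol(geno)
  if (length(chrom) != nv || length(pos) != nv)
    stop("`chrom` and `pos` must have one entry per variant", call. = FALSE)
  if (!is.null(dp) && length(dp) != nv)
    stop("`dp` must have one entry per variant", call. = FALSE)
  bad <- !(geno %in% c(0L, 1L, 2L) | is.na(geno))
  if (any(bad)) stop("genotype values must be 0, 1, 2 or NA", call. = FALSE)
  if (!is.null(dp) && any(dp < 0, na.rm = TRUE))
    stop("depths must be non-negative", call. = FALSE)
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (length(p) > 1 && any(diff(p) <= 0))
      stop("positions must be strictly increasing within chromosome ", ch,
           call. = FALSE)
  }
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(nrow(geno)))
  if (!is.null(sample_group) && length(sample_group) != nrow(geno))
    stop("`sample_group` must have one entry per sample", call. = FALSE)
  rownames(geno) <- sample_ids
  structure(list(geno = geno, chrom = as.character(chrom),
                 pos = as.integer(pos), dp = dp,
                 sample_ids = sample_ids, sample_group = sample_group),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("Genotype matrix:", nrow(x$geno), "samples x", ncol(x$geno),
      "variants\n")
  cat("  chromosomes:", length(unique(x$chrom)), "\n")
  if (!is.null(x$dp))
    cat("  depth: median", stats::median(x$dp), " range [",
        min(x$dp), ",", max(x$dp), "]\n")
  if (!is.null(x$sample_group)) {
    tb <- table(x$sample_group)
    cat("  groups:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

# Subset variants (logical/integer index) keeping annotations in step.
subset_variants <- function(gm, idx) {
  genotype_matrix(gm$geno[, idx, drop = FALSE], gm$chrom[idx], gm$pos[idx],
                  dp = if (!is.null(gm$dp)) gm$dp[idx],
                  sample_ids = gm$sample_ids, sample_group = gm$sample_group)
}

# Resolve a group selector (NULL = all samples) to a sample index vector.
resolve_samples <- function(gm, group) {
  if (is.null(group)) return(seq_along(gm$sample_ids))
  if (all(group %in% gm$sample_ids)) return(match(group, gm$sample_ids))
  if (!is.null(gm$sample_group) && all(group %in% gm$sample_group))
    return(which(gm$sample_group %in% group))
  stop("unknown sample or group label: ",
       paste(setdiff(group, c(gm$sample_ids, gm$sample_group)),
             collapse = ", "), call. = FALSE)
}

#' Convert simulated haplotypes to a genotype matrix
#'
#' Pairs consecutive haplotypes of each locus into diploid individuals
#' (haplotypes 1+2 form sample 1, and so on), assigns each locus its own
#' chromosome, draws integer infinite-sites positions uniformly within the
#' locus, and annotates per-variant depth from a [depth_model()].
#'
#' @param haps list of haplotype matrices from [simulate_haplotypes()].
#' @param spec the [simulation_spec()] that produced them.
#' @param chrom_labels optional character vector, one chromosome name per
#'   locus; defaults to `A_1 ... A_k` with the last ~10% of loci labelled
#'   `Z_*` to emulate an autosome/Z partition.
#' @param depth optional [depth_model()]; when supplied, per-variant DP is
#'   drawn from it.
#' @param sample_group optional per-sample group labels; for a two-deme
#'   spec the default labels deme 1 `"historical"` and deme 2
#'   `"contemporary"`.
#' @return a [genotype_matrix()].
#' @export
haplotypes_to_genotypes <- function(haps, spec, chrom_labels = NULL,
                                    depth = NULL, sample_group = NULL) {
  n_dip <- spec$n_diploids
  n_loci <- length(haps)
  if (is.null(chrom_labels)) {
    n_z <- max(0L, floor(n_loci / 10))
    chrom_labels <- c(paste0("A_", seq_len(n_loci - n_z)),
                      if (n_z > 0) paste0("Z_", seq_len(n_z)))
  }
  if (is.null(sample_group) && spec$demography$model == "two_deme") {
    deme <- attr(haps[[1]], "deme")[seq(1, 2 * n_dip, by = 2)]
    sample_group <- ifelse(deme == 1L, "historical", "contemporary")
  }
  geno_list <- vector("list", n_loci)
  chrom <- character(0); pos <- integer(0)
  for (l in seq_len(n_loci)) {
    h <- haps[[l]]
    s <- ncol(h)
    if (s > spec$locus_length)
      stop("locus ", l, " has more segregating sites than positions; ",
           "increase `locus_length`", call. = FALSE)
    g <- h[seq(1, nrow(h), by = 2), , drop = FALSE] +
         h[seq(2, nrow(h), by = 2), , drop = FALSE]
    p <- sort(sample.int(spec$locus_length, s))
    # infinite sites: deduplication is by sampling without replacement
    geno_list[[l]] <- g
    chrom <- c(chrom, rep(chrom_labels[l], s))
    pos <- c(pos, p)
  }
  geno <- do.call(cbind, geno_list)
  dp <- if (!is.null(depth)) draw_depths(depth, ncol(geno)) else NULL
  genotype_matrix(geno, chrom, pos, dp = dp,
                  sample_ids = paste0("sample", seq_len(n_dip)),
                  sample_group = sample_group)
}
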