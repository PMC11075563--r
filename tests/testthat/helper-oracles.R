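# Independent brute-force oracles used across the suite.

# Nearest-rank (inverse-ECDF) quantile by explicit sorting.
oracle_nearest_rank <- function(x, q) {
  s <- sort(x)
  s[ceiling(q * length(s))]
}

# Per-site average pairwise difference between allele copies, by exhaustive
# enumeration of copy pairs at every site.
oracle_pi <- function(geno, L) {
  total <- 0
  for (v in seq_len(ncol(geno))) {
    g <- unname(geno[, v])
    copies <- unlist(lapply(g[!is.na(g)], function(d) {
      if (d == 0) c(0, 0) else if (d == 1) c(0, 1) else c(1, 1)
    }))
    m <- length(copies)
    if (m < 2) next
    diffs <- 0
    for (a in seq_len(m - 1)) for (b in (a + 1):m)
      diffs <- diffs + (copies[a] != copies[b])
    total <- total + diffs / (m * (m - 1) / 2)
  }
  total / L
}

# Pairwise IBS dissimilarity by explicit per-pair looping.
oracle_ibs <- function(geno) {
  n <- nrow(geno)
  d <- matrix(0, n, n)
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    num <- 0; den <- 0
    for (v in seq_len(ncol(geno))) {
      if (is.na(geno[a, v]) || is.na(geno[b, v])) next
      num <- num + (1 - abs(geno[a, v] - geno[b, v]) / 2)
      den <- den + 1
    }
    d[a, b] <- d[b, a] <- 1 - num / den
  }
  d
}

# Random genotype matrix with optional missingness.
random_gm <- function(n_samples, n_variants, miss = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- matrix(sample(0:2, n_samples * n_variants, replace = TRUE),
              n_samples)
  if (miss > 0) g[stats::runif(length(g)) < miss] <- NA
  genotype_matrix(g, chrom = rep("A_1", n_variants), pos = seq_len(n_variants),
                  dp = sample(5:50, n_variants, replace = TRUE))
}

# Standard mitogenome mask fixture: three repeat regions, 551 columns.
mito_mask_ranges <- function() {
  data.frame(start = c(966, 1538, 16023), end = c(977, 1574, 16524))
}
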