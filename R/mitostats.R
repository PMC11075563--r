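#' Remove masked column ranges from an alignment
#'
#' Drops the union of the given 1-based inclusive column ranges from
#' every sequence — the treatment applied to repeat/homopolymer regions
#' (monomeric C runs, variable-copy repeats) that cannot be aligned or
#' assembled reliably.
#'
#' @param aln character matrix alignment (sequences x columns), as from
#'   [generate_mito_alignment()] or [read_alignment()].
#' @param ranges data frame with columns `start` and `end` (1-based,
#'   inclusive); overlapping ranges are unioned.
#' @return the masked alignment; attribute `effective_length` holds the
#'   remaining column count.
#' @examples
#' aln <- matrix(rep(c("A", "C", "G", "T"), 2), nrow = 2, byrow = TRUE)
#' ncol(apply_mask(aln, data.frame(start = 2, end = 3)))  # 2
#' @export
apply_mask <- function(aln, ranges) {
  L <- ncol(aln)
  if (is.null(ranges) || nrow(ranges) == 0) {
    attr(aln, "effective_length") <- L
    return(aln)
  }
  if (any(ranges$start < 1 | ranges$end > L | ranges$start > ranges$end))
    stop("mask range out of bounds for a ", L, "-column alignment",
         call. = FALSE)
  drop_cols <- unique(unlist(mapply(seq, ranges$start, ranges$end,
                                    SIMPLIFY = FALSE)))
  out <- aln[, -drop_cols, drop = FALSE]
  class(out) <- class(aln)
  attr(out, "effective_length") <- ncol(out)
  out
}

#' Haplotype count and haplotype diversity
#'
#' `H` is the number of distinct sequences; haplotype diversity is the
#' sample-size-corrected probability that two random sequences differ:
#' `Hd = n * (1 - sum(p_k^2)) / (n - 1)` with `p_k` the relative
#' frequency of haplotype k.
#'
#' @param aln character matrix alignment, >= 2 sequences.
#' @return list with `H` and `Hd`.
#' @examples
#' aln <- rbind(c("A", "A"), c("A", "A"), c("A", "C"), c("A", "C"))
#' haplotype_stats(aln)  # H = 2, Hd = 2/3
#' @export
haplotype_stats <- function(aln) {
  n <- nrow(aln)
  if (n < 2) stop("need at least 2 sequences", call. = FALSE)
  keys <- apply(aln, 1, paste, collapse = "")
  tab <- table(keys)
  p <- as.numeric(tab) / n
  list(H = length(tab), Hd = n * (1 - sum(p^2)) / (n - 1))
}

#' Mitogenome alignment summary statistics
#'
#' The classic alignment-based summary for a set of mitogenomes: number
#' of haplotypes H, haplotype diversity Hd, segregating sites S, per-site
#' nucleotide diversity pi, per-site Watterson's theta (with n = number
#' of sequences), and the mean pairwise p-distance.
#'
#' Columns containing a gap or IUPAC ambiguity code (e.g. the R of a
#' heteroplasmic site) in any sequence are excluded from S and pi
#' (complete deletion); p-distance compares each pair over its
#' pairwise-complete columns. Per-site values are normalized by the
#' post-mask alignment length.
#'
#' @param aln character matrix alignment, >= 2 sequences.
#' @return an object of class `mito_summary`: list with `H`, `Hd`, `S`,
#'   `pi`, `theta`, `mean_p_distance`, `n`, `L`.
#' @export
mito_diversity <- function(aln) {
  n <- nrow(aln)
  if (n < 2) stop("need at least 2 sequences", call. = FALSE)
  L <- ncol(aln)
  if (L == 0) stop("alignment has length 0", call. = FALSE)
  aln_u <- toupper(unclass(aln))
  is_base <- aln_u %in% c("A", "C", "G", "T")
  dim(is_base) <- dim(aln_u)
  clean <- colSums(is_base) == n           # complete-deletion column set
  a_clean <- aln_u[, clean, drop = FALSE]
  n_states <- apply(a_clean, 2, function(col) length(unique(col)))
  S <- sum(n_states > 1)

  # pairwise differences on the complete-deletion columns; p-distance on
  # pairwise-complete columns
  diffs <- 0
  pdist <- numeric(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    diffs <- diffs + sum(a_clean[i, ] != a_clean[j, ])
    both <- is_base[i, ] & is_base[j, ]
    n_comp <- sum(both)
    pdist <- c(pdist, if (n_comp > 0)
      sum(aln_u[i, both] != aln_u[j, both]) / n_comp else NA_real_)
  }
  n_pairs <- n * (n - 1) / 2
  hs <- haplotype_stats(aln_u)
  structure(list(H = hs$H, Hd = hs$Hd, S = S,
                 pi = diffs / n_pairs / L,
                 theta = watterson_theta(S, n, L),
                 mean_p_distance = mean(pdist, na.rm = TRUE),
                 n = n, L = L),
            class = "mito_summary")
}

#' @export
print.mito_summary <- function(x, ...) {
  cat("Mitogenome summary (", x$n, "sequences,", x$L, "bp )\n")
  cat(sprintf("  H = %d   Hd = %.4g   S = %d\n", x$H, x$Hd, x$S))
  cat(sprintf("  pi = %.5f   theta = %.5f   mean p-distance = %.5f\n",
              x$pi, x$theta, x$mean_p_distance))
  invisible(x)
}

#' Read a BED-like mask table
#'
#' Three-column TSV (`name`, `start`, `end`), 1-based inclusive alignment
#' column coordinates.
#'
#' @param path TSV path; lines starting with `#` ignored.
#' @return data frame with `name`, `start`, `end`.
#' @export
read_mask <- function(path) {
  m <- utils::read.table(path, header = FALSE, sep = "\t",
                         comment.char = "#", stringsAsFactors = FALSE)
  names(m)[1:3] <- c("name", "start", "end")
  m
}
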