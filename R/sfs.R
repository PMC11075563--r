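#' Folded site frequency spectrum
#'
#' For a sample of n diploids (2n allele copies) the folded SFS is the
#' vector `eta[i]`, i = 1..n, counting sites whose minor-allele copy
#' number is i. Sites monomorphic in the selected samples contribute
#' nothing; sites with any missing genotype among the selected samples
#' are skipped (and counted in the `n_skipped_missing` attribute) rather
#' than projected down. A site at exactly 50% frequency belongs to the
#' top class i = n.
#'
#' @param gm a [genotype_matrix()], or a binary haplotype matrix from
#'   [simulate_locus()] (rows = haplotypes).
#' @param group optional sample subset (ids or group labels); every
#'   selected sample must be genotyped at a site for it to count.
#' @return an object of class `folded_sfs`: list with `eta` (named count
#'   vector), `n_diploids`, `n_alleles`.
#' @examples
#' h <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 0))  # 4 haplotypes
#' folded_sfs(h)$eta
#' @export
folded_sfs <- function(gm, group = NULL) {
  if (is.matrix(gm)) {
    if (nrow(gm) %% 2 != 0)
      stop("haplotype matrix must have an even number of rows",
           call. = FALSE)
    ac <- colSums(gm)
    an <- rep(nrow(gm), ncol(gm))
    n_dip <- nrow(gm) / 2
    n_skip <- 0L
  } else {
    stopifnot(inherits(gm, "genotype_matrix"))
    rows <- resolve_samples(gm, group)
    if (length(rows) == 0) stop("empty sample subset", call. = FALSE)
    g <- gm$geno[rows, , drop = FALSE]
    complete <- colSums(is.na(g)) == 0
    n_skip <- sum(!complete)
    g <- g[, complete, drop = FALSE]
    ac <- colSums(g)
    n_dip <- length(rows)
    an <- rep(2L * n_dip, ncol(g))
  }
  minor <- pmin(ac, an - ac)
  minor <- minor[minor > 0]
  eta <- tabulate(minor, nbins = n_dip)
  names(eta) <- seq_len(n_dip)
  structure(list(eta = eta, n_diploids = n_dip, n_alleles = 2L * n_dip),
            class = "folded_sfs", n_skipped_missing = n_skip)
}

#' Fold an unfolded spectrum
#'
#' Folds a vector of derived-allele-count classes `xi[i]`, i = 1..2n-1,
#' into minor-allele classes: `eta[i] = xi[i] + xi[2n-i]` for i < n and
#' `eta[n] = xi[n]`.
#'
#' @param xi numeric vector of length `2n - 1` of unfolded class counts.
#' @return a `folded_sfs`.
#' @examples
#' fold_spectrum(c(3, 2, 1, 0, 2))$eta  # 5 2 1
#' @export
fold_spectrum <- function(xi) {
  if (length(xi) %% 2 != 1)
    stop("unfolded spectrum must have 2n - 1 classes", call. = FALSE)
  n2 <- length(xi) + 1L          # 2n allele copies
  n <- n2 / 2
  eta <- vapply(seq_len(n), function(i)
    if (i < n) xi[i] + xi[n2 - i] else xi[i], numeric(1))
  names(eta) <- seq_len(n)
  structure(list(eta = eta, n_diploids = n, n_alleles = n2),
            class = "folded_sfs", n_skipped_missing = 0L)
}

#' @export
print.folded_sfs <- function(x, ...) {
  cat("Folded SFS,", x$n_diploids, "diploids (", x$n_alleles,
      "allele copies ),", sum(x$eta), "sites\n")
  print(x$eta)
  invisible(x)
}

#' Flattening transform of the folded SFS
#'
#' Reweights the folded classes so that the constant-population-size
#' expectation is flat: raw weights `r[i] = eta[i] * i * (2n - i) / (2n)`
#' for i < n and `r[n] = eta[n] * n`, renormalized to proportions
#' `phi = r / sum(r)`. Under the standard neutral coalescent
#' `E[eta[i]]` is proportional to `1/i + 1/(2n - i)` (and `1/n` for the
#' top class), so every weighted class has the same expectation and the
#' transformed spectrum of a constant-size population sits at `1/n` in
#' each of the n classes; an excess at low classes signals population
#' expansion.
#'
#' @param f a `folded_sfs` with at least one segregating site.
#' @return an object of class `transformed_sfs`: list with `phi` (sums to
#'   1), `n_classes`.
#' @export
sfs_transform <- function(f) {
  stopifnot(inherits(f, "folded_sfs"))
  if (sum(f$eta) == 0) stop("empty spectrum: no segregating sites",
                            call. = FALSE)
  n <- f$n_diploids
  n2 <- f$n_alleles
  i <- seq_len(n)
  w <- ifelse(i < n, i * (n2 - i) / n2, n)
  r <- f$eta * w
  structure(list(phi = r / sum(r), n_classes = n),
            class = "transformed_sfs")
}

#' @export
print.transformed_sfs <- function(x, ...) {
  cat("Transformed SFS,", x$n_classes, "classes (flat expectation",
      sprintf("1/%d = %.4f )\n", x$n_classes, 1 / x$n_classes))
  print(round(x$phi, 4))
  invisible(x)
}

#' Two-panel spectrum figure
#'
#' Left panel: raw folded counts per minor-allele-frequency class. Right
#' panel: the flattening-transformed proportions with a reference line at
#' `1/n_classes`, the constant-population expectation.
#'
#' @param f a `folded_sfs`.
#' @param t the matching `transformed_sfs`.
#' @param out output file path (`.png` or `.pdf`).
#' @return invisibly, the path.
#' @export
plot_spectra <- function(f, t, out) {
  if (grepl("\\.pdf$", out)) grDevices::pdf(out, width = 9, height = 4.5)
  else grDevices::png(out, width = 900, height = 450)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  graphics::barplot(f$eta, names.arg = names(f$eta),
                    xlab = "minor-allele copies", ylab = "sites",
                    main = "Folded SFS", col = "steelblue")
  graphics::barplot(t$phi, names.arg = seq_len(t$n_classes),
                    xlab = "minor-allele copies", ylab = expression(phi),
                    main = "Transformed", col = "grey70")
  graphics::abline(h = 1 / t$n_classes, lty = 2, col = "red")
  invisible(out)
}
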