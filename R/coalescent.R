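#' Demography models for the coalescent simulator
#'
#' Constructors for the three demographic scenarios the simulator supports.
#' Time is measured backwards from the present in coalescent units (2N
#' generations for the reference population size N); under these units a
#' pair of lineages in a constant-size population coalesces at rate 1.
#'
#' * `demography_constant()` — a single panmictic population of constant
#'   size.
#' * `demography_growth(rate)` — exponential growth towards the present at
#'   rate `rate` per coalescent time unit, i.e. the population was smaller
#'   in the past by a factor `exp(-rate * t)`, so the pairwise coalescent
#'   rate at time `t` is `exp(rate * t)`.
#' * `demography_two_deme(split_depth)` — two demes of equal size with no
#'   migration that merge into a single ancestral population at time
#'   `split_depth`; samples are split evenly between the demes.
#'
#' @param rate exponential growth rate per coalescent time unit (> 0).
#' @param split_depth time of the deme merger, coalescent units (> 0).
#' @return an object of class `demography`.
#' @examples
#' demography_growth(5)
#' @export
demography_constant <- function() {
  structure(list(model = "constant"), class = "demography")
}

#' @rdname demography_constant
#' @export
demography_growth <- function(rate) {
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("growth `rate` must be a single positive number", call. = FALSE)
  structure(list(model = "growth", rate = rate), class = "demography")
}

#' @rdname demography_constant
#' @export
demography_two_deme <- function(split_depth) {
  if (!is.numeric(split_depth) || length(split_depth) != 1L ||
      !is.finite(split_depth) || split_depth <= 0)
    stop("`split_depth` must be a single positive number", call. = FALSE)
  structure(list(model = "two_deme", split_depth = split_depth,
                 migration = 0), class = "demography")
}

#' Specification of a multi-locus coalescent simulation
#'
#' Bundles the parameters that drive the synthetic-data generator: the
#' sample size, the per-locus scaled mutation rate, the number of
#' independent (unlinked, non-recombining) loci, the demography and the
#' locus length used when placing infinite-sites mutations at integer
#' positions.
#'
#' `theta` follows the usual ms convention: for a sample of k sequences
#' the expected number of segregating sites per locus is
#' `theta * sum(1/(1:(k-1)))` and the expected average number of pairwise
#' differences per locus is `theta`.
#'
#' @param n_diploids number of diploid individuals (>= 2); the simulator
#'   draws `2 * n_diploids` haplotypes per locus.
#' @param theta per-locus scaled mutation rate (> 0).
#' @param n_loci number of independent loci (>= 1).
#' @param demography a [demography_constant()], [demography_growth()] or
#'   [demography_two_deme()] object.
#' @param locus_length locus length in bp; mutation positions are drawn
#'   uniformly on `1:locus_length` without replacement.
#' @return an object of class `simulation_spec`.
#' @examples
#' simulation_spec(n_diploids = 11, theta = 5, n_loci = 100)
#' @export
simulation_spec <- function(n_diploids, theta, n_loci,
                            demography = demography_constant(),
                            locus_length = 10000L) {
  if (!is.numeric(n_diploids) || n_diploids < 2)
    stop("`n_diploids` must be >= 2", call. = FALSE)
  if (!is.numeric(theta) || theta <= 0)
    stop("`theta` must be > 0", call. = FALSE)
  if (!is.numeric(n_loci) || n_loci < 1)
    stop("`n_loci` must be >= 1", call. = FALSE)
  if (!inherits(demography, "demography"))
    stop("`demography` must be built by a demography_*() constructor",
         call. = FALSE)
  if (locus_length < 1) stop("`locus_length` must be >= 1", call. = FALSE)
  structure(list(n_diploids = as.integer(n_diploids), theta = theta,
                 n_loci = as.integer(n_loci), demography = demography,
                 locus_length = as.integer(locus_length)),
            class = "simulation_spec")
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat("Coalescent simulation spec\n")
  cat("  diploids:", x$n_diploids, " (", 2L * x$n_diploids, "haplotypes )\n")
  cat("  theta/locus:", x$theta, "  loci:", x$n_loci,
      "  locus length:", x$locus_length, "bp\n")
  cat("  demography:", x$demography$model, "\n")
  invisible(x)
}

# Draw one genealogy: returns segments (per-lineage branch pieces) with
# their lengths and the tip sets below them.  n_hap tips; deme is an
# integer vector of tip deme labels (all 1 for panmictic models).
sim_genealogy <- function(n_hap, demography) {
  deme <- rep(1L, n_hap)
  if (demography$model == "two_deme") {
    deme <- rep(c(1L, 2L), length.out = n_hap)
    deme <- sort(deme)  # first half deme 1, second half deme 2
  }
  desc <- as.list(seq_len(n_hap))       # tip sets of active lineages
  lin_deme <- deme
  t_now <- 0
  merged <- demography$model != "two_deme"
  seg_len <- numeric(0)
  seg_desc <- list()

  add_segments <- function(dt) {
    if (dt <= 0) return(invisible(NULL))
    k <- length(desc)
    seg_len <<- c(seg_len, rep(dt, k))
    seg_desc <<- c(seg_desc, desc)
    invisible(NULL)
  }

  while (length(desc) > 1L) {
    k <- length(desc)
    if (!merged) {
      k1 <- sum(lin_deme == 1L); k2 <- k - k1
      rate <- k1 * (k1 - 1) / 2 + k2 * (k2 - 1) / 2
      dt <- if (rate > 0) stats::rexp(1, rate) else Inf
      if (t_now + dt >= demography$split_depth) {
        add_segments(demography$split_depth - t_now)
        t_now <- demography$split_depth
        merged <- TRUE
        lin_deme[] <- 1L
        next
      }
      add_segments(dt)
      t_now <- t_now + dt
      p1 <- k1 * (k1 - 1) / 2 / rate
      d <- if (stats::runif(1) < p1) 1L else 2L
      idx <- which(lin_deme == d)
      pair <- sample(idx, 2L)
    } else {
      pair_rate <- k * (k - 1) / 2
      if (demography$model == "growth") {
        r <- demography$rate
        # hazard(t) = pair_rate * exp(r t); invert the cumulative hazard
        e <- stats::rexp(1)
        dt <- log(1 + r * e / (pair_rate * exp(r * t_now))) / r
      } else {
        dt <- stats::rexp(1, pair_rate)
      }
      add_segments(dt)
      t_now <- t_now + dt
      pair <- sample.int(k, 2L)
    }
    i <- min(pair); j <- max(pair)
    desc[[i]] <- c(desc[[i]], desc[[j]])
    desc[[j]] <- NULL
    lin_deme <- lin_deme[-j]
  }
  list(seg_len = seg_len, seg_desc = seg_desc, tmrca = t_now, deme = deme)
}

#' Simulate one locus under the coalescent with infinite-sites mutation
#'
#' Draws a genealogy for `2 * n_diploids` haplotypes from the demography in
#' `spec` (Hudson's algorithm: exponential waiting times between
#' coalescences, no intra-locus recombination), then drops a
#' `Poisson(theta/2 * total branch length)` number of mutations uniformly
#' on the branches. Each mutation creates a new biallelic column whose
#' carriers are the tips below the mutated branch.
#'
#' @param spec a [simulation_spec()].
#' @return binary matrix, `2 * n_diploids` rows (haplotypes) by S columns
#'   (segregating sites); 1 marks the derived allele. Attribute `tmrca`
#'   holds the tree height in coalescent units; attribute `deme` the tip
#'   deme labels.
#' @examples
#' set.seed(1)
#' h <- simulate_locus(simulation_spec(3, theta = 2, n_loci = 1))
#' colSums(h)  # derived-allele counts per site
#' @export
simulate_locus <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  n_hap <- 2L * spec$n_diploids
  g <- sim_genealogy(n_hap, spec$demography)
  total_len <- sum(g$seg_len)
  s <- stats::rpois(1, spec$theta / 2 * total_len)
  out <- matrix(0L, nrow = n_hap, ncol = s)
  if (s > 0) {
    hit <- sample.int(length(g$seg_len), s, replace = TRUE,
                      prob = g$seg_len)
    for (m in seq_len(s)) out[g$seg_desc[[hit[m]]], m] <- 1L
  }
  attr(out, "tmrca") <- g$tmrca
  attr(out, "deme") <- g$deme
  out
}

#' Simulate all loci of a specification
#'
#' Calls [simulate_locus()] once per locus. Results are reproducible for a
#' fixed `seed`.
#'
#' @param spec a [simulation_spec()].
#' @param seed optional integer seed applied before simulation.
#' @return list of haplotype matrices, one per locus (see
#'   [simulate_locus()]).
#' @export
simulate_haplotypes <- function(spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(spec$n_loci), function(i) simulate_locus(spec))
}
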