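test_that("spec and demography constructors validate their inputs", {
  expect_error(simulation_spec(1, 1, 1), ">= 2")
  expect_error(simulation_spec(5, 0, 1), "> 0")
  expect_error(demography_growth(-1), "positive")
  expect_error(demography_two_deme(0), "positive")
  expect_error(simulation_spec(5, 1, 1, demography = list(model = "x")),
               "demography")
})

test_that("TMRCA of two lineages has mean 1 in coalescent units", {
  set.seed(7)
  t2 <- replicate(10000, woodpop:::sim_genealogy(2, demography_constant())$tmrca)
  se <- sd(t2) / sqrt(length(t2))
  expect_lt(abs(mean(t2) - 1), 3 * se)
})

test_that("segregating sites match the Watterson expectation across designs", {
  set.seed(101)
  for (cfg in list(c(n = 2, theta = 1), c(n = 5, theta = 2),
                   c(n = 11, theta = 10))) {
    n_loci <- 400
    spec <- simulation_spec(cfg[["n"]], cfg[["theta"]], n_loci,
                            locus_length = 50000)
    s <- vapply(simulate_haplotypes(spec), ncol, integer(1))
    expected <- cfg[["theta"]] * sum(1 / seq_len(2 * cfg[["n"]] - 1))
    se <- sd(s) / sqrt(n_loci)
    expect_lt(abs(mean(s) - expected), 3 * se)
  }
})

test_that("mean pairwise differences match theta", {
  set.seed(19)
  spec <- simulation_spec(5, theta = 2, n_loci = 600)
  pi_locus <- vapply(simulate_haplotypes(spec), function(h) {
    k <- nrow(h); j <- colSums(h)
    sum(2 * j * (k - j) / (k * (k - 1)))
  }, numeric(1))
  se <- sd(pi_locus) / sqrt(length(pi_locus))
  expect_lt(abs(mean(pi_locus) - 2), 3 * se)
})

test_that("theta -> 0 gives zero segregating sites", {
  set.seed(3)
  spec <- simulation_spec(5, theta = 1e-9, n_loci = 50)
  expect_true(all(vapply(simulate_haplotypes(spec), ncol, integer(1)) == 0))
})

test_that("identical spec and seed give identical haplotypes and VCF bytes", {
  spec <- simulation_spec(4, theta = 3, n_loci = 10)
  h1 <- simulate_haplotypes(spec, seed = 99)
  h2 <- simulate_haplotypes(spec, seed = 99)
  expect_identical(h1, h2)
  v1 <- tempfile(fileext = ".vcf"); v2 <- tempfile(fileext = ".vcf")
  set.seed(5); write_vcf(h1, v1, spec)
  set.seed(5); write_vcf(h2, v2, spec)
  expect_identical(readLines(v1), readLines(v2))
})

test_that("growth demography yields more singletons than constant size", {
  set.seed(23)
  n_loci <- 500
  frac_singleton <- function(demog) {
    spec <- simulation_spec(6, theta = 4, n_loci, demography = demog)
    eta <- Reduce(`+`, lapply(simulate_haplotypes(spec),
                              function(h) folded_sfs(h)$eta))
    eta[1] / sum(eta)
  }
  expect_gt(frac_singleton(demography_growth(20)),
            frac_singleton(demography_constant()))
})

test_that("VCF records recount the simulated haplotype columns", {
  set.seed(31)
  spec <- simulation_spec(2, theta = 20, n_loci = 1, locus_length = 1000)
  haps <- simulate_haplotypes(spec)
  expect_error(write_vcf(haps[[1]][1:3, , drop = FALSE], tempfile(), spec),
               "odd")
  vcf <- tempfile(fileext = ".vcf")
  write_vcf(haps, vcf, spec)
  body <- grep("^[^#]", readLines(vcf), value = TRUE)
  expect_length(body, ncol(haps[[1]]))
  # allele count per record equals the haplotype column sum
  gt <- sapply(strsplit(body, "\t"), function(f) f[10:11])
  ac <- apply(gt, 2, function(g)
    sum(as.integer(unlist(strsplit(sub(":.*", "", g), "\\|")))))
  expect_equal(unname(ac), unname(colSums(haps[[1]])))
})

test_that("zero segregating sites writes a header-only VCF", {
  set.seed(1)
  spec <- simulation_spec(3, theta = 1e-9, n_loci = 2)
  vcf <- tempfile(fileext = ".vcf")
  write_vcf(simulate_haplotypes(spec), vcf, spec)
  expect_length(grep("^[^#]", readLines(vcf)), 0)
})

test_that("depth model without outliers concentrates on its mean", {
  set.seed(41)
  dp <- draw_depths(depth_model(mean_depth = 30, dispersion = 8,
                                outlier_fraction = 0), 1e5)
  expect_lt(abs(mean(dp) - 30) / 30, 0.05)
  expect_true(all(dp >= 0))
})

test_that("depth model outlier tail separates median from 90th percentile", {
  set.seed(43)
  dp <- draw_depths(depth_model(mean_depth = 22.7, dispersion = 5,
                                outlier_fraction = 0.02,
                                outlier_scale = 5), 5e4)
  expect_gt(max(dp), 10 * median(dp))
})

test_that("coords generator respects truth and is deterministic", {
  tr <- rearrangement_truth(data.frame(
    query_chrom = c("q1", "q2"), ref_chrom = c("chr1", "chr2"),
    ref_start = 1, ref_end = 3e6, orientation = "+"))
  set.seed(5)
  co <- generate_coords(tr, blocks_per_segment = 100, spurious_rate = 0)
  pairs_seen <- unique(paste(co$query_chrom, co$ref_chrom))
  pairs_truth <- paste(tr$segments$query_chrom, tr$segments$ref_chrom)
  expect_true(all(pairs_seen %in% pairs_truth))
  set.seed(5)
  co2 <- generate_coords(tr, blocks_per_segment = 100, spurious_rate = 0)
  expect_identical(co, co2)
  f1 <- tempfile(); f2 <- tempfile()
  write_coords(co, f1); write_coords(co2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("truth constructor rejects duplicated segments", {
  expect_error(rearrangement_truth(data.frame(
    query_chrom = "q1", ref_chrom = c("chr1", "chr1"),
    ref_start = 1, ref_end = 100, orientation = "+")), "overlapping")
})

test_that("mito alignment with theta 0 is clonal; repeat regions maskable", {
  set.seed(2)
  aln <- generate_mito_alignment(5, theta = 0, length = 500)
  expect_equal(haplotype_stats(aln)$H, 1)
  expect_equal(haplotype_stats(aln)$Hd, 0)
  aln2 <- generate_mito_alignment(12, theta = 10, length = 17320,
                                  repeat_ranges = mito_mask_ranges())
  expect_true(all(aln2[, 966:977] == "C"))
  masked <- apply_mask(aln2, mito_mask_ranges())
  expect_equal(ncol(masked), 16769)
})

test_that("mito alignment segregating sites track theta", {
  set.seed(47)
  theta <- 87 / sum(1 / (1:11))   # E[S] = 87 for 12 sequences
  s <- replicate(200, mito_diversity(
    generate_mito_alignment(12, theta, length = 17320))$S)
  se <- sd(s) / sqrt(length(s))
  expect_lt(abs(mean(s) - 87), 3 * se)
})

test_that("simulator folded SFS is indistinguishable from msprime's", {
  # small theta per locus keeps sites nearly independent (at most ~1 site
  # per genealogy), which the chi-square contingency test requires
  n_dip <- 6; theta <- 0.3; n_loci <- 5000
  set.seed(1)
  spec <- simulation_spec(n_dip, theta, n_loci)
  eta_pkg <- Reduce(`+`, lapply(simulate_haplotypes(spec),
                                function(h) folded_sfs(h)$eta))
  py <- tempfile(fileext = ".py")
  writeLines(c(
    "import msprime, numpy as np, sys",
    "theta, n_dip, n_loci, seed = float(sys.argv[1]), int(sys.argv[2]), int(sys.argv[3]), int(sys.argv[4])",
    "eta = np.zeros(n_dip)",
    "reps = msprime.sim_ancestry(samples=n_dip, ploidy=2, population_size=0.5,",
    "    sequence_length=1000, num_replicates=n_loci, random_seed=seed)",
    "for i, ts in enumerate(reps):",
    "    mts = msprime.sim_mutations(ts, rate=theta/2/1000,",
    "        random_seed=seed + i + 1, discrete_genome=False)",
    "    afs = mts.allele_frequency_spectrum(polarised=False, span_normalise=False)",
    "    eta += afs[1:n_dip + 1]",
    "print(','.join(str(int(x)) for x in eta))"), py)
  out <- system2("python", c(py, theta, n_dip, n_loci, 1234), stdout = TRUE)
  eta_ms <- as.numeric(strsplit(out[length(out)], ",")[[1]])
  expect_length(eta_ms, n_dip)
  p <- suppressWarnings(chisq.test(rbind(eta_pkg, eta_ms)))$p.value
  expect_gt(p, 0.01)
})
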