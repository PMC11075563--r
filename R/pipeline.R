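#' End-to-end analysis pipeline on simulated data
#'
#' Wires the stages together through files, the way the subcommands would
#' be run by hand: simulate genotypes and write a VCF, read it back,
#' apply the depth filter, then compute the diversity table, the folded
#' and transformed SFS (with figure), the genotype PCA and the
#' IBS-clustering groups. Every output is a plain-text table stamped
#' with the configuration hash; a JSON manifest records parameters and
#' input checksums. Reruns with the same config and seed are
#' byte-identical.
#'
#' @param config list with elements `out_dir`, `seed`, and optionally
#'   `spec` (a [simulation_spec()]), `depth` (a [depth_model()]),
#'   `min_dp`, `ceiling_quantile`, `sfs_group`, `cut_height`. When an
#'   existing `vcf` path is supplied the simulation stage is skipped.
#' @return invisibly, the output directory; side effect: files
#'   `sim.vcf`, `filtered.vcf`, `filter_report.tsv`, `diversity.tsv`,
#'   `sfs.tsv`, `sfs.png`, `pca_scores.tsv`, `dissimilarity.tsv`,
#'   `tree.nwk`, `groups.tsv`, `manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.null(config$out_dir)) stop("config needs `out_dir`", call. = FALSE)
  if (is.null(config$seed)) stop("config needs `seed`", call. = FALSE)
  if (!is.null(config$vcf) && !file.exists(config$vcf))
    stop("config `vcf` does not exist: ", config$vcf, call. = FALSE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- config$spec %||% simulation_spec(11, theta = 5, n_loci = 200)
  depth <- config$depth %||% depth_model()
  min_dp <- config$min_dp %||% 10
  ceiling_q <- config$ceiling_quantile %||% 0.90
  cut_height <- config$cut_height %||% 1.0

  cfg_txt <- paste(deparse(config[setdiff(names(config), "out_dir")]),
                   collapse = "")
  tf <- tempfile(); writeLines(cfg_txt, tf)
  cfg_hash <- unname(tools::md5sum(tf)); unlink(tf)
  stamp <- paste0("# config_hash: ", cfg_hash)
  out <- function(f) file.path(config$out_dir, f)
  write_stamped <- function(df, f) {
    con <- file(out(f), "w"); on.exit(close(con))
    writeLines(stamp, con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  set.seed(config$seed)
  if (is.null(config$vcf)) {
    haps <- simulate_haplotypes(spec)
    vcf_path <- out("sim.vcf")
    write_vcf(haps, vcf_path, spec, depth = depth)
  } else vcf_path <- config$vcf

  gm <- read_vcf(vcf_path)
  flt <- apply_depth_filter(gm, min_dp = min_dp,
                            ceiling_quantile = ceiling_q)
  write_gm_vcf(flt$gm, out("filtered.vcf"))
  write_stamped(data.frame(n_input = flt$report$n_input,
                           n_retained = flt$report$n_retained,
                           dp_ceiling = flt$report$dp_ceiling,
                           interval_low = flt$report$retained_interval[1],
                           interval_high = flt$report$retained_interval[2],
                           dp_source = flt$report$dp_source),
                "filter_report.tsv")

  gmf <- flt$gm
  chroms <- unique(gmf$chrom)
  auto <- grep("^A", chroms, value = TRUE)
  zchr <- grep("^Z", chroms, value = TRUE)
  L_per_chrom <- spec$locus_length
  parts <- list(partition_spec("total", chroms,
                               length(chroms) * L_per_chrom))
  if (length(auto) && length(zchr)) {
    parts <- c(parts,
               list(partition_spec("autosomes", auto,
                                   length(auto) * L_per_chrom),
                    partition_spec("Z", zchr, length(zchr) * L_per_chrom)))
  }
  div <- diversity_summary(gmf, parts, groups = unique(gmf$sample_group))
  write_stamped(as.data.frame(div), "diversity.tsv")

  f <- folded_sfs(gmf, group = config$sfs_group)
  if (sum(f$eta) > 0) {
    t <- sfs_transform(f)
    write_stamped(data.frame(class = seq_along(f$eta), eta = f$eta,
                             phi = t$phi), "sfs.tsv")
    plot_spectra(f, t, out("sfs.png"))
  }

  if (nrow(gmf$geno) >= 3 && ncol(gmf$geno) >= 2) {
    pca <- genotype_pca(gmf, k = min(2L, nrow(gmf$geno) - 1L))
    write_stamped(data.frame(sample = rownames(pca$scores),
                             round(pca$scores, 6)), "pca_scores.tsv")
    d <- ibs_dissimilarity(gmf)
    write_stamped(data.frame(sample = rownames(d), round(unclass(d), 6)),
                  "dissimilarity.tsv")
    hc <- hclust_cut(d, height = cut_height)
    writeLines(c(stamp, hc$newick), out("tree.nwk"))
    write_stamped(data.frame(sample = names(hc$labels),
                             group = hc$labels), "groups.tsv")
  }

  manifest <- list(package = "woodpop",
                   version = as.character(utils::packageVersion("woodpop")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."),
                   seed = config$seed, config_hash = cfg_hash,
                   parameters = list(
                     n_diploids = spec$n_diploids, theta = spec$theta,
                     n_loci = spec$n_loci,
                     demography = spec$demography$model,
                     min_dp = min_dp, ceiling_quantile = ceiling_q,
                     cut_height = cut_height),
                   input_checksums = as.list(tools::md5sum(vcf_path)))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(config$out_dir)
}
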