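#' Read a VCF into a genotype matrix
#'
#' Loads a VCF (plain or bgzipped) through vcfR and keeps biallelic SNP
#' records only; multiallelic records and indels are dropped and counted.
#' Genotypes become alternate-allele dosages (0/1/2), `./.` becomes `NA`.
#' Per-variant depth is taken from INFO/DP when present, otherwise from
#' the sum of per-sample FORMAT/DP values; the source used is recorded.
#'
#' @param path VCF file path.
#' @return a [genotype_matrix()] with attributes `n_dropped_multiallelic`,
#'   `n_dropped_indel` and `dp_source` (`"INFO"`, `"FORMAT_sum"` or
#'   `"none"`).
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  n_body <- length(grep("^[^#]", readLines(path, warn = FALSE)))
  if (n_body == 0) {
    # header-only VCF: empty matrix with the declared samples
    hdr <- readLines(path, warn = FALSE)
    chrom_line <- grep("^#CHROM", hdr, value = TRUE)
    ids <- if (length(chrom_line))
      utils::tail(strsplit(chrom_line, "\t")[[1]], -9L) else character(0)
    gm <- genotype_matrix(matrix(integer(0), nrow = max(1L, length(ids)),
                                 ncol = 0),
                          chrom = character(0), pos = integer(0),
                          dp = NULL, sample_ids =
                            if (length(ids)) ids else "sample1")
    attr(gm, "n_dropped_multiallelic") <- 0L
    attr(gm, "n_dropped_indel") <- 0L
    attr(gm, "dp_source") <- "none"
    return(gm)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix  # includes the INFO column, unlike getFIX()
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  multi <- grepl(",", alt)
  snp <- nchar(ref) == 1 & nchar(alt) == 1 & ref %in% c("A", "C", "G", "T") &
    alt %in% c("A", "C", "G", "T") & !is.na(alt)
  keep <- !multi & snp
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field", call. = FALSE)
  gt <- gt[keep, , drop = FALSE]
  dose <- apply(gt, 2, function(col) {
    a <- strsplit(col, "[/|]")
    vapply(a, function(x) {
      if (any(x == "." | is.na(x))) return(NA_integer_)
      sum(as.integer(x))
    }, integer(1))
  })
  if (is.null(dim(dose))) dose <- matrix(dose, nrow = sum(keep))
  info <- fix[keep, "INFO"]
  dp_info <- suppressWarnings(as.numeric(sub(".*\\bDP=([0-9.]+).*", "\\1",
                                             info)))
  has_info_dp <- grepl("(^|;)DP=", info)
  if (all(has_info_dp) && length(info) > 0) {
    dp <- dp_info
    dp_source <- "INFO"
  } else {
    dp_fmt <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
    if (!is.null(dp_fmt)) {
      dp <- unname(rowSums(dp_fmt[keep, , drop = FALSE], na.rm = TRUE))
      dp_source <- "FORMAT_sum"
    } else {
      dp <- NULL
      dp_source <- "none"
    }
  }
  gm <- genotype_matrix(t(dose), chrom = fix[keep, "CHROM"],
                        pos = as.integer(fix[keep, "POS"]), dp = dp,
                        sample_ids = colnames(gt))
  attr(gm, "n_dropped_multiallelic") <- sum(multi)
  attr(gm, "n_dropped_indel") <- sum(!snp & !multi)
  attr(gm, "dp_source") <- dp_source
  gm
}

#' Nearest-rank empirical depth quantile
#'
#' The depth ceiling used by the retention rule is the inverse-ECDF
#' (nearest-rank, type-1) quantile of the observed per-variant depth
#' distribution: the smallest observed value x such that at least a
#' fraction `q` of depths are <= x.
#'
#' @param dp numeric vector of depths (NA allowed, ignored).
#' @param q quantile in (0, 1); default 0.90.
#' @return the depth quantile (one of the observed values).
#' @examples
#' depth_ceiling(1:100, 0.90)  # 90
#' @export
depth_ceiling <- function(dp, q = 0.90) {
  dp <- dp[is.finite(dp)]
  if (length(dp) == 0) stop("no finite depth values", call. = FALSE)
  if (q <= 0 || q >= 1) stop("`q` must be in (0, 1)", call. = FALSE)
  out <- unname(stats::quantile(dp, q, type = 1, names = FALSE))
  if (is.integer(dp)) out <- as.integer(out)  # quantile promotes to double
  out
}

#' Depth-interval variant retention
#'
#' Retains a variant iff its depth lies in the closed interval
#' `[min_dp, ceiling]`, where the ceiling is the nearest-rank
#' `ceiling_quantile` quantile of the full pre-filter depth distribution
#' (computed once, not iteratively). This removes both poorly supported
#' variants and the deep-coverage outliers produced by collapsed repeats.
#'
#' @param gm a [genotype_matrix()] with `dp` populated.
#' @param min_dp lower depth bound, fold-coverage (default 10).
#' @param ceiling_quantile quantile for the upper bound (default 0.90).
#' @return list with elements `gm` (the filtered [genotype_matrix()]) and
#'   `report` — a `filter_report` with `n_input`, `n_retained`,
#'   `dp_ceiling`, `retained_interval` and `dp_source`.
#' @export
apply_depth_filter <- function(gm, min_dp = 10, ceiling_quantile = 0.90) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(gm$dp)) stop("genotype matrix has no depth annotation",
                           call. = FALSE)
  ceil <- depth_ceiling(gm$dp, ceiling_quantile)
  keep <- !is.na(gm$dp) & gm$dp >= min_dp & gm$dp <= ceil
  report <- structure(list(
    n_input = length(gm$dp), n_retained = sum(keep), dp_ceiling = ceil,
    retained_interval = c(min_dp, ceil),
    dp_source = attr(gm, "dp_source") %||% "unknown"),
    class = "filter_report")
  list(gm = subset_variants(gm, keep), report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Depth filter: retained", x$n_retained, "of", x$n_input,
      sprintf("variants within [%g; %g]\n", x$retained_interval[1],
              x$retained_interval[2]))
  invisible(x)
}

#' Write a genotype matrix back out as VCF
#'
#' Used by the pipeline to persist the filtered variant set. Genotypes
#' are written unphased (`0/1` style); per-variant DP goes to INFO.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_gm_vcf <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  uc <- unique(gm$chrom)
  writeLines(c("##fileformat=VCFv4.2",
               "##source=woodpop depth filter",
               if (length(uc)) sprintf("##contig=<ID=%s>", uc),
               "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", gm$sample_ids), collapse = "\t"), con)
  gt_str <- c("0/0", "0/1", "1/1")
  nv <- ncol(gm$geno)
  if (nv > 0) {
    rows <- vapply(seq_len(nv), function(v) {
      g <- gm$geno[, v]
      gt <- ifelse(is.na(g), "./.", gt_str[g + 1L])
      info <- if (!is.null(gm$dp)) paste0("DP=", gm$dp[v]) else "."
      paste(c(gm$chrom[v], gm$pos[v], ".", "A", "G", ".", "PASS", info,
              "GT", gt), collapse = "\t")
    }, character(1))
    writeLines(rows, con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
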