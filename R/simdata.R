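#' Per-variant sequencing depth model
#'
#' Depths are drawn from a negative-binomial base distribution (mean
#' `mean_depth`, size `dispersion`) contaminated by a Pareto-tailed
#' outlier mixture: with probability `outlier_fraction` a variant's depth
#' is `mean_depth * outlier_scale * U^(-1/alpha)` (Pareto with shape
#' `alpha = 1.5`), giving the heavy right tail typical of collapsed
#' repeats — the regime in which a 90th-percentile depth ceiling is far
#' above the median.
#'
#' @param mean_depth mean fold-coverage of the negative-binomial base
#'   (> 0).
#' @param dispersion negative-binomial size parameter; smaller is more
#'   overdispersed.
#' @param outlier_fraction proportion of variants drawn from the outlier
#'   tail, in `[0, 1)`.
#' @param outlier_scale multiplier on `mean_depth` for the outlier tail.
#' @return an object of class `depth_model`.
#' @examples
#' set.seed(1)
#' summary(draw_depths(depth_model(), 1000))
#' @export
depth_model <- function(mean_depth = 22.7, dispersion = 5,
                        outlier_fraction = 0.02, outlier_scale = 5) {
  if (mean_depth <= 0) stop("`mean_depth` must be > 0", call. = FALSE)
  if (outlier_fraction < 0 || outlier_fraction >= 1)
    stop("`outlier_fraction` must be in [0, 1)", call. = FALSE)
  structure(list(mean_depth = mean_depth, dispersion = dispersion,
                 outlier_fraction = outlier_fraction,
                 outlier_scale = outlier_scale, pareto_shape = 1.5),
            class = "depth_model")
}

#' @rdname depth_model
#' @param model a `depth_model`.
#' @param n number of depths to draw.
#' @return `draw_depths()`: integer vector of `n` depths.
#' @export
draw_depths <- function(model, n) {
  stopifnot(inherits(model, "depth_model"))
  dp <- stats::rnbinom(n, size = model$dispersion, mu = model$mean_depth)
  if (model$outlier_fraction > 0) {
    out <- stats::runif(n) < model$outlier_fraction
    n_out <- sum(out)
    if (n_out > 0) {
      pareto <- stats::runif(n_out)^(-1 / model$pareto_shape)
      dp[out] <- round(model$mean_depth * model$outlier_scale * pareto)
    }
  }
  as.integer(dp)
}

#' Write simulated haplotypes as a VCF file
#'
#' Pairs consecutive haplotypes into phased diploid genotypes and writes a
#' VCF v4.2 file with GT and per-sample DP FORMAT fields plus a
#' per-variant INFO/DP. Contigs are declared in the header; positions are
#' strictly increasing within each chromosome. With zero segregating
#' sites a header-only VCF is written.
#'
#' @param haps either one haplotype matrix or a list of them (one per
#'   locus); every matrix must have the same even number of rows.
#' @param path output file path.
#' @param spec the [simulation_spec()] used (provides `locus_length` for
#'   position placement and contig declaration).
#' @param depth a [depth_model()] for per-variant DP.
#' @param chrom_labels optional chromosome name per locus (default as in
#'   [haplotypes_to_genotypes()]).
#' @param sample_ids optional sample names.
#' @return invisibly, the path. The genotype matrix actually written is
#'   attached as attribute `"gm"`.
#' @export
write_vcf <- function(haps, path, spec, depth = depth_model(),
                      chrom_labels = NULL, sample_ids = NULL) {
  if (is.matrix(haps)) haps <- list(haps)
  n_hap <- nrow(haps[[1]])
  if (n_hap %% 2 != 0) stop("odd number of haplotypes", call. = FALSE)
  gm <- haplotypes_to_genotypes(haps, spec, chrom_labels = chrom_labels,
                                depth = depth)
  if (!is.null(sample_ids)) gm$sample_ids <- sample_ids
  # re-derive phased alleles from the haplotypes, locus by locus
  al1 <- do.call(cbind, lapply(haps, function(h)
    h[seq(1, n_hap, by = 2), , drop = FALSE]))
  al2 <- do.call(cbind, lapply(haps, function(h)
    h[seq(2, n_hap, by = 2), , drop = FALSE]))

  con <- file(path, "w")
  on.exit(close(con))
  uc <- unique(gm$chrom)
  writeLines(c("##fileformat=VCFv4.2",
               "##source=woodpop coalescent simulator",
               sprintf("##contig=<ID=%s,length=%d>", uc, spec$locus_length),
               "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Sample depth\">"),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", gm$sample_ids), collapse = "\t"), con)
  nv <- ncol(gm$geno)
  if (nv > 0) {
    n_dip <- nrow(gm$geno)
    ref <- rep_len(c("A", "C", "G", "T"), nv)
    alt <- rep_len(c("G", "T", "A", "C"), nv)
    sample_dp <- matrix(pmax(0L, as.integer(round(
      gm$dp / n_dip + stats::rnorm(nv * n_dip, 0, 0.5)))), nrow = n_dip)
    rows <- vapply(seq_len(nv), function(v) {
      gt <- paste0(al1[, v], "|", al2[, v], ":", sample_dp[, v])
      paste(c(gm$chrom[v], gm$pos[v], ".", ref[v], alt[v], ".", "PASS",
              paste0("DP=", gm$dp[v]), "GT:DP", gt), collapse = "\t")
    }, character(1))
    writeLines(rows, con)
  }
  attr(path, "gm") <- gm
  invisible(path)
}

#' Ground-truth rearrangement map for the synteny fixture generator
#'
#' Describes, for each query chromosome, the ordered reference intervals
#' it derives from. Segments must not overlap on the query; each maps to
#' exactly one reference interval.
#'
#' @param segments data frame with columns `query_chrom`, `ref_chrom`,
#'   `ref_start`, `ref_end`, `orientation` (`"+"`/`"-"`).
#' @return an object of class `rearrangement_truth`.
#' @examples
#' rearrangement_truth(data.frame(
#'   query_chrom = c("q1", "q2"), ref_chrom = c("chr1", "chr2"),
#'   ref_start = c(1, 1), ref_end = c(5e6, 3e6), orientation = "+"))
#' @export
rearrangement_truth <- function(segments) {
  need <- c("query_chrom", "ref_chrom", "ref_start", "ref_end", "orientation")
  if (!all(need %in% names(segments)))
    stop("segments need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(segments$ref_start > segments$ref_end))
    stop("ref_start must be <= ref_end", call. = FALSE)
  # overlap check on the reference side within each (ref_chrom) is allowed;
  # the constraint is that the same reference interval is not reused for
  # one query chromosome (segments non-overlapping on the query by design:
  # each row is one contiguous query block laid end to end)
  for (q in unique(segments$query_chrom)) {
    s <- segments[segments$query_chrom == q, ]
    key <- paste(s$ref_chrom, s$ref_start, s$ref_end)
    if (anyDuplicated(key))
      stop("overlapping truth segments for query chromosome ", q,
           call. = FALSE)
  }
  structure(list(segments = segments), class = "rearrangement_truth")
}

#' Generate a whole-genome alignment coordinate table with known truth
#'
#' Tiles each truth segment into alignment blocks (lengths drawn around
#' `mean_block` bp, identities high) and adds spurious short, low-identity
#' blocks between random chromosome pairs at rate `spurious_rate`, so that
#' identity/length filters remove exactly the noise. Output follows the
#' MUMmer `show-coords -T` tab dialect used by [parse_coords()].
#'
#' @param truth a [rearrangement_truth()].
#' @param blocks_per_segment number of alignment blocks per truth segment.
#' @param identity_noise sd of the (Gaussian) identity jitter around 94%.
#' @param mean_block mean block length, bp.
#' @param spurious_rate spurious blocks as a proportion of true blocks.
#' @return data frame of alignment blocks (see [parse_coords()] for
#'   columns) with attribute `"truth"`.
#' @export
generate_coords <- function(truth, blocks_per_segment = 600,
                            identity_noise = 2, mean_block = 2000,
                            spurious_rate = 0.05) {
  stopifnot(inherits(truth, "rearrangement_truth"))
  segs <- truth$segments
  rows <- vector("list", nrow(segs))
  for (i in seq_len(nrow(segs))) {
    s <- segs[i, ]
    span <- s$ref_end - s$ref_start + 1
    n_b <- blocks_per_segment
    starts <- sort(sample.int(max(1, span - mean_block), n_b, replace = TRUE)) +
      s$ref_start - 1
    lens <- pmax(600L, as.integer(round(stats::rlnorm(n_b,
      log(mean_block), 0.4))))
    ends <- pmin(starts + lens - 1, s$ref_end)
    lens <- ends - starts + 1
    qlen <- pmax(1L, as.integer(round(lens * stats::runif(n_b, 0.95, 1.05))))
    qstart <- cumsum(c(1L, qlen[-n_b] + sample.int(200, n_b - 1, replace = TRUE)))
    ident <- pmin(99.9, pmax(75,
      stats::rnorm(n_b, 94, identity_noise)))
    rows[[i]] <- data.frame(
      ref_start = starts, ref_end = ends,
      query_start = qstart, query_end = qstart + qlen - 1,
      ref_alen = lens, query_alen = qlen,
      identity = round(ident, 2),
      ref_chrom = s$ref_chrom, query_chrom = s$query_chrom,
      stringsAsFactors = FALSE)
  }
  blocks <- do.call(rbind, rows)
  n_spur <- round(spurious_rate * nrow(blocks))
  if (n_spur > 0) {
    rc <- sample(unique(segs$ref_chrom), n_spur, replace = TRUE)
    qc <- sample(unique(segs$query_chrom), n_spur, replace = TRUE)
    len <- sample(50:450, n_spur, replace = TRUE)
    st <- sample.int(1e6, n_spur, replace = TRUE)
    qs <- sample.int(1e6, n_spur, replace = TRUE)
    spur <- data.frame(
      ref_start = st, ref_end = st + len - 1,
      query_start = qs, query_end = qs + len - 1,
      ref_alen = len, query_alen = len,
      identity = round(stats::runif(n_spur, 40, 69), 2),
      ref_chrom = rc, query_chrom = qc, stringsAsFactors = FALSE)
    blocks <- rbind(blocks, spur)
  }
  rownames(blocks) <- NULL
  attr(blocks, "truth") <- truth
  blocks
}

#' Write an alignment block table in show-coords tab dialect
#'
#' @param blocks data frame as produced by [generate_coords()].
#' @param path output TSV path.
#' @return invisibly, the path.
#' @export
write_coords <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("/ref.fa /query.fa", "NUCMER", "",
               paste(c("[S1]", "[E1]", "[S2]", "[E2]", "[LEN 1]", "[LEN 2]",
                       "[% IDY]", "[TAGS]"), collapse = "\t")), con)
  writeLines(paste(blocks$ref_start, blocks$ref_end, blocks$query_start,
                   blocks$query_end, blocks$ref_alen, blocks$query_alen,
                   sprintf("%.2f", blocks$identity), blocks$ref_chrom,
                   blocks$query_chrom, sep = "\t"), con)
  invisible(path)
}

#' Simulate a mitogenome multiple alignment
#'
#' Sequences evolve on a constant-size coalescent tree of `n_seqs`
#' haploid mitogenomes with infinite-sites mutation (`theta` in the ms
#' convention, so the expected number of segregating sites is
#' `theta * sum(1/(1:(n_seqs-1)))`). Each mutation picks a fresh column
#' and substitutes a different base in the carriers. `repeat_ranges`
#' optionally overwrites column ranges with a monomeric C homopolymer in
#' all sequences, emulating the repeat regions one would mask.
#'
#' @param n_seqs number of sequences (>= 2).
#' @param theta scaled mutation rate for the whole molecule.
#' @param length alignment length, bp.
#' @param repeat_ranges optional data frame `start`, `end` (1-based
#'   inclusive) of homopolymer regions to insert.
#' @return character matrix, `n_seqs` rows of single-character bases, with
#'   row names `ind1...`; class `c("mito_alignment", "matrix")`.
#' @examples
#' set.seed(1)
#' aln <- generate_mito_alignment(5, theta = 4, length = 1000)
#' dim(aln)
#' @export
generate_mito_alignment <- function(n_seqs, theta, length,
                                    repeat_ranges = NULL) {
  if (n_seqs < 2) stop("`n_seqs` must be >= 2", call. = FALSE)
  if (length < 1) stop("`length` must be >= 1", call. = FALSE)
  anc <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
  aln <- matrix(rep(anc, each = n_seqs), nrow = n_seqs)
  if (theta > 0) {
    g <- sim_genealogy(n_seqs, demography_constant())
    s <- stats::rpois(1, theta / 2 * sum(g$seg_len))
    s <- min(s, length)
    if (s > 0) {
      cols <- sample.int(length, s)
      hit <- sample.int(base::length(g$seg_len), s, replace = TRUE,
                        prob = g$seg_len)
      for (m in seq_len(s)) {
        col <- cols[m]
        derived <- sample(setdiff(c("A", "C", "G", "T"), anc[col]), 1)
        aln[g$seg_desc[[hit[m]]], col] <- derived
      }
    }
  }
  if (!is.null(repeat_ranges)) {
    for (i in seq_len(nrow(repeat_ranges))) {
      r <- repeat_ranges$start[i]:repeat_ranges$end[i]
      if (any(r < 1 | r > length))
        stop("repeat range outside alignment", call. = FALSE)
      aln[, r] <- "C"
    }
  }
  rownames(aln) <- paste0("ind", seq_len(n_seqs))
  class(aln) <- c("mito_alignment", class(aln))
  aln
}

#' Read / write aligned FASTA
#'
#' Thin wrappers over ape's FASTA I/O returning the character-matrix
#' alignment representation used by [apply_mask()] and friends.
#'
#' @param path FASTA file of equal-length aligned sequences.
#' @return `read_alignment()`: character matrix (sequences x columns,
#'   uppercase).
#' @export
read_alignment <- function(path) {
  d <- ape::read.dna(path, format = "fasta", as.character = TRUE,
                     as.matrix = TRUE)
  aln <- toupper(unclass(d))
  class(aln) <- c("mito_alignment", class(aln))
  aln
}

#' @rdname read_alignment
#' @param aln character matrix alignment.
#' @export
write_alignment <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(aln))) {
    writeLines(paste0(">", rownames(aln)[i]), con)
    writeLines(paste(aln[i, ], collapse = ""), con)
  }
  invisible(path)
}
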