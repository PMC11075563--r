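#' Synteny filter configuration
#'
#' Thresholds for whole-genome-alignment block filtering and link-based
#' chromosome-pair retention. Two presets mirror common practice:
#' `"distant"` (70% identity, 500 bp) for a diverged reference such as
#' chicken, and `"close"` (80% identity, 10 kb) for a close, repeat-rich
#' relative where short alignments are mostly noise.
#'
#' @param min_identity identity threshold, percent; blocks must exceed it
#'   strictly.
#' @param min_length length threshold, bp; blocks must exceed it strictly.
#' @param min_links minimum deduplicated link count for a chromosome pair
#'   to be retained (inclusive).
#' @param preset `"distant"`, `"close"`, or `NULL` to use the explicit
#'   thresholds.
#' @return an object of class `synteny_config`.
#' @examples
#' synteny_config(preset = "close")
#' @export
synteny_config <- function(min_identity = 70, min_length = 500,
                           min_links = 500, preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("distant", "close"))
    if (preset == "distant") { min_identity <- 70; min_length <- 500 }
    else { min_identity <- 80; min_length <- 10000 }
  }
  if (min_identity <= 0 || min_length <= 0 || min_links <= 0)
    stop("thresholds must be positive", call. = FALSE)
  structure(list(min_identity = min_identity, min_length = min_length,
                 min_links = min_links), class = "synteny_config")
}

#' Parse a show-coords tab-dialect alignment table
#'
#' Reads the tab-delimited output of `show-coords -T` (header lines
#' tolerated): columns S1, E1, S2, E2, LEN1, LEN2, %IDY, then the
#' reference and query sequence tags. Coordinates are 1-based inclusive.
#'
#' @param path coords TSV path.
#' @return data frame of alignment blocks with columns `ref_start`,
#'   `ref_end`, `query_start`, `query_end`, `ref_alen`, `query_alen`,
#'   `identity`, `ref_chrom`, `query_chrom`.
#' @export
parse_coords <- function(path) {
  lines <- readLines(path, warn = FALSE)
  is_data <- grepl("^-?[0-9]+\t", lines)
  data <- lines[is_data]
  if (length(data) == 0)
    return(data.frame(ref_start = integer(0), ref_end = integer(0),
                      query_start = integer(0), query_end = integer(0),
                      ref_alen = integer(0), query_alen = integer(0),
                      identity = numeric(0), ref_chrom = character(0),
                      query_chrom = character(0)))
  parts <- strsplit(data, "\t")
  nf <- lengths(parts)
  if (any(nf < 9))
    stop("malformed coords row(s) at line(s): ",
         paste(which(is_data)[nf < 9], collapse = ", "), call. = FALSE)
  m <- do.call(rbind, parts)
  num <- suppressWarnings(apply(m[, 1:7, drop = FALSE], 2, as.numeric))
  if (is.null(dim(num))) num <- matrix(num, nrow = 1)
  bad <- rowSums(is.na(num)) > 0
  if (any(bad))
    stop("unparseable numeric fields at line(s): ",
         paste(which(is_data)[bad], collapse = ", "), call. = FALSE)
  out <- data.frame(ref_start = as.integer(num[, 1]),
                    ref_end = as.integer(num[, 2]),
                    query_start = as.integer(num[, 3]),
                    query_end = as.integer(num[, 4]),
                    ref_alen = as.integer(num[, 5]),
                    query_alen = as.integer(num[, 6]),
                    identity = num[, 7],
                    ref_chrom = m[, 8], query_chrom = m[, 9],
                    stringsAsFactors = FALSE)
  if (any(out$identity < 0 | out$identity > 100))
    stop("identity outside [0, 100] at line(s): ",
         paste(which(is_data)[out$identity < 0 | out$identity > 100],
               collapse = ", "), call. = FALSE)
  if (any(out$ref_start > out$ref_end))
    stop("ref_start > ref_end in coords input", call. = FALSE)
  out
}

#' Filter alignment blocks on identity and length
#'
#' Keeps blocks whose identity is strictly greater than `min_identity`
#' and whose reference alignment length is strictly greater than
#' `min_length` ("more than" / "greater than" semantics).
#'
#' @param blocks data frame from [parse_coords()] or [generate_coords()].
#' @param cfg a [synteny_config()].
#' @return the retained subset of `blocks`.
#' @export
filter_blocks <- function(blocks, cfg = synteny_config()) {
  stopifnot(inherits(cfg, "synteny_config"))
  keep <- blocks$identity > cfg$min_identity &
    blocks$ref_alen > cfg$min_length
  out <- blocks[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign query chromosomes to reference chromosomes by greatest overlap
#'
#' For each query chromosome, the aligned reference bp (sum of reference
#' alignment lengths of filtered blocks) is accumulated per reference
#' chromosome; the query chromosome is assigned to the argmax and renamed
#' after it. Ties break towards the pair with more links, then the
#' lexicographically smaller reference label. When several query
#' chromosomes map to one reference chromosome (the norm for a
#' fragmented, microchromosome-rich genome) their new names carry
#' suffixes `a`, `b`, ... in order of decreasing overlap.
#'
#' @param blocks filtered blocks (see [filter_blocks()]).
#' @return data frame of class `assignment_table`, sorted by query
#'   chromosome: `query_chrom`, `ref_chrom`, `total_overlap_bp`,
#'   `n_links`, `new_name`.
#' @export
assign_chromosomes <- function(blocks) {
  if (nrow(blocks) == 0)
    return(structure(data.frame(query_chrom = character(0),
                                ref_chrom = character(0),
                                total_overlap_bp = numeric(0),
                                n_links = integer(0),
                                new_name = character(0)),
                     class = c("assignment_table", "data.frame")))
  agg <- stats::aggregate(ref_alen ~ query_chrom + ref_chrom, data = blocks,
                          FUN = sum)
  cnt <- stats::aggregate(ref_alen ~ query_chrom + ref_chrom, data = blocks,
                          FUN = length)
  names(agg)[3] <- "total_overlap_bp"
  agg$n_links <- cnt$ref_alen[match(paste(agg$query_chrom, agg$ref_chrom),
                                    paste(cnt$query_chrom, cnt$ref_chrom))]
  picked <- do.call(rbind, lapply(split(agg, agg$query_chrom), function(a) {
    a <- a[order(-a$total_overlap_bp, -a$n_links, a$ref_chrom), ]
    a[1, ]
  }))
  picked <- picked[order(picked$query_chrom), ]
  # suffix collisions by descending overlap within each reference chrom
  picked$new_name <- picked$ref_chrom
  for (rc in unique(picked$ref_chrom)) {
    idx <- which(picked$ref_chrom == rc)
    if (length(idx) > 1) {
      ord <- idx[order(-picked$total_overlap_bp[idx])]
      picked$new_name[ord] <- paste0(rc, letters[seq_along(ord)])
    }
  }
  rownames(picked) <- NULL
  structure(picked, class = c("assignment_table", "data.frame"))
}

#' Retain chromosome pairs by unique-link count
#'
#' A link is one filtered alignment block between a (query, reference)
#' chromosome pair; duplicated rows with identical reference and query
#' intervals count once. Pairs with at least `min_links` unique links are
#' retained (inclusive bound), as when drawing only the well-supported
#' ribbons of a circos figure.
#'
#' @param table an `assignment_table` from [assign_chromosomes()].
#' @param blocks the filtered blocks the table was computed from.
#' @param cfg a [synteny_config()] (uses `min_links`).
#' @return list with `pairs` (retained rows of `table` plus
#'   `n_unique_links`) and `links` (the deduplicated blocks of retained
#'   pairs, circos-ready columns ref_chrom, ref_start, ref_end,
#'   query_chrom, query_start, query_end).
#' @export
retain_by_links <- function(table, blocks, cfg = synteny_config()) {
  key <- paste(blocks$ref_chrom, blocks$ref_start, blocks$ref_end,
               blocks$query_chrom, blocks$query_start, blocks$query_end)
  uniq <- blocks[!duplicated(key), , drop = FALSE]
  pair_of <- paste(uniq$query_chrom, uniq$ref_chrom)
  cnt <- table(pair_of)
  tbl_pair <- paste(table$query_chrom, table$ref_chrom)
  table$n_unique_links <- as.integer(cnt[tbl_pair])
  table$n_unique_links[is.na(table$n_unique_links)] <- 0L
  keep <- table$n_unique_links >= cfg$min_links
  pairs <- table[keep, , drop = FALSE]
  rownames(pairs) <- NULL
  links <- uniq[pair_of %in% tbl_pair[keep],
                c("ref_chrom", "ref_start", "ref_end",
                  "query_chrom", "query_start", "query_end")]
  rownames(links) <- NULL
  list(pairs = pairs, links = links)
}

#' Order query chromosomes by median reference hit position
#'
#' Each query chromosome (segment) gets the median of the reference
#' midpoints of its filtered blocks on its assigned reference chromosome;
#' query chromosomes are then sorted by (assigned reference chromosome,
#' median position). This is the ordering used to lay rearranged
#' segments alongside the reference in a synteny figure.
#'
#' @param blocks filtered blocks.
#' @param table an `assignment_table`.
#' @return data frame `query_chrom`, `ref_chrom`, `median_ref_pos`,
#'   `order` (1-based rank), sorted into final order.
#' @export
order_segments <- function(blocks, table) {
  if (nrow(table) == 0)
    return(data.frame(query_chrom = character(0), ref_chrom = character(0),
                      median_ref_pos = numeric(0), order = integer(0)))
  med <- vapply(seq_len(nrow(table)), function(i) {
    b <- blocks[blocks$query_chrom == table$query_chrom[i] &
                  blocks$ref_chrom == table$ref_chrom[i], , drop = FALSE]
    stats::median((b$ref_start + b$ref_end) / 2)
  }, numeric(1))
  out <- data.frame(query_chrom = table$query_chrom,
                    ref_chrom = table$ref_chrom,
                    median_ref_pos = med, stringsAsFactors = FALSE)
  out <- out[order(out$ref_chrom, out$median_ref_pos, out$query_chrom), ]
  out$order <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
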