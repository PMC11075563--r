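# Small hand-built block table used across several cases.
toy_blocks <- function() {
  data.frame(
    ref_start   = c(100, 5000, 200, 900, 100),
    ref_end     = c(1099, 6999, 1199, 1899, 699),
    query_start = c(1, 1, 1, 1200, 1),
    query_end   = c(1000, 2000, 1000, 2199, 600),
    ref_alen    = c(1000, 2000, 1000, 1000, 600),
    query_alen  = c(1000, 2000, 1000, 1000, 600),
    identity    = c(95, 92, 88, 90, 60),
    ref_chrom   = c("chr1", "chr1", "chr2", "chr2", "chr3"),
    query_chrom = c("q1", "q1", "q2", "q2", "q3"),
    stringsAsFactors = FALSE)
}

test_that("coords tables round-trip through write and parse", {
  tr <- rearrangement_truth(data.frame(
    query_chrom = "q1", ref_chrom = "chr1", ref_start = 1, ref_end = 2e6,
    orientation = "+"))
  set.seed(7)
  co <- generate_coords(tr, blocks_per_segment = 50, spurious_rate = 0.1)
  path <- tempfile(fileext = ".coords")
  write_coords(co, path)
  back <- parse_coords(path)
  expect_equal(nrow(back), nrow(co))
  expect_equal(back$ref_start, co$ref_start)
  expect_equal(back$identity, co$identity)
  expect_equal(back$query_chrom, co$query_chrom)
})

test_that("parser rejects malformed numeric fields and bad identities", {
  p1 <- tempfile()
  writeLines(c("[S1]\t[E1]", "1\t100\t1\t100\t100\t100\tNOPE\tchr1\tq1"), p1)
  expect_error(parse_coords(p1), "unparseable")
  p2 <- tempfile()
  writeLines("1\t100\t1\t100\t100\t100\t101\tchr1\tq1", p2)
  expect_error(parse_coords(p2), "identity")
  p3 <- tempfile()
  writeLines(c("header only", "NUCMER"), p3)
  expect_equal(nrow(parse_coords(p3)), 0)
})

test_that("block filter is strict at both default thresholds", {
  b <- data.frame(ref_start = 1, ref_end = 600,
                  query_start = 1, query_end = 600,
                  ref_alen = c(600, 600, 500, 501, 600),
                  query_alen = 600,
                  identity = c(70.0, 70.1, 85, 85, 85),
                  ref_chrom = "chr1", query_chrom = "q1")
  kept <- filter_blocks(b, synteny_config(preset = "distant"))
  # identity must exceed 70 and length exceed 500, both strictly:
  # (70.0, 600) and (85, 500) sit on the boundaries and are dropped
  expect_equal(nrow(kept), 3)
  expect_true(all(kept$identity > 70 & kept$ref_alen > 500))
  expect_false(any(kept$identity == 70 | kept$ref_alen == 500))
})

test_that("close preset uses the 80% / 10 kb thresholds", {
  b <- data.frame(ref_start = 1, ref_end = 2e4,
                  query_start = 1, query_end = 2e4,
                  ref_alen = c(20000, 20000, 10000, 10001),
                  query_alen = 20000,
                  identity = c(80.0, 80.1, 90, 90),
                  ref_chrom = "chr1", query_chrom = "q1")
  kept <- filter_blocks(b, synteny_config(preset = "close"))
  expect_equal(nrow(kept), 2)
  expect_equal(kept$identity, c(80.1, 90))
  expect_equal(kept$ref_alen, c(20000, 10001))
})

test_that("filtering is monotone in both thresholds", {
  set.seed(9)
  tr <- rearrangement_truth(data.frame(
    query_chrom = "q1", ref_chrom = "chr1", ref_start = 1, ref_end = 2e6,
    orientation = "+"))
  co <- generate_coords(tr, blocks_per_segment = 200, spurious_rate = 0.3)
  n_base <- nrow(filter_blocks(co, synteny_config(70, 500)))
  expect_lte(nrow(filter_blocks(co, synteny_config(80, 500))), n_base)
  expect_lte(nrow(filter_blocks(co, synteny_config(70, 2000))), n_base)
})

test_that("assignment picks the greatest-overlap reference chromosome", {
  at <- assign_chromosomes(toy_blocks())
  expect_equal(at$ref_chrom[at$query_chrom == "q1"], "chr1")
  expect_equal(at$ref_chrom[at$query_chrom == "q2"], "chr2")
  expect_equal(at$total_overlap_bp[at$query_chrom == "q1"], 3000)
  expect_equal(at$n_links[at$query_chrom == "q1"], 2)
  expect_equal(nrow(assign_chromosomes(toy_blocks()[0, ])), 0)
})

test_that("overlap ties break by link count then reference label", {
  b <- data.frame(ref_start = 1, ref_end = 1000,
                  query_start = 1, query_end = 1000,
                  ref_alen = c(1000, 500, 500),
                  query_alen = 1000, identity = 90,
                  ref_chrom = c("chrB", "chrA", "chrA"),
                  query_chrom = "q1")
  at <- assign_chromosomes(b)  # equal 1000 bp overlap; chrA has 2 links
  expect_equal(at$ref_chrom, "chrA")
  b2 <- b[1:2, ]; b2$ref_alen <- c(1000, 1000)
  at2 <- assign_chromosomes(b2)  # equal overlap, equal links -> label order
  expect_equal(at2$ref_chrom, "chrA")
})

test_that("name collisions get overlap-ordered suffixes", {
  b <- data.frame(ref_start = 1, ref_end = 1000, query_start = 1,
                  query_end = 1000, ref_alen = c(2000, 800), query_alen = 1000,
                  identity = 90, ref_chrom = "chr1",
                  query_chrom = c("qBig", "qSmall"))
  at <- assign_chromosomes(b)
  expect_equal(at$new_name[at$query_chrom == "qBig"], "chr1a")
  expect_equal(at$new_name[at$query_chrom == "qSmall"], "chr1b")
})

test_that("link retention deduplicates and keeps >= min_links inclusively", {
  mk <- function(qc, n, dup = 0) {
    b <- data.frame(ref_start = seq_len(n) * 10, ref_end = seq_len(n) * 10 + 5,
                    query_start = seq_len(n), query_end = seq_len(n) + 5,
                    ref_alen = 600, query_alen = 600, identity = 90,
                    ref_chrom = "chr1", query_chrom = qc)
    if (dup > 0) b <- rbind(b, b[seq_len(dup), ])
    b
  }
  blocks <- rbind(mk("q500", 500, dup = 30), mk("q499", 499, dup = 100))
  at <- assign_chromosomes(blocks)
  res <- retain_by_links(at, blocks, synteny_config(min_links = 500))
  expect_equal(res$pairs$query_chrom, "q500")   # 499 unique links dropped
  expect_equal(res$pairs$n_unique_links, 500)
  expect_equal(nrow(res$links), 500)
  all_kept <- retain_by_links(at, blocks, synteny_config(min_links = 1))
  expect_setequal(all_kept$pairs$query_chrom, c("q500", "q499"))
})

test_that("segments order by median reference hit position", {
  b <- data.frame(
    ref_start = c(4.8e6, 5.2e6, 0.9e6, 1.1e6, 2e6),
    ref_end = c(4.9e6, 5.3e6, 1.0e6, 1.2e6, 2.1e6),
    query_start = 1, query_end = 1e5, ref_alen = 1e5, query_alen = 1e5,
    identity = 95, ref_chrom = "chr1",
    query_chrom = c("far", "far", "near", "near", "near"))
  at <- assign_chromosomes(b)
  ord <- order_segments(b, at)
  expect_equal(ord$query_chrom, c("near", "far"))
  expect_equal(ord$median_ref_pos[ord$query_chrom == "far"],
               stats::median(c(4.85e6, 5.25e6)))
  # single-block chromosome: median = that block midpoint
  one <- b[5, ]; one$query_chrom <- "solo"
  at2 <- assign_chromosomes(rbind(b, one))
  ord2 <- order_segments(rbind(b, one), at2)
  expect_equal(ord2$median_ref_pos[ord2$query_chrom == "solo"], 2.05e6)
})

test_that("assignment and ordering are invariant to row shuffling", {
  set.seed(21)
  tr <- rearrangement_truth(data.frame(
    query_chrom = c("q1", "q2", "q3"),
    ref_chrom = c("chr2", "chr1", "chr1"),
    ref_start = c(1, 1, 6e6), ref_end = c(4e6, 5e6, 1e7),
    orientation = "+"))
  co <- generate_coords(tr, blocks_per_segment = 120, spurious_rate = 0.2)
  fb <- filter_blocks(co)
  shuffled <- fb[sample(nrow(fb)), ]
  expect_equal(assign_chromosomes(fb), assign_chromosomes(shuffled))
  expect_equal(order_segments(fb, assign_chromosomes(fb)),
               order_segments(shuffled, assign_chromosomes(shuffled)))
})

test_that("overlap bookkeeping sums filtered block lengths per pair", {
  fb <- filter_blocks(toy_blocks())
  at <- assign_chromosomes(fb)
  by_pair <- tapply(fb$ref_alen, paste(fb$query_chrom, fb$ref_chrom), sum)
  expect_equal(sum(at$total_overlap_bp), sum(by_pair))
})
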