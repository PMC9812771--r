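# Hand-built alignment tables: one fragment = two rows sharing a qname.
mk_aln <- function(..., chrom_lengths = c(chr1 = 100000L), sample_id = "s1") {
  rows <- list(...)
  a <- do.call(rbind, lapply(rows, function(r)
    data.frame(qname = r[[1]], mate = as.integer(r[[2]]), chrom = r[[3]],
               pos = as.integer(r[[4]]), mapq = as.integer(r[[5]]),
               strand = "+", seq = r[[6]], secondary = FALSE,
               supplementary = FALSE, duplicate = FALSE,
               stringsAsFactors = FALSE)))
  a <- a[order(a$chrom, a$pos), , drop = FALSE]
  rownames(a) <- NULL
  attr(a, "chrom_lengths") <- chrom_lengths
  attr(a, "sample_id") <- sample_id
  a
}
IRR_SEQ <- strrep("AGC", 34)           # 102 bp pure CAG-family read
ANCH_SEQ <- paste0(strrep("ACGTT", 10), strrep("GATCC", 10))  # non-repeat

test_that("an anchored pair yields one event at the anchor position", {
  a <- mk_aln(list("f1", 1, "chr1", 5000, 60, ANCH_SEQ),
              list("f1", 2, "chr1", 5400, 0, IRR_SEQ))
  p <- scan_alignments(a)
  expect_equal(nrow(p$events), 1L)
  expect_equal(p$events$anchor_pos, 5000L)
  expect_equal(p$events$anchor_mapq, 60L)
  expect_equal(p$events$motif, "AGC")
})

test_that("anchor and in-repeat mapping-quality thresholds are enforced at their boundaries", {
  ev <- function(anchor_mapq, irr_mapq) {
    a <- mk_aln(list("f1", 1, "chr1", 5000, anchor_mapq, ANCH_SEQ),
                list("f1", 2, "chr1", 5400, irr_mapq, IRR_SEQ))
    nrow(scan_alignments(a)$events)
  }
  expect_equal(ev(50, 40), 1L)  # both at their inclusive boundaries
  expect_equal(ev(49, 40), 0L)  # anchor below minimum
  expect_equal(ev(50, 41), 0L)  # in-repeat mate above maximum
})

test_that("pairs whose two mates are both in-repeat reads contribute no event", {
  a <- mk_aln(list("f1", 1, "chr1", 5000, 0, IRR_SEQ),
              list("f1", 2, "chr1", 5400, 0, IRR_SEQ))
  expect_equal(nrow(scan_alignments(a)$events), 0L)
})

test_that("high-quality repeat-content reads do not become in-repeat mates", {
  # a read can tile a motif yet align uniquely; mapq > max_irr_mapq excludes it
  a <- mk_aln(list("f1", 1, "chr1", 5000, 60, ANCH_SEQ),
              list("f1", 2, "chr1", 5400, 60, IRR_SEQ))
  expect_equal(nrow(scan_alignments(a)$events), 0L)
})

test_that("duplicates are dropped as pairs and secondary records are ignored", {
  a <- mk_aln(list("f1", 1, "chr1", 5000, 60, ANCH_SEQ),
              list("f1", 2, "chr1", 5400, 0, IRR_SEQ),
              list("f2", 1, "chr1", 6000, 60, ANCH_SEQ),
              list("f2", 2, "chr1", 6400, 0, IRR_SEQ))
  a$duplicate[a$qname == "f2"][1] <- TRUE
  p <- scan_alignments(a)
  expect_equal(nrow(p$events), 1L)
  b <- mk_aln(list("f1", 1, "chr1", 5000, 60, ANCH_SEQ),
              list("f1", 2, "chr1", 5400, 0, IRR_SEQ),
              list("f1", 2, "chr1", 7000, 0, IRR_SEQ))
  b$secondary[3] <- TRUE
  expect_equal(nrow(scan_alignments(b)$events), 1L)
})

test_that("the scanner rejects malformed alignment streams", {
  a <- mk_aln(list("f1", 1, "chr1", 5000, 60, ANCH_SEQ),
              list("f1", 2, "chr1", 5400, 0, IRR_SEQ))
  attr(a, "chrom_lengths") <- NULL
  expect_error(scan_alignments(a), "chrom_lengths")
  b <- mk_aln(list("f1", 1, "chr1", 5000, 60, ANCH_SEQ),
              list("f1", 2, "chr1", 5400, 0, IRR_SEQ),
              list("f2", 1, "chr1", 6000, 60, ANCH_SEQ))
  expect_error(scan_alignments(b), "unpaired")
  d <- mk_aln(list("f1", 1, "chr1", 5400, 60, ANCH_SEQ),
              list("f1", 2, "chr1", 5000, 0, IRR_SEQ))
  d <- d[c(2, 1), ]  # break coordinate order
  attr(d, "chrom_lengths") <- c(chr1 = 100000L)
  expect_error(scan_alignments(d), "coordinate-sorted")
  expect_error(scan_alignments(a[0, ]), "empty")
})

test_that("global depth is mean autosomal coverage and excludes sex chromosomes", {
  a <- mk_aln(list("f1", 1, "chr1", 5000, 60, ANCH_SEQ),
              list("f1", 2, "chr1", 5400, 60, ANCH_SEQ),
              list("f2", 1, "chrX", 100, 60, ANCH_SEQ),
              list("f2", 2, "chrX", 500, 60, ANCH_SEQ),
              chrom_lengths = c(chr1 = 10000L, chrX = 10000L))
  p <- scan_alignments(a)
  expect_equal(p$global_depth, 200 / 10000)  # chrX bases and length excluded
})

test_that("events cluster by motif and distance into half-open loci", {
  prof <- function(positions, motifs, sample_id) {
    ev <- data.frame(sample_id = sample_id, chrom = "chr1",
                     anchor_pos = as.integer(positions), anchor_mapq = 60L,
                     motif = motifs, stringsAsFactors = FALSE)
    structure(list(sample_id = sample_id, role = "tumour", pair_id = "p1",
                   read_length = 100L, global_depth = 40, events = ev,
                   chrom_lengths = c(chr1 = 100000L)),
              class = "sample_profile")
  }
  p1 <- prof(c(1000, 1200, 1400), "AGC", "s1")
  cl <- cluster_events(list(p1))
  expect_equal(nrow(cl$loci), 1L)
  expect_equal(cl$loci$start, 1000L)
  expect_equal(cl$loci$end, 1500L)  # max anchor + read length, half-open
  # same positions, different motifs: two loci
  p2 <- prof(c(1000, 1200, 1400), c("AGC", "AAAG", "AGC"), "s1")
  expect_equal(nrow(cluster_events(list(p2))$loci), 2L)
  # gap above the merge distance: two loci
  p3 <- prof(c(1000, 1600), "AGC", "s1")
  expect_equal(nrow(cluster_events(list(p3), merge_distance = 500L)$loci), 2L)
  expect_equal(nrow(cluster_events(list(p3), merge_distance = 600L)$loci), 1L)
})

test_that("cluster counts are complete across samples with explicit zeros", {
  prof <- function(positions, sample_id) {
    ev <- data.frame(sample_id = rep(sample_id, length(positions)),
                     chrom = rep("chr1", length(positions)),
                     anchor_pos = as.integer(positions),
                     anchor_mapq = rep(60L, length(positions)),
                     motif = rep("AGC", length(positions)),
                     stringsAsFactors = FALSE)
    structure(list(sample_id = sample_id, role = "tumour", pair_id = "p1",
                   read_length = 100L, global_depth = 40, events = ev,
                   chrom_lengths = c(chr1 = 100000L)),
              class = "sample_profile")
  }
  cl <- cluster_events(list(prof(c(1000, 1100), "s1"), prof(integer(0), "s2")))
  counts <- cl$counts
  expect_equal(sort(unique(counts$sample_id)), c("s1", "s2"))
  expect_equal(counts$raw[counts$sample_id == "s1"], 2)
  expect_equal(counts$raw[counts$sample_id == "s2"], 0)
})

test_that("global normalization rescales counts by depth and is scale-exact", {
  expect_equal(global_normalize(10, 20, target_depth = 40), 20)
  expect_equal(global_normalize(c(3, 0), c(40, 40)), c(3, 0))
  expect_error(global_normalize(1, 0), "positive")
})

test_that("doubling every read pair doubles raw counts but not normalized values", {
  a <- mk_aln(list("f1", 1, "chr1", 5000, 60, ANCH_SEQ),
              list("f1", 2, "chr1", 5400, 0, IRR_SEQ),
              list("f2", 1, "chr1", 5100, 60, ANCH_SEQ),
              list("f2", 2, "chr1", 5500, 0, IRR_SEQ))
  b <- a
  b$qname <- paste0(b$qname, "x")
  ab <- rbind(a, b)
  ab <- ab[order(ab$chrom, ab$pos), ]
  attr(ab, "chrom_lengths") <- attr(a, "chrom_lengths")
  p1 <- scan_alignments(a, sample_id = "s", role = "tumour", pair_id = "p1")
  p2 <- scan_alignments(ab, sample_id = "s", role = "tumour", pair_id = "p1")
  expect_equal(nrow(p2$events), 2L * nrow(p1$events))
  expect_equal(p2$global_depth, 2 * p1$global_depth)
  expect_equal(global_normalize(nrow(p2$events), p2$global_depth),
               global_normalize(nrow(p1$events), p1$global_depth))
})

test_that("profile order does not change the cohort matrix", {
  prof <- function(positions, sample_id, role, pair_id) {
    ev <- data.frame(sample_id = rep(sample_id, length(positions)),
                     chrom = rep("chr1", length(positions)),
                     anchor_pos = as.integer(positions),
                     anchor_mapq = rep(60L, length(positions)),
                     motif = rep("AGC", length(positions)),
                     stringsAsFactors = FALSE)
    structure(list(sample_id = sample_id, role = role, pair_id = pair_id,
                   read_length = 100L, global_depth = 40, events = ev,
                   chrom_lengths = c(chr1 = 100000L)),
              class = "sample_profile")
  }
  ps <- list(prof(c(1000, 1100), "t1", "tumour", "p1"),
             prof(1050, "n1", "normal", "p1"),
             prof(integer(0), "t2", "tumour", "p2"),
             prof(1000, "n2", "normal", "p2"))
  m1 <- build_cohort_matrix(ps, cluster_events(ps))
  m2 <- build_cohort_matrix(rev(ps), cluster_events(rev(ps)))
  expect_equal(m1$raw[, colnames(m1$raw)], m2$raw[, colnames(m1$raw)])
  expect_equal(m1$loci, m2$loci)
})

test_that("cohort matrices require bijective tumour-normal pairing", {
  prof <- function(sample_id, role, pair_id) {
    structure(list(sample_id = sample_id, role = role, pair_id = pair_id,
                   read_length = 100L, global_depth = 40,
                   events = data.frame(sample_id = character(0),
                                       chrom = character(0),
                                       anchor_pos = integer(0),
                                       anchor_mapq = integer(0),
                                       motif = character(0)),
                   chrom_lengths = c(chr1 = 1000L)),
              class = "sample_profile")
  }
  ps <- list(prof("t1", "tumour", "p1"), prof("n1", "normal", "p2"))
  expect_error(build_cohort_matrix(ps, cluster_events(ps)), "pair")
})
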