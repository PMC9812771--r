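test_that("a generated genome embeds repeat tracts at the requested coordinates", {
  g <- make_repeat_genome(
    10000L, data.frame(start = c(2000L, 5000L), motif = c("CAG", "GAAA"),
                       copies = c(10L, 5L)), seed = 1)
  s <- g$sequences[["chr1"]]
  expect_equal(nchar(s), 10000L)
  expect_equal(substring(s, 2001, 2030), strrep("AGC", 10))  # canonical form
  expect_equal(substring(s, 5001, 5020), strrep("AAAG", 5))
  expect_equal(g$truth$ref_start, c(2000L, 5000L))
  expect_equal(g$truth$end - g$truth$start, c(30L, 20L))
})

test_that("genome construction rejects overlapping or out-of-bounds loci", {
  expect_error(make_repeat_genome(
    1000L, data.frame(start = c(100L, 110L), motif = "AG", copies = 10L),
    seed = 1), "overlapping")
  expect_error(make_repeat_genome(
    1000L, data.frame(start = 990L, motif = "AG", copies = 10L), seed = 1),
    "past chromosome end")
})

test_that("expanding a tract shifts downstream loci and preserves flanks", {
  g <- make_repeat_genome(
    10000L, data.frame(start = c(2000L, 5000L), motif = c("CAG", "GAAA"),
                       copies = c(10L, 5L)), seed = 2)
  ex <- expand_reference(g, data.frame(chrom = "chr1", ref_start = 2000L,
                                       target_copies = 50L))
  expect_equal(nchar(ex$sequences[["chr1"]]), 10000L + 120L)
  expect_equal(ex$truth$start, c(2000L, 5120L))
  expect_equal(ex$truth$ref_start, c(2000L, 5000L))  # reference key immutable
  s0 <- g$sequences[["chr1"]]; s1 <- ex$sequences[["chr1"]]
  expect_equal(substring(s1, 1, 2000), substring(s0, 1, 2000))
  expect_equal(substring(s1, 2001, 2150), strrep("AGC", 50))
  expect_equal(substring(s1, 2151, 10120), substring(s0, 2031, 10000))
  expect_error(
    expand_reference(g, data.frame(chrom = "chr1", ref_start = 1L,
                                   target_copies = 5L)),
    "not present")
})

test_that("haplotype and reference coordinates round-trip outside expanded tracts", {
  g <- make_repeat_genome(
    10000L, data.frame(start = c(2000L, 5000L), motif = c("CAG", "GAAA"),
                       copies = c(10L, 5L)), seed = 3)
  ex <- expand_reference(g, data.frame(chrom = "chr1", ref_start = 2000L,
                                       target_copies = 50L))
  ref <- c(0L, 1999L, 2030L, 4999L, 6000L)
  hap <- tropicr:::ref_to_hap(ex, "chr1", ref)
  expect_equal(hap, c(0L, 1999L, 2150L, 5119L, 6120L))
  expect_equal(tropicr:::hap_to_ref(ex, "chr1", hap), ref)
  # positions inside the inserted tract collapse onto the reference tract
  inside <- tropicr:::hap_to_ref(ex, "chr1", c(2000L, 2100L, 2149L))
  expect_true(all(inside >= 2000L & inside < 2030L))
})

test_that("simulated read pairs reproduce their origin sequence and coverage", {
  g <- make_repeat_genome(20000L,
                          data.frame(start = 9000L, motif = "CAG",
                                     copies = 10L), seed = 4)
  cfg <- sim_config(coverage = 20, error_rate = 0, seed = 5)
  r <- simulate_reads(g, cfg)
  expect_equal(nrow(r), 2 * round(20 * 20000 / (2 * 100)))
  expect_true(all(nchar(r$seq) == 100L))
  s <- g$sequences[["chr1"]]
  fwd <- r[r$mate == 1, ][1:50, ]
  expect_equal(fwd$seq, substring(s, fwd$start + 1, fwd$start + 100))
  rev <- r[r$mate == 2, ][1:50, ]
  expect_equal(rev$seq,
               revcomp(substring(s, rev$start + 1, rev$start + 100)))
  # realized base coverage close to nominal
  expect_equal(sum(nchar(r$seq)) / 20000, 20, tolerance = 0.01)
})

test_that("substitution errors occur at close to the configured rate", {
  g <- make_repeat_genome(50000L,
                          data.frame(start = 9000L, motif = "CAG",
                                     copies = 10L), seed = 6)
  cfg <- sim_config(coverage = 20, error_rate = 0.02, seed = 7)
  r <- simulate_reads(g, cfg)
  s <- g$sequences[["chr1"]]
  m1 <- r[r$mate == 1, ]
  truth <- substring(s, m1$start + 1, m1$start + 100)
  mism <- mapply(function(a, b)
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
    m1$seq[1:2000], truth[1:2000])
  rate <- sum(mism) / (2000 * 100)
  expect_gt(rate, 0.017)
  expect_lt(rate, 0.023)
})

test_that("the oracle aligner flags in-repeat reads and lifts positions to reference", {
  g <- make_repeat_genome(20000L,
                          data.frame(start = 9000L, motif = "CAG",
                                     copies = 20L), seed = 8)
  ex <- expand_reference(g, data.frame(chrom = "chr1", ref_start = 9000L,
                                       target_copies = 100L))  # 300 bp tract
  cfg <- sim_config(coverage = 30, error_rate = 0, seed = 9)
  r <- simulate_reads(ex, cfg)
  a <- oracle_align(r, ex, sample_id = "s1")
  expect_equal(attr(a, "chrom_lengths")[["chr1"]], 20000L)  # reference scale
  expect_equal(attr(a, "sample_id"), "s1")
  expect_false(is.unsorted(a$pos[a$chrom == "chr1"]))
  pure <- repeat_purity(a$seq, "CAG") >= 0.9
  expect_equal(a$mapq, ifelse(pure, 0L, 60L))
  expect_true(any(pure))
  expect_true(all(a$pos >= 0 & a$pos < 20000L))
  # reads fully inside the expanded tract land on the reference tract
  irr_pos <- a$pos[pure]
  expect_true(all(irr_pos >= 9000 - 100 & irr_pos < 9060))
})

test_that("amplification reads raise regional coverage in proportion to copy number", {
  g <- make_repeat_genome(100000L,
                          data.frame(start = 50000L, motif = "CAG",
                                     copies = 30L), seed = 10)
  cfg <- sim_config(coverage = 30, error_rate = 0, seed = 11)
  region <- data.frame(chrom = "chr1", start = 50000L, end = 50090L)
  expect_equal(nrow(simulate_amplification(g, region, 2L, cfg, seed = 1)), 0)
  r6 <- simulate_amplification(g, region, 6L, cfg, seed = 1)
  r4 <- simulate_amplification(g, region, 4L, cfg, seed = 1)
  expect_equal(nrow(r6) / nrow(r4), 2, tolerance = 0.01)  # (6/2-1)/(4/2-1)
  expect_true(all(r6$start >= 49000 - 500 & r6$start <= 51090 + 500))
  expect_error(simulate_amplification(g, region, 1L, cfg, seed = 1),
               ">= 2")
})

test_that("cohorts in fixed carrier mode place exactly the designed number of carriers", {
  g <- make_repeat_genome(30000L,
                          data.frame(start = 15000L, motif = "CAG",
                                     copies = 20L), seed = 12)
  cfg <- sim_config(coverage = 10, n_pairs = 10L, carrier_frequency = 0.3,
                    seed = 13)
  ex <- data.frame(chrom = "chr1", ref_start = 15000L, target_copies = 70L)
  coh <- simulate_cohort(g, ex, cfg)
  expect_equal(sum(coh$truth$carrier), 3L)
  expect_equal(nrow(coh$manifest), 20L)
  expect_setequal(unique(coh$manifest$role), c("tumour", "normal"))
  expect_length(coh$alignments, 20L)
  for (a in coh$alignments) {
    expect_false(is.unsorted(a$pos[a$chrom == "chr1"]))
    tab <- table(a$qname)
    expect_true(all(tab == 2L))
  }
})

test_that("downsampling keeps mates together and is seed-deterministic", {
  g <- make_repeat_genome(20000L,
                          data.frame(start = 9000L, motif = "CAG",
                                     copies = 10L), seed = 14)
  cfg <- sim_config(coverage = 20, seed = 15)
  r <- simulate_reads(g, cfg)
  a <- oracle_align(r, g, sample_id = "s")
  d1 <- downsample(a, 1 / 3, seed = 99)
  d2 <- downsample(a, 1 / 3, seed = 99)
  expect_identical(d1, d2)
  expect_true(all(table(d1$qname) == 2L))
  expect_equal(nrow(d1) / nrow(a), 1 / 3, tolerance = 0.1)
  expect_identical(downsample(a, 1, seed = 1), a)
  expect_error(downsample(a, 0, seed = 1), "fraction")
})

test_that("identical configuration and seed reproduce identical cohorts", {
  g <- make_repeat_genome(20000L,
                          data.frame(start = 9000L, motif = "CAG",
                                     copies = 20L), seed = 16)
  cfg <- sim_config(coverage = 10, n_pairs = 2L, seed = 17)
  ex <- data.frame(chrom = "chr1", ref_start = 9000L, target_copies = 70L)
  c1 <- simulate_cohort(g, ex, cfg)
  c2 <- simulate_cohort(g, ex, cfg)
  expect_identical(c1, c2)
  cfg2 <- sim_config(coverage = 10, n_pairs = 2L, seed = 18)
  c3 <- simulate_cohort(g, ex, cfg2)
  expect_false(identical(c1$alignments, c3$alignments))
})

test_that("simulation configuration validates its parameters", {
  expect_error(sim_config(coverage = 30), "seed")
  expect_error(sim_config(error_rate = 0.3, seed = 1), "error_rate")
  expect_error(sim_config(read_length = 10, seed = 1), "read_length")
  expect_error(sim_config(fragment_mean = 50, seed = 1), "fragment_mean")
})
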