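one_gene_targets <- function(len = 100L, gene = "BRCA1", chrom = "chr1",
                             start = 1000L) {
  data.frame(chrom = chrom, start = start, end = start + len, gene = gene)
}

flat_track <- function(depth, len = 100L, chrom = "chr1", start = 1000L) {
  depth_track(data.frame(chrom = chrom, start = start, end = start + len,
                         depth = depth))
}

test_that("gap fractions count sub-threshold and uncovered bases", {
  tg <- one_gene_targets()
  expect_equal(gap_fraction(flat_track(30), tg)$gap_fraction, 0)

  # depth 10 on the first 25 bases, 30 on the rest
  tr <- depth_track(data.frame(chrom = "chr1", start = c(1000L, 1025L),
                               end = c(1025L, 1100L), depth = c(10L, 30L)))
  gf <- gap_fraction(tr, tg)
  expect_equal(gf$gap_fraction, 0.25)
  expect_equal(gf$gap_bases, 25)

  # target bases with no depth interval count at depth 0
  tr2 <- flat_track(30, len = 60L)  # covers only 1000-1060
  expect_equal(gap_fraction(tr2, tg)$gap_fraction, 0.4)

  # gap definition is strict <: depth exactly at threshold is not a gap
  expect_equal(gap_fraction(flat_track(20), tg)$gap_fraction, 0)
  expect_equal(gap_fraction(flat_track(19), tg)$gap_fraction, 1)

  expect_error(gap_fraction(flat_track(30),
                            data.frame(chrom = "chr1", start = 10L, end = 10L,
                                       gene = "EMPTY")), "EMPTY")
})

test_that("band classification partitions bases and yields gene verdicts", {
  tg <- one_gene_targets()
  expect_equal(classify_bands(flat_track(17), tg)$verdict, "reviewable")
  expect_equal(classify_bands(flat_track(21), tg)$verdict, "pass")
  tr <- depth_track(data.frame(chrom = "chr1", start = c(1000L, 1001L),
                               end = c(1001L, 1100L), depth = c(3L, 40L)))
  cb <- classify_bands(tr, tg)
  expect_equal(cb$verdict, "fail")
  expect_equal(cb$fail_bases, 1)
  # band boundaries: 15 is reviewable (inclusive floor), 20 is pass
  expect_equal(classify_bands(flat_track(15), tg)$reviewable_bases, 100)
  expect_equal(classify_bands(flat_track(14), tg)$fail_bases, 100)
  expect_error(classify_bands(flat_track(30), tg, review_floor = 25), "strictly")
})

test_that("threshold coverage is inclusive and complements the gap fraction", {
  tg <- one_gene_targets()
  expect_equal(coverage_at(flat_track(30), tg)$frac_ge_t, 1.0)
  expect_equal(coverage_at(flat_track(29), tg)$frac_ge_t, 0.0)
  half <- depth_track(data.frame(chrom = "chr1", start = c(1000L, 1050L),
                                 end = c(1050L, 1100L), depth = c(10L, 50L)))
  expect_equal(coverage_at(half, tg)$frac_ge_t, 0.5)
})

test_that("coverage identities hold on random multi-exon tracks", {
  set.seed(21)
  genes <- c("BRCA1", "ATM", "CHEK2")
  tg <- simulate_targets(genes, n_exons = 4L, exon_len = 50L, intron_len = 30L)
  tr <- simulate_depth(tg, mean_depth = 25, overdispersion = 5, seed = 77)
  for (t in c(10, 20, 30)) {
    gf <- gap_fraction(tr, tg, gap_threshold = t)
    cv <- coverage_at(tr, tg, t = t)
    # complement identity, exactly
    expect_equal(gf$gap_fraction + cv$frac_ge_t, rep(1, length(genes)))
  }
  # monotone in the threshold
  g10 <- gap_fraction(tr, tg, 10)$gap_fraction
  g20 <- gap_fraction(tr, tg, 20)$gap_fraction
  g30 <- gap_fraction(tr, tg, 30)$gap_fraction
  expect_true(all(g10 <= g20 & g20 <= g30))
  # band counts partition the target
  cb <- classify_bands(tr, tg)
  expect_equal(cb$pass_bases + cb$reviewable_bases + cb$fail_bases,
               cb$target_bases)
  # against the brute per-base oracle for one gene
  pb <- per_base_depth(tr, tg, "ATM")
  expect_equal(gap_fraction(tr, tg, 20)$gap_bases[gap_fraction(tr, tg, 20)$gene == "ATM"],
               sum(pb < 20))
})

test_that("splitting a target and recombining base counts is lossless", {
  tr <- simulate_depth(one_gene_targets(len = 200L), mean_depth = 22,
                       overdispersion = 4, seed = 5)
  whole <- gap_fraction(tr, one_gene_targets(len = 200L))
  halves <- rbind(
    data.frame(chrom = "chr1", start = 1000L, end = 1080L, gene = "left"),
    data.frame(chrom = "chr1", start = 1080L, end = 1200L, gene = "right"))
  parts <- gap_fraction(tr, halves)
  expect_equal(sum(parts$gap_bases), whole$gap_bases)
  expect_equal(sum(parts$target_bases), whole$target_bases)
})

test_that("overlapping target intervals are merged before counting", {
  tr <- flat_track(10, len = 100L)
  tg <- rbind(one_gene_targets(len = 60L), one_gene_targets(len = 100L))
  gf <- gap_fraction(tr, tg)
  expect_equal(gf$target_bases, 100)  # union, not 160
  expect_equal(gf$gap_bases, 100)
})

test_that("depth tracks reject overlaps and round-trip through bedGraph", {
  expect_error(depth_track(data.frame(chrom = "chr1", start = c(0L, 5L),
                                      end = c(10L, 15L), depth = c(1L, 2L))),
               "overlap")
  expect_error(depth_track(data.frame(chrom = "chr1", start = 5L, end = 5L,
                                      depth = 1L)), "end > start")
  tr <- simulate_depth(one_gene_targets(), mean_depth = 30,
                       overdispersion = 10, seed = 9)
  p <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph(tr, p)
  expect_equal(as.data.frame(read_bedgraph(p)), as.data.frame(tr))
  # targets BED round trip
  tg <- simulate_targets(c("BRCA1", "ATM"), n_exons = 3L)
  pb <- withr::local_tempfile(fileext = ".bed")
  write_targets_bed(tg, pb)
  expect_equal(read_targets_bed(pb), tg)
})

test_that("cohort gap comparison matches rank oracles and handles degeneracy", {
  tg <- one_gene_targets()
  mk_reports <- function(fracs, cohort) {
    do.call(rbind, lapply(seq_along(fracs), function(i) {
      data.frame(sample = paste0(cohort, i), gene = "BRCA1",
                 target_bases = 100, gap_bases = round(100 * fracs[i]),
                 gap_fraction = fracs[i])
    }))
  }
  # identical constant cohorts: degenerate, p = 1
  a <- mk_reports(rep(0, 5), "a"); b <- mk_reports(rep(0, 5), "b")
  cmp <- compare_gap_cohorts(a, b)
  expect_equal(cmp$p_value, 1)
  expect_equal(cmp$test_used, "degenerate")

  # all-zero vs all-0.5 with n=10: decisive rank separation
  a2 <- mk_reports(rep(0, 10), "a")
  b2 <- mk_reports(seq(0.45, 0.55, length.out = 10), "b")
  cmp2 <- compare_gap_cohorts(a2, b2)
  expect_lt(cmp2$p_value, 0.001)
  expect_equal(cmp2$gap_pct_b, 50, tolerance = 1e-6)

  # 3 vs 3: p agrees with the exact permutation oracle within the
  # documented normal-approximation tolerance
  set.seed(31)
  fa <- runif(3, 0, 0.1); fb <- runif(3, 0.2, 0.4)
  cmp3 <- compare_gap_cohorts(mk_reports(fa, "a"), mk_reports(fb, "b"))
  if (cmp3$test_used == "mann_whitney")
    expect_lt(abs(cmp3$p_value - exact_mwu_p(fa, fb)), 0.19)

  # pooled mode uses base totals
  cmpp <- compare_gap_cohorts(a2, b2, pooled = TRUE)
  expect_equal(cmpp$gap_pct_b, sum(b2$gap_bases) / sum(b2$target_bases) * 100)

  # mismatched gene sets are an error
  b3 <- b2; b3$gene <- "ATM"
  expect_error(compare_gap_cohorts(a2, b3), "one cohort only")
  expect_error(compare_gap_cohorts(mk_reports(c(0, 0.1), "a"), b2), ">= 3")
})
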