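test_that("scoring files round-trip bit-exactly and single-row files parse", {
  m <- tiny_model()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_score_file(m, path)
  m2 <- read_score_file(path)
  expect_identical(as.data.frame(m), as.data.frame(m2))
  expect_identical(attr(m2, "build"), "GRCh38")
  expect_identical(attr(m2, "name"), "tiny")

  # single-variant file at a known breast-cancer PRS locus
  p1 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#genome_build=GRCh38",
               paste("chr_name", "chr_position", "effect_allele", "other_allele",
                     "effect_weight", "effect_allele_frequency", sep = "\t"),
               paste("chr1", "117598870", "A", "C", "0.05", "0.2", sep = "\t")), p1)
  m1 <- read_score_file(p1)
  expect_equal(nrow(m1), 1)
  expect_equal(m1$pos, 117598870L)
  expect_equal(m1$weight, 0.05)

  # round-trip of a large simulated model, including NA frequencies
  big <- simulate_score_model(sim_config(seed = 7, m_variants = 120))
  big$eaf[5] <- NA
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_score_file(big, p2)
  expect_identical(as.data.frame(read_score_file(p2)), as.data.frame(big))
})

test_that("header-only scoring files give an empty, valid model", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#genome_build=GRCh38",
               paste(c("chr_name", "chr_position", "effect_allele",
                       "other_allele", "effect_weight"), collapse = "\t")), p)
  m <- read_score_file(p)
  expect_s3_class(m, "score_model")
  expect_equal(nrow(m), 0)
})

test_that("malformed scoring files fail with informative errors", {
  mk <- function(rows) {
    p <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame(2))
    writeLines(c("#genome_build=GRCh38",
                 paste(c("chr_name", "chr_position", "effect_allele",
                         "other_allele", "effect_weight",
                         "effect_allele_frequency"), collapse = "\t"), rows), p)
    p
  }
  row <- function(pos, w = "0.1", eaf = "0.3")
    paste("chr1", pos, "A", "C", w, eaf, sep = "\t")

  # NA weight on row 3
  expect_error(read_score_file(mk(c(row(1), row(2), row(3, w = "NA")))),
               "row 3")
  # eaf outside [0,1] with row number
  expect_error(read_score_file(mk(c(row(1), row(2, eaf = "1.5")))), "row 2")
  # duplicate full variant key
  expect_error(read_score_file(mk(c(row(5), row(5)))), "duplicate")

  # missing required column is named
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste(c("chr_name", "chr_position", "effect_allele",
                       "effect_weight"), collapse = "\t"),
               paste("chr1", "10", "A", "0.1", sep = "\t")), p)
  expect_error(read_score_file(p), "other_allele")

  # non-GRCh38 builds are rejected with a liftover hint
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#genome_build=GRCh37",
               paste(c("chr_name", "chr_position", "effect_allele",
                       "other_allele", "effect_weight"), collapse = "\t"),
               paste("chr1", "10", "A", "C", "0.1", sep = "\t")), p2)
  expect_error(read_score_file(p2), "lift")
})

test_that("score_model invariants are enforced", {
  base <- data.frame(chrom = "chr1", pos = 10L, effect_allele = "A",
                     other_allele = "C", weight = 0.1, eaf = 0.5)
  expect_s3_class(score_model(base), "score_model")
  expect_error(score_model(transform(base, other_allele = "A")), "identical")
  expect_error(score_model(transform(base, effect_allele = "N")), "allele")
  expect_error(score_model(transform(base, weight = Inf)), "finite")
  expect_error(score_model(transform(base, eaf = -0.1)), "\\[0,1\\]")
  expect_error(score_model(rbind(base, base)), "duplicate")
  # same position with distinct allele pair is allowed (4-tuple key)
  expect_silent(score_model(rbind(base, transform(base, effect_allele = "G"))))
})

test_that("match_variant resolves orientation, strand flips and indels", {
  sv <- function(eff, oth, eaf = NA)
    list(chrom = "chr1", pos = 100L, effect_allele = eff, other_allele = oth,
         eaf = eaf)
  ob <- function(ref, alt, af = NULL)
    list(chrom = "chr1", pos = 100L, ref = ref, alt = alt, af = af)

  expect_equal(match_variant(sv("A", "C"), ob("C", "A"))$status, "exact")
  expect_equal(match_variant(sv("A", "C"), ob("C", "A"))$transform, "identity")
  m <- match_variant(sv("C", "A"), ob("C", "A"))
  expect_equal(m$status, "swap")
  expect_equal(m$transform, "complement")
  # reverse-complement matches: A/C on the other strand reads T/G
  expect_equal(match_variant(sv("A", "C"), ob("G", "T"))$status, "flip")
  expect_equal(match_variant(sv("A", "C"), ob("T", "G"))$status, "flip_swap")
  expect_equal(match_variant(sv("A", "C"), ob("A", "G"))$status, "mismatch")
  expect_error(match_variant(sv("A", "C"),
                             list(chrom = "chr1", pos = 101L, ref = "C", alt = "A")),
               "positions differ")

  # indels: exact string equality only, flips are ill-defined
  expect_equal(match_variant(sv("TA", "T"), ob("T", "TA"))$status, "exact")
  expect_equal(match_variant(sv("TA", "T"), ob("TA", "T"))$status, "swap")
  expect_equal(match_variant(sv("TA", "T"), ob("A", "AT"))$status, "mismatch")
})

test_that("palindromic variants obey the frequency-concordance rule", {
  sv <- function(eaf) list(chrom = "chr1", pos = 1L, effect_allele = "A",
                           other_allele = "T", eaf = eaf)
  ob <- function(af = NULL) list(chrom = "chr1", pos = 1L, ref = "A",
                                 alt = "T", af = af)
  # near-0.5 frequency: always ambiguous
  expect_equal(match_variant(sv(0.49), ob(0.49))$status, "ambiguous")
  expect_equal(match_variant(sv(0.58), ob(0.6))$status, "ambiguous")  # |eaf-.5|=.08 inside margin
  # no observed frequency: ambiguous
  expect_equal(match_variant(sv(0.9), ob())$status, "ambiguous")
  # concordant: effect allele (A) is textual REF, so observed ALT freq should
  # be ~1-eaf on the same strand
  m <- match_variant(sv(0.9), ob(0.12))
  expect_equal(m$status, "swap")
  expect_equal(m$transform, "complement")
  # discordant: observed ALT freq matches eaf, i.e. the file is on the
  # opposite strand and the effect allele aligns with ALT
  m2 <- match_variant(sv(0.9), ob(0.88))
  expect_equal(m2$status, "exact")
  expect_equal(m2$transform, "identity")
  # C/G pair behaves the same
  svc <- list(chrom = "chr1", pos = 1L, effect_allele = "C",
              other_allele = "G", eaf = 0.8)
  expect_equal(match_variant(svc, list(chrom = "chr1", pos = 1L, ref = "G",
                                       alt = "C", af = 0.79))$status, "exact")
})

test_that("implied effect dosage is invariant under REF/ALT record exchange", {
  set.seed(11)
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (i in 1:200) {
    eff <- sample(bases, 1)
    oth <- sample(setdiff(bases, c(eff, comp[[eff]])), 1)
    sv <- list(chrom = "chr1", pos = 1L, effect_allele = eff,
               other_allele = oth, eaf = runif(1))
    # as-written and REF/ALT-exchanged encodings of the same site
    orient <- sample(list(c(oth, eff), c(eff, oth),
                          unname(c(comp[oth], comp[eff]))), 1)[[1]]
    ob1 <- list(chrom = "chr1", pos = 1L, ref = orient[1], alt = orient[2])
    ob2 <- list(chrom = "chr1", pos = 1L, ref = orient[2], alt = orient[1])
    m1 <- match_variant(sv, ob1); m2 <- match_variant(sv, ob2)
    d_alt <- sample(0:2, 1)
    eff_d1 <- if (m1$transform == "complement") 2 - d_alt else d_alt
    # record 2 encodes the complementary ALT dosage
    eff_d2 <- if (m2$transform == "complement") 2 - (2 - d_alt) else 2 - d_alt
    expect_equal(eff_d1, eff_d2)
  }
})

test_that("overlap_models counts shared variants symmetrically", {
  m <- simulate_score_model(sim_config(seed = 3, m_variants = 40))
  self <- overlap_models(m, m)
  expect_equal(self$n_shared, 40)

  a <- score_model(data.frame(chrom = "chr1", pos = 1:3 * 10L,
                              effect_allele = "A", other_allele = "C",
                              weight = 0.1, eaf = 0.3))
  b <- score_model(data.frame(chrom = "chr2", pos = 1:3 * 10L,
                              effect_allele = "A", other_allele = "C",
                              weight = 0.1, eaf = 0.3))
  expect_equal(overlap_models(a, b)$n_shared, 0)

  # different builds without rsids cannot be compared
  b37 <- score_model(as.data.frame(b)[, 1:6], build = "GRCh37")
  a_norsid <- score_model(as.data.frame(a)[, 1:6])
  expect_error(overlap_models(a_norsid, b37), "build")
})

test_that("a synthetic 306/313 model pair shares exactly its constructed 295", {
  # synthetic stand-ins for a sequencing-optimized 306-variant score and its
  # 313-variant array-based parent sharing 295 variants by construction
  parent <- simulate_score_model(sim_config(seed = 21, m_variants = 313))
  pv <- as.data.frame(parent)
  keep <- pv[1:295, ]
  extra <- simulate_score_model(sim_config(seed = 22, m_variants = 11))
  ev <- as.data.frame(extra)
  ev$rsid <- sprintf("rs8%06d", 1:11)  # distinct from the parent's ids
  child <- score_model(rbind(keep, ev), name = "synthetic_bridges_like")
  ov <- overlap_models(child, parent)
  expect_equal(ov$n_shared, 295)
  expect_equal(overlap_models(parent, child)$n_shared, 295)
  # swapped/flipped re-encodings still count as the same variant
  flipped <- keep
  flipped$effect_allele <- keep$other_allele
  flipped$other_allele <- keep$effect_allele
  flipped$rsid <- NA_character_
  child2 <- score_model(rbind(flipped, ev))
  expect_equal(overlap_models(child2, parent)$n_shared, 295)
})
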