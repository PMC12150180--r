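# Shared fixtures and independent oracles for the test suite.
# Everything is generated in code; no binary fixtures.

# a small fully-specified score model for I/O and matching tests
tiny_model <- function() {
  score_model(data.frame(
    chrom = c("chr1", "chr2", "chr5"),
    pos = c(117598870L, 69945455L, 82217128L),
    effect_allele = c("A", "G", "TA"),
    other_allele = c("C", "A", "T"),
    weight = c(0.05, -0.12, 0.3),
    eaf = c(0.2, 0.35, 0.1),
    rsid = c("rs12406858", "rs6756513", "rs146817970"),
    stringsAsFactors = FALSE), name = "tiny", build = "GRCh38")
}

# write a VCF from explicit records; gt is a matrix of GT strings
# (variants x samples)
write_test_vcf <- function(path, chrom, pos, ref, alt, gt, samples,
                           id = NULL) {
  id <- id %||% rep(".", length(pos))
  lines <- c("##fileformat=VCFv4.2",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"))
  for (i in seq_along(pos))
    lines <- c(lines, paste(c(chrom[i], pos[i], id[i], ref[i], alt[i], ".",
                              "PASS", ".", "GT", gt[i, ]), collapse = "\t"))
  writeLines(lines, path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent naive two-loop PRS reference: plain double accumulation in
# model order, no matrix algebra
naive_prs <- function(dosages, weights) {
  vapply(seq_len(nrow(dosages)), function(i) {
    s <- 0
    for (j in seq_along(weights)) s <- s + weights[j] * dosages[i, j]
    s
  }, double(1))
}

# exact two-sided Mann-Whitney permutation p-value by complete enumeration
# of all C(n1+n2, n1) group labelings; statistic U of the first group
exact_mwu_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  pooled <- c(x, y)
  u_stat <- function(idx) {
    rk <- rank(pooled)
    sum(rk[idx]) - n1 * (n1 + 1) / 2
  }
  mu <- n1 * (n - n1) / 2
  obs_dev <- abs(u_stat(seq_len(n1)) - mu)
  combs <- utils::combn(n, n1)
  devs <- apply(combs, 2, function(idx) abs(u_stat(idx) - mu))
  mean(devs >= obs_dev - 1e-12)
}

# brute-force Poisson-binomial pmf by 2^n enumeration
brute_pb_pmf <- function(p) {
  n <- length(p)
  pmf <- numeric(n + 1)
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[seq_len(n)]
    pr <- prod(ifelse(bits == 1, p, 1 - p))
    k <- sum(bits)
    pmf[k + 1] <- pmf[k + 1] + pr
  }
  pmf
}

# per-base depth expansion oracle for coverage tests (small regions only)
per_base_depth <- function(track, targets, gene) {
  tg <- targets[targets$gene == gene, , drop = FALSE]
  out <- integer()
  for (i in seq_len(nrow(tg))) {
    for (b in (tg$start[i]):(tg$end[i] - 1L)) {
      hit <- track$chrom == tg$chrom[i] & track$start <= b & track$end > b
      out <- c(out, if (any(hit)) track$depth[which(hit)[1]] else 0L)
    }
  }
  out
}
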