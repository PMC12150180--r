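#' Configuration for the synthetic study generator
#'
#' Bundles and validates the parameters of the liability-threshold cohort
#' simulation. Defaults emulate the cohort shape this pipeline is built for:
#' a ~306-variant breast-cancer score, 661 cases vs 1000 non-cancer controls,
#' and a PRS explaining 5% of liability variance at a background prevalence
#' of 12%, which places the case/control separation at Cohen's D around 0.4.
#'
#' @param seed integer seed; mandatory (no implicit entropy).
#' @param m_variants number of score variants.
#' @param n_cases,n_controls cohort sizes.
#' @param h2_prs liability variance fraction attributable to the PRS, in (0,1).
#' @param prevalence disease prevalence K in (0,1).
#' @param eaf_range effect-allele frequency range, within (0,1).
#' @param weight_sd standard deviation of the simulated per-allele weights.
#' @return An object of class `sim_config` (named list).
#' @export
sim_config <- function(seed, m_variants = 306L, n_cases = 661L,
                       n_controls = 1000L, h2_prs = 0.05, prevalence = 0.12,
                       eaf_range = c(0.05, 0.95), weight_sd = 0.1) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop2("sim_config requires an explicit seed")
  assert_that(m_variants >= 1, "m_variants must be >= 1")
  assert_that(n_cases >= 1 && n_controls >= 1, "cohort sizes must be >= 1")
  assert_that(h2_prs > 0 && h2_prs < 1, "h2_prs must lie in (0,1)")
  assert_that(prevalence > 0 && prevalence < 1, "prevalence must lie in (0,1)")
  assert_that(length(eaf_range) == 2 && all(eaf_range > 0 & eaf_range < 1) &&
                eaf_range[1] <= eaf_range[2], "eaf_range must lie within (0,1)")
  assert_that(weight_sd > 0, "weight_sd must be positive")
  structure(list(seed = as.integer(seed), m_variants = as.integer(m_variants),
                 n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
                 h2_prs = h2_prs, prevalence = prevalence,
                 eaf_range = eaf_range, weight_sd = weight_sd),
            class = "sim_config")
}

#' Simulate a score model
#'
#' Draws `m_variants` autosomal variants with unique positions, effect-allele
#' frequencies uniform over `eaf_range` and weights N(0, weight_sd^2).
#' Alleles are non-palindromic single nucleotides by default; a fraction of
#' palindromic (A/T, C/G) variants can be injected to exercise strand
#' harmonization.
#'
#' @param cfg a [sim_config()].
#' @param palindromic_fraction fraction of variants given palindromic allele
#'   pairs (default 0).
#' @return a [score_model()], sorted by position.
#' @export
simulate_score_model <- function(cfg, palindromic_fraction = 0) {
  stopifnot(inherits(cfg, "sim_config"))
  m <- cfg$m_variants
  pool <- 2.4e8
  if (m > 22 * pool) stop2("m_variants exceeds the position pool")
  withr::with_seed(cfg$seed, {
    chrom_i <- sample(1:22, m, replace = TRUE)
    pos <- integer(m)
    repeat {
      pos <- sample.int(pool, m, replace = TRUE)
      if (!anyDuplicated(paste(chrom_i, pos))) break
    }
    bases <- c("A", "C", "G", "T")
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    eff <- sample(bases, m, replace = TRUE)
    oth <- vapply(eff, function(e)
      sample(setdiff(bases, c(e, comp[[e]])), 1), character(1))
    n_pal <- round(palindromic_fraction * m)
    if (n_pal > 0) {
      ip <- sample.int(m, n_pal)
      oth[ip] <- comp[eff[ip]]
    }
    eaf <- stats::runif(m, cfg$eaf_range[1], cfg$eaf_range[2])
    wt <- stats::rnorm(m, 0, cfg$weight_sd)
    ord <- order(chrom_i, pos)
    score_model(data.frame(chrom = paste0("chr", chrom_i)[ord], pos = pos[ord],
                           effect_allele = unname(eff)[ord],
                           other_allele = unname(oth)[ord],
                           weight = wt[ord], eaf = eaf[ord],
                           rsid = sprintf("rs9%06d", seq_len(m)),
                           stringsAsFactors = FALSE),
                name = sprintf("synthetic_prs_m%d_seed%d", m, cfg$seed),
                build = "GRCh38")
  })
}

#' Expected case-minus-noncase mean of the standardized PRS
#'
#' Closed-form oracle for the liability-threshold simulation with controls
#' drawn from the non-cases: with threshold `t = qnorm(1 - K)`, the expected
#' standardized-PRS means are `sqrt(h2) * dnorm(t)/K` among cases and
#' `-sqrt(h2) * dnorm(t)/(1-K)` among non-cases, so the difference is
#' `sqrt(h2) * dnorm(t) * (1/K + 1/(1-K))`.
#'
#' @param h2_prs liability variance fraction of the PRS, in (0,1) (0 allowed
#'   as the degenerate limit).
#' @param prevalence disease prevalence K in (0,1).
#' @return expected difference of standardized-PRS means.
#' @export
closed_form_shift <- function(h2_prs, prevalence) {
  assert_that(h2_prs >= 0 && h2_prs <= 1, "h2_prs must lie in [0,1]")
  assert_that(prevalence > 0 && prevalence < 1, "prevalence must lie in (0,1)")
  t <- stats::qnorm(1 - prevalence)
  sqrt(h2_prs) * stats::dnorm(t) * (1 / prevalence + 1 / (1 - prevalence))
}

# genotype count -> unphased GT string
.gt_string <- c("0/0", "0/1", "1/1")

# write a minimal multi-sample VCF 4.2 (GT only)
write_vcf <- function(model, genotypes, samples, path, swap = NULL) {
  v <- as.data.frame(model)
  m <- nrow(v)
  if (is.null(swap)) swap <- rep(FALSE, m)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=prspipe_synthetic_cohort",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t")), con)
  for (j in seq_len(m)) {
    g <- genotypes[, j]
    if (swap[j]) { ref <- v$effect_allele[j]; alt <- v$other_allele[j]; g <- 2L - g }
    else { ref <- v$other_allele[j]; alt <- v$effect_allele[j] }
    writeLines(paste(c(v$chrom[j], v$pos[j],
                       if (is.na(v$rsid[j])) "." else v$rsid[j],
                       ref, alt, ".", "PASS", ".", "GT",
                       .gt_string[g + 1L]), collapse = "\t"), con)
  }
  invisible(path)
}

#' Simulate a case/control cohort under a liability-threshold model
#'
#' Genotypes are drawn per variant as Binomial(2, eaf) (Hardy-Weinberg,
#' linkage equilibrium). The standardized PRS `P_i` enters a latent liability
#' `L_i = sqrt(h2) P_i + sqrt(1-h2) e_i`, `e_i ~ N(0,1)`; an individual is a
#' case when `L_i > qnorm(1 - K)`. Individuals are rejection-sampled until
#' the case and control quotas are filled; controls are non-cases (mirroring
#' a non-cancer control cohort), not population samples.
#'
#' The VCF is written with deterministically alternating REF/ALT orientation
#' (every second variant stores the effect allele as REF), so downstream
#' harmonization is exercised on every run.
#'
#' @param model a [score_model()] with complete effect-allele frequencies.
#' @param cfg a [sim_config()].
#' @param dir output directory for `cohort.vcf` and `samples.tsv`.
#' @param max_chunks rejection-sampling budget (chunks of 2000 draws).
#' @return list with `vcf`, `sample_sheet` (paths) and `truth`, a data.frame
#'   per individual: `sample`, `group`, `liability`, `raw_prs` (effect-allele
#'   scale), `std_prs`, `case`.
#' @export
simulate_cohort <- function(model, cfg, dir, max_chunks = 2000L) {
  stopifnot(inherits(cfg, "sim_config"))
  validate_score_model(model)
  v <- as.data.frame(model)
  if (any(is.na(v$eaf))) stop2("model must carry effect-allele frequencies")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f <- v$eaf; b <- v$weight; m <- nrow(v)
  mu <- sum(2 * f * b)
  sig <- sqrt(sum(2 * f * (1 - f) * b^2))
  if (sig == 0) stop2("model PRS variance is zero")
  thr <- stats::qnorm(1 - cfg$prevalence)
  a <- sqrt(cfg$h2_prs); e_sd <- sqrt(1 - cfg$h2_prs)

  withr::with_seed(cfg$seed + 1L, {
    G_case <- NULL; G_ctrl <- NULL
    L_case <- numeric(); L_ctrl <- numeric()
    P_case <- numeric(); P_ctrl <- numeric()
    chunk <- 2000L
    for (it in seq_len(max_chunks)) {
      if (length(L_case) >= cfg$n_cases && length(L_ctrl) >= cfg$n_controls) break
      G <- matrix(stats::rbinom(chunk * m, 2L, rep(f, each = chunk)), chunk, m)
      P <- (as.numeric(G %*% b) - mu) / sig
      L <- a * P + e_sd * stats::rnorm(chunk)
      is_case <- L > thr
      need_case <- cfg$n_cases - length(L_case)
      if (need_case > 0 && any(is_case)) {
        take <- which(is_case)[seq_len(min(need_case, sum(is_case)))]
        G_case <- rbind(G_case, G[take, , drop = FALSE])
        L_case <- c(L_case, L[take]); P_case <- c(P_case, P[take])
      }
      need_ctrl <- cfg$n_controls - length(L_ctrl)
      if (need_ctrl > 0 && any(!is_case)) {
        take <- which(!is_case)[seq_len(min(need_ctrl, sum(!is_case)))]
        G_ctrl <- rbind(G_ctrl, G[take, , drop = FALSE])
        L_ctrl <- c(L_ctrl, L[take]); P_ctrl <- c(P_ctrl, P[take])
      }
    }
    if (length(L_case) < cfg$n_cases || length(L_ctrl) < cfg$n_controls)
      stop2("rejection-sampling budget exceeded; increase max_chunks or ",
            "prevalence (K=", cfg$prevalence, " may be too extreme)")
    samples <- c(sprintf("case_%04d", seq_len(cfg$n_cases)),
                 sprintf("ctrl_%04d", seq_len(cfg$n_controls)))
    G_all <- rbind(G_case, G_ctrl)
    truth <- data.frame(sample = samples,
                        group = rep(c("case", "control"),
                                    c(cfg$n_cases, cfg$n_controls)),
                        liability = c(L_case, L_ctrl),
                        raw_prs = as.numeric(G_all %*% b),
                        std_prs = c(P_case, P_ctrl),
                        case = rep(c(TRUE, FALSE), c(cfg$n_cases, cfg$n_controls)),
                        stringsAsFactors = FALSE)
    vcf_path <- file.path(dir, "cohort.vcf")
    write_vcf(model, G_all, samples, vcf_path,
              swap = (seq_len(m) %% 2L) == 0L)
    sheet <- data.frame(sample_id = samples, group = truth$group,
                        carrier = NA_integer_, prior_prob = NA_real_)
    sheet_path <- file.path(dir, "samples.tsv")
    utils::write.table(sheet, sheet_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    list(vcf = vcf_path, sample_sheet = sheet_path, truth = truth)
  })
}

#' Synthetic exon targets for a gene panel
#'
#' Lays each gene out on its own chromosome as a regular exon structure
#' (disjoint between genes by construction), 0-based half-open.
#'
#' @param genes character vector of gene symbols.
#' @param n_exons exons per gene.
#' @param exon_len exon length in bases.
#' @param intron_len gap between exons in bases.
#' @return data.frame `chrom`, `start`, `end`, `gene`.
#' @export
simulate_targets <- function(genes, n_exons = 12L, exon_len = 120L,
                             intron_len = 800L) {
  rows <- lapply(seq_along(genes), function(i) {
    start0 <- 1e6 + (seq_len(n_exons) - 1L) * (exon_len + intron_len)
    data.frame(chrom = paste0("chr", i), start = as.integer(start0),
               end = as.integer(start0 + exon_len), gene = genes[i],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate a per-sample depth track over exon targets
#'
#' Per-base depth is drawn from a negative binomial around `mean_depth`
#' (overdispersed relative to Poisson, so sub-threshold excursions occur at
#' realistic rates), then run-length-compressed into bedGraph-style
#' intervals. `gap_spec` plants low-depth stretches of known size at the
#' start of named genes, so ground-truth gap fractions are exact.
#'
#' @param targets gene target regions (`chrom`, `start`, `end`, `gene`).
#' @param mean_depth mean read depth (default 41.2).
#' @param overdispersion negative-binomial size parameter (default 200;
#'   larger = tighter around the mean).
#' @param gap_spec optional data.frame with columns `gene`, `depth`,
#'   `n_bases`: plant `n_bases` contiguous bases at the given depth at the
#'   start of each listed gene's target.
#' @param seed integer seed.
#' @return a [depth_track()].
#' @export
simulate_depth <- function(targets, mean_depth = 41.2, overdispersion = 200,
                           gap_spec = NULL, seed) {
  if (missing(seed)) stop2("simulate_depth requires an explicit seed")
  assert_that(mean_depth > 0, "mean_depth must be positive")
  withr::with_seed(as.integer(seed), {
    rows <- list()
    for (g in unique(targets$gene)) {
      tg <- targets[targets$gene == g, , drop = FALSE]
      tg <- tg[order(tg$chrom, tg$start), ]
      widths <- tg$end - tg$start
      total <- sum(widths)
      depth <- stats::rnbinom(total, size = overdispersion, mu = mean_depth)
      if (!is.null(gap_spec) && g %in% gap_spec$gene) {
        gs <- gap_spec[gap_spec$gene == g, , drop = FALSE]
        planted <- sum(as.integer(gs$n_bases))
        if (planted > total)
          stop2("planted gap of ", planted, " bases exceeds the ", total,
                "-base target of gene ", g)
        off_p <- 0L
        for (r in seq_len(nrow(gs))) {
          nb <- as.integer(gs$n_bases[r])
          depth[(off_p + 1L):(off_p + nb)] <- as.integer(gs$depth[r])
          off_p <- off_p + nb
        }
        # unplanted bases stay clear of the gap band so planted truth is exact
        depth[-seq_len(planted)] <- pmax(depth[-seq_len(planted)], 20L)
      }
      off <- 0L
      for (i in seq_len(nrow(tg))) {
        d <- depth[(off + 1L):(off + widths[i])]
        off <- off + widths[i]
        r <- rle(d)
        ends <- cumsum(r$lengths)
        starts <- c(0L, ends[-length(ends)])
        rows[[length(rows) + 1L]] <-
          data.frame(chrom = tg$chrom[i], start = tg$start[i] + starts,
                     end = tg$start[i] + ends, depth = r$values,
                     stringsAsFactors = FALSE)
      }
    }
    depth_track(do.call(rbind, rows))
  })
}

#' Simulate per-patient prior probabilities and carrier status
#'
#' Priors are Beta-distributed with the given mean and concentration
#' (shape1 = mean * concentration, shape2 = (1 - mean) * concentration);
#' carrier status is Bernoulli(prior) per patient, so the expected observed
#' carrier count equals the summed priors by construction and the
#' expected-vs-observed yield test holds under its own null.
#'
#' @param n number of patients.
#' @param mean_rate mean prior probability (default 0.13).
#' @param concentration Beta concentration parameter (> 0, default 30).
#' @param seed integer seed.
#' @return data.frame with `prior_prob` and `carrier` (0/1).
#' @export
simulate_priors <- function(n, mean_rate = 0.13, concentration = 30, seed) {
  if (missing(seed)) stop2("simulate_priors requires an explicit seed")
  assert_that(mean_rate > 0 && mean_rate < 1, "mean_rate must lie in (0,1)")
  assert_that(concentration > 0, "concentration must be positive")
  withr::with_seed(as.integer(seed), {
    p <- stats::rbeta(n, mean_rate * concentration,
                      (1 - mean_rate) * concentration)
    carrier <- stats::rbinom(n, 1L, p)
    data.frame(prior_prob = p, carrier = carrier)
  })
}

#' The 13 HBOC core genes and the actionable-gene panel fixture
#'
#' Reads the editable gene-panel fixtures shipped with the package:
#' `panel = "hboc_core"` is the 13-gene diagnostic panel (BRCA1, BRCA2,
#' PALB2, RAD51C, RAD51D, BRIP1, BARD1, PTEN, CDH1, STK11, TP53, CHEK2,
#' ATM); `panel = "actionable"` is the secondary-findings list.
#'
#' @param panel which panel to read.
#' @return character vector of gene symbols.
#' @export
gene_panel <- function(panel = c("hboc_core", "actionable")) {
  panel <- match.arg(panel)
  path <- system.file("extdata", paste0(panel, "_genes.txt"), package = "prspipe")
  readLines(path)
}

#' Emit a complete miniature synthetic study
#'
#' Writes every input the pipeline consumes into one directory: a scoring
#' file, a multi-sample VCF with a matching sample sheet (priors and carrier
#' status filled in for the cases), exon targets for the 13 HBOC core genes,
#' two cohorts of per-sample bedGraph depth tracks (one with planted gaps),
#' and a classified-variant table derived from the simulated carriers.
#'
#' @param dir output directory.
#' @param seed integer seed.
#' @param m_variants,n_cases,n_controls study size (default 50 variants,
#'   200 + 200 samples).
#' @param n_depth_samples depth-track samples per platform cohort.
#' @param mean_rate mean prior probability for the cases.
#' @param secondary_rate per-case probability of a pathogenic secondary
#'   finding in an actionable gene (default 0.03).
#' @return invisible list of all paths plus the simulation truth.
#' @export
make_fixture_study <- function(dir, seed, m_variants = 50L, n_cases = 200L,
                               n_controls = 200L, n_depth_samples = 6L,
                               mean_rate = 0.13, secondary_rate = 0.03) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- sim_config(seed = seed, m_variants = m_variants, n_cases = n_cases,
                    n_controls = n_controls)
  model <- simulate_score_model(cfg)
  score_path <- file.path(dir, "score_model.tsv")
  write_score_file(model, score_path)
  cohort <- simulate_cohort(model, cfg, dir)

  # priors + carrier status for the cases
  pr <- simulate_priors(n_cases, mean_rate = mean_rate, seed = seed + 2L)
  sheet <- utils::read.table(cohort$sample_sheet, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  is_case <- sheet$group == "case"
  sheet$prior_prob[is_case] <- pr$prior_prob
  sheet$carrier[is_case] <- pr$carrier
  utils::write.table(sheet, cohort$sample_sheet, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # classified-variant table: one LP/P core-gene variant per carrier,
  # plus VUS sprinkled over non-carriers
  core <- gene_panel("hboc_core")
  carriers <- sheet$sample_id[is_case][pr$carrier == 1]
  vt <- withr::with_seed(as.integer(seed) + 3L, {
    lp <- data.frame(patient_id = carriers,
                     gene = sample(core, length(carriers), replace = TRUE),
                     hgvs = sprintf("c.%d%s>%s", sample.int(5000, length(carriers)),
                                    sample(c("A", "C", "G", "T"), length(carriers), TRUE),
                                    sample(c("A", "C", "G", "T"), length(carriers), TRUE)),
                     classification = sample(c("pathogenic", "likely pathogenic"),
                                             length(carriers), replace = TRUE),
                     stringsAsFactors = FALSE)
    n_vus <- max(3L, round(0.1 * n_cases))
    vus <- data.frame(patient_id = sample(sheet$sample_id[is_case], n_vus, TRUE),
                      gene = sample(core, n_vus, replace = TRUE),
                      hgvs = sprintf("c.%dG>T", sample.int(5000, n_vus)),
                      classification = "VUS", stringsAsFactors = FALSE)
    # secondary findings in actionable genes for ~3% of the cases
    act <- gene_panel("actionable")
    sf_who <- sheet$sample_id[is_case][stats::rbinom(n_cases, 1L,
                                                     secondary_rate) == 1]
    sf <- data.frame(patient_id = sf_who,
                     gene = sample(act, length(sf_who), replace = TRUE),
                     hgvs = sprintf("c.%dC>T", sample.int(5000, length(sf_who))),
                     classification = "pathogenic", stringsAsFactors = FALSE)
    rbind(lp, vus, sf)
  })
  var_path <- file.path(dir, "variants.tsv")
  utils::write.table(vt, var_path, sep = "\t", quote = FALSE, row.names = FALSE)

  targets <- simulate_targets(core)
  bed_path <- file.path(dir, "targets.bed")
  write_targets_bed(targets, bed_path)

  depth_dir <- file.path(dir, "depth")
  dir.create(depth_dir, showWarnings = FALSE)
  manifest <- list()
  for (i in seq_len(n_depth_samples)) {
    # genome cohort: tight depth, one sample with a planted reviewable gap
    gs <- if (i == 1)
      data.frame(gene = "BRCA1", depth = 17L, n_bases = 60L) else NULL
    tr <- simulate_depth(targets, mean_depth = 41.2, overdispersion = 200,
                         gap_spec = gs, seed = seed + 10L + i)
    p <- file.path(depth_dir, sprintf("gs_%02d.bedGraph", i))
    write_bedgraph(tr, p)
    manifest[[length(manifest) + 1L]] <-
      data.frame(sample = sprintf("gs_%02d", i), cohort = "srGS", path = p)
    # exome cohort: lower, noisier depth with planted hard gaps
    gs2 <- data.frame(gene = c("ATM", "BARD1"), depth = c(5L, 10L),
                      n_bases = c(120L, 80L))
    tr2 <- simulate_depth(targets, mean_depth = 35, overdispersion = 8,
                          gap_spec = gs2, seed = seed + 100L + i)
    p2 <- file.path(depth_dir, sprintf("es_%02d.bedGraph", i))
    write_bedgraph(tr2, p2)
    manifest[[length(manifest) + 1L]] <-
      data.frame(sample = sprintf("es_%02d", i), cohort = "ES", path = p2)
  }
  man <- do.call(rbind, manifest)
  man_path <- file.path(dir, "depth_manifest.tsv")
  utils::write.table(man, man_path, sep = "\t", quote = FALSE, row.names = FALSE)

  invisible(list(score_model = score_path, vcf = cohort$vcf,
                 sample_sheet = cohort$sample_sheet, variants = var_path,
                 targets = bed_path, depth_manifest = man_path,
                 truth = cohort$truth))
}
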