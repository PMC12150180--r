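#' Extract effect-allele dosages for a score model from a VCF
#'
#' Reads genotypes (GT) from a VCF 4.2+ file, decomposes multi-allelic records
#' into biallelic ones (symbolic ALT alleles such as `<DEL>` are skipped),
#' matches every model variant against the records at its position with
#' [match_variant()], and returns per-sample effect-allele dosages.
#'
#' Half-missing genotypes (one allele absent) and `./.` count as missing;
#' phase is ignored. When several decomposed records at the same position are
#' compatible with a model variant, the best status wins (exact, then swap,
#' then flip, then flip_swap). Model variants with no usable record get
#' status `missing`; ambiguous palindromic variants are excluded (all-NA
#' dosage column).
#'
#' @param model a [score_model()] (build GRCh38).
#' @param vcf path to a VCF file (plain or bgzipped).
#' @param samples character vector of sample ids to extract; default all.
#' @param af_margin passed to [match_variant()].
#' @return An object of class `dosage_matrix`: list with `samples`,
#'   `variants` (model keys), `dosages` (samples x variants numeric matrix,
#'   NA = missing) and `statuses` (one row per model variant).
#' @export
extract_dosages <- function(model, vcf, samples = NULL, af_margin = 0.08) {
  validate_score_model(model)
  if (!identical(attr(model, "build"), "GRCh38"))
    stop2("position matching requires a GRCh38 model; pre-lift the scoring file")
  v <- as.data.frame(model)
  x <- vcfR::read.vcfR(vcf, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(x), stringsAsFactors = FALSE)
  gt_raw <- vcfR::extract.gt(x, element = "GT")
  vcf_samples <- colnames(gt_raw)
  if (is.null(samples)) samples <- vcf_samples
  absent <- setdiff(samples, vcf_samples)
  if (length(absent) > 0)
    stop2("sample id(s) absent from VCF: ", paste(absent, collapse = ", "))
  gt_raw <- gt_raw[, samples, drop = FALSE]

  # decompose into biallelic records: one (row, alt index) pair per record
  recs <- list()
  for (r in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[r], ",", fixed = TRUE)[[1]]
    for (k in seq_along(alts)) {
      if (grepl("^<", alts[k])) next  # symbolic ALT
      recs[[length(recs) + 1L]] <- list(row = r, k = k,
                                        chrom = fix$CHROM[r],
                                        pos = as.integer(fix$POS[r]),
                                        ref = fix$REF[r], alt = alts[k])
    }
  }
  rec_chrom <- vapply(recs, function(z) norm_chrom(z$chrom), character(1))
  rec_pos <- vapply(recs, function(z) z$pos, integer(1))

  # ALT-dosage of decomposed record k: count of allele index k in GT
  rec_dosage <- function(rec) {
    gts <- gt_raw[rec$row, ]
    parts <- strsplit(gts, "[/|]")
    vapply(parts, function(p) {
      if (length(p) != 2L || any(p == ".") || any(is.na(p))) return(NA_real_)
      sum(p == as.character(rec$k))
    }, double(1))
  }

  n_s <- length(samples); n_v <- nrow(v)
  dosages <- matrix(NA_real_, n_s, n_v, dimnames = list(samples, NULL))
  status <- character(n_v); transform <- rep(NA_character_, n_v)
  prio <- c(exact = 1, swap = 2, flip = 3, flip_swap = 4, ambiguous = 5, mismatch = 6)

  for (j in seq_len(n_v)) {
    hit <- which(rec_chrom == norm_chrom(v$chrom[j]) & rec_pos == v$pos[j])
    if (length(hit) == 0) { status[j] <- "missing"; next }
    best <- NULL; best_p <- Inf; best_d <- NULL
    for (h in hit) {
      rec <- recs[[h]]
      d <- rec_dosage(rec)
      af <- if (all(is.na(d))) NA_real_ else mean(d, na.rm = TRUE) / 2
      m <- match_variant(v[j, ], list(chrom = rec$chrom, pos = rec$pos,
                                      ref = rec$ref, alt = rec$alt, af = af),
                         af_margin = af_margin)
      if (prio[[m$status]] < best_p) { best <- m; best_p <- prio[[m$status]]; best_d <- d }
    }
    status[j] <- best$status
    transform[j] <- best$transform
    if (!is.na(best$transform)) {
      dosages[, j] <- if (best$transform == "complement") 2 - best_d else best_d
    }
  }
  keys <- paste0(v$chrom, ":", v$pos, ":", v$other_allele, ">", v$effect_allele)
  colnames(dosages) <- keys
  structure(list(samples = samples, variants = keys, dosages = dosages,
                 statuses = data.frame(variant = keys, status = status,
                                       transform = transform,
                                       stringsAsFactors = FALSE)),
            class = "dosage_matrix")
}

#' @export
print.dosage_matrix <- function(x, ...) {
  tab <- table(factor(x$statuses$status,
                      levels = c("exact", "swap", "flip", "flip_swap",
                                 "ambiguous", "mismatch", "missing")))
  cat(sprintf("<dosage_matrix> %d sample(s) x %d model variant(s)\n",
              length(x$samples), length(x$variants)))
  print(tab)
  invisible(x)
}

#' Compute raw polygenic risk scores
#'
#' The raw score of sample i is the weighted dosage sum over the model
#' variants, S_i = sum_j beta_j * d_ij. Missing dosages (unmatched variants,
#' ambiguous palindromic variants, missing genotypes) are handled by policy:
#' \describe{
#'   \item{impute_af}{replace the missing dosage by its Hardy-Weinberg
#'     expectation 2 * eaf_j (the default; keeps scores comparable across
#'     samples with different callable sets).}
#'   \item{omit}{drop the term.}
#'   \item{fail}{error on any missing dosage.}
#' }
#'
#' @param dm a [extract_dosages()] result.
#' @param model the matching [score_model()].
#' @param policy one of "impute_af", "omit", "fail".
#' @return An object of class `prs_scores`: data.frame with columns `sample`,
#'   `raw`, `n_used` (genotyped variants contributing), `n_imputed`.
#' @export
compute_raw_prs <- function(dm, model, policy = c("impute_af", "omit", "fail")) {
  policy <- match.arg(policy)
  v <- as.data.frame(model)
  stopifnot(inherits(dm, "dosage_matrix"))
  if (length(dm$variants) != nrow(v))
    stop2("dosage matrix has ", length(dm$variants), " variants but model has ", nrow(v))
  d <- dm$dosages
  miss <- is.na(d)
  if (policy == "fail" && any(miss)) {
    j <- which(colSums(miss) > 0)[1]
    stop2("missing dosage at model variant ", dm$variants[j], " (policy=fail)")
  }
  w <- v$weight
  if (policy == "impute_af") {
    need <- which(colSums(miss) > 0)
    no_af <- need[is.na(v$eaf[need])]
    if (length(no_af) > 0)
      stop2("policy=impute_af but variant ", dm$variants[no_af[1]],
            " has no effect-allele frequency")
    imp <- matrix(rep(2 * v$eaf, each = nrow(d)), nrow(d), ncol(d))
    d[miss] <- imp[miss]
    raw <- .ordered_score_sum(d, w)
    n_imputed <- rowSums(miss)
  } else {
    d0 <- d; d0[miss] <- 0
    raw <- .ordered_score_sum(d0, w)
    n_imputed <- rep(0L, nrow(d))
  }
  n_used <- rowSums(!miss)
  if (any(n_used == 0))
    warning("sample(s) with no genotyped model variants: ",
            paste(dm$samples[n_used == 0], collapse = ", "), call. = FALSE)
  structure(data.frame(sample = dm$samples, raw = raw,
                       n_used = as.integer(n_used),
                       n_imputed = as.integer(n_imputed),
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("prs_scores", "data.frame"), policy = policy)
}

# weighted dosage sum accumulated variant-by-variant in model order, in
# plain double precision: the result is reproducible and independent of the
# BLAS in use (a BLAS gemm may reorder the summation)
.ordered_score_sum <- function(d, w) {
  raw <- numeric(nrow(d))
  for (j in seq_along(w)) raw <- raw + w[j] * d[, j]
  raw
}

#' Build a control-cohort calibration reference
#'
#' Stores the control mean, sample standard deviation (n-1 denominator) and
#' the sorted raw scores of a control cohort; used to convert raw scores into
#' z-scores and empirical percentiles.
#'
#' @param control_raw numeric vector of control raw scores (>= 2, non-constant).
#' @return An object of class `prs_calibration`.
#' @export
build_calibration <- function(control_raw) {
  control_raw <- as.numeric(control_raw)
  if (length(control_raw) < 2 || any(!is.finite(control_raw)))
    stop2("calibration needs >= 2 finite control scores")
  s <- stats::sd(control_raw)
  if (s == 0) stop2("degenerate calibration: control scores are constant")
  structure(list(mean = mean(control_raw), sd = s,
                 sorted = sort(control_raw), n = length(control_raw)),
            class = "prs_calibration")
}

#' @export
print.prs_calibration <- function(x, ...) {
  cat(sprintf("<prs_calibration> n=%d controls, mean=%.4g, sd=%.4g\n",
              x$n, x$mean, x$sd))
  invisible(x)
}

#' Calibrate raw scores against a control reference
#'
#' Adds z-scores `z = (raw - mean_c) / sd_c` and percentiles to a score table.
#' The default percentile is the empirical midrank against the control
#' distribution, `(#controls below + 0.5 * #controls equal) / n_controls`;
#' `method = "normal"` uses the normal-theory percentile `pnorm(z)` instead.
#' `top_decile` flags percentiles at or above `top_band`.
#'
#' @param records a `prs_scores` data.frame (or any data.frame with a `raw`
#'   column).
#' @param ref a [build_calibration()] reference.
#' @param method "empirical" (default) or "normal".
#' @param top_band percentile threshold for the top band (default 0.9).
#' @return `records` with `z`, `percentile`, `top_decile` columns appended.
#' @export
calibrate <- function(records, ref, method = c("empirical", "normal"),
                      top_band = 0.9) {
  method <- match.arg(method)
  stopifnot(inherits(ref, "prs_calibration"))
  raw <- records$raw
  z <- (raw - ref$mean) / ref$sd
  if (method == "empirical") {
    sc <- ref$sorted
    pct <- vapply(raw, function(r)
      (sum(sc < r) + 0.5 * sum(sc == r)) / ref$n, double(1))
  } else {
    pct <- stats::pnorm(z)
  }
  records$z <- z
  records$percentile <- pct
  records$top_decile <- pct >= top_band
  records
}

#' Export a CanRisk-compatible PRS block
#'
#' Emits the PRS header line that the CanRisk risk-assessment tool accepts as
#' part of its pedigree input, carrying the score correlation parameter alpha
#' and the calibrated z-score, both with fixed 4-decimal formatting. alpha is
#' a property of the published score (square root of the liability variance
#' it explains) and is supplied by the user, never computed here.
#'
#' @param record one-row `prs_scores` data.frame with a `z` column, or a
#'   single z value.
#' @param alpha score correlation parameter, strictly inside (0, 1).
#' @return character scalar, the `##PRS=...` header line.
#' @export
export_canrisk <- function(record, alpha) {
  z <- if (is.numeric(record)) record[1] else record$z[1]
  if (is.null(z) || is.na(z)) stop2("record carries no z-score; calibrate first")
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) ||
      alpha <= 0 || alpha >= 1)
    stop2("alpha must lie strictly inside (0, 1)")
  sprintf("##PRS=alpha=%.4f,zscore=%.4f", alpha, z)
}

#' Write a per-sample PRS table
#'
#' Tab-separated with columns sample_id, raw, n_used, n_imputed, z,
#' percentile, top_decile.
#'
#' @param records calibrated `prs_scores`.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_prs_table <- function(records, path) {
  out <- data.frame(sample_id = records$sample, raw = records$raw,
                    n_used = records$n_used, n_imputed = records$n_imputed,
                    z = records$z, percentile = records$percentile,
                    top_decile = records$top_decile)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-sample PRS table written by [write_prs_table()]
#' @param path PRS table path.
#' @return data.frame.
#' @export
read_prs_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
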