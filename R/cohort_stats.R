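#' Cohen's D (pooled-SD standardized mean difference)
#'
#' `d = (mean(x) - mean(y)) / s_p` with the pooled standard deviation
#' `s_p = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1+n2-2))`. The sign follows the
#' first argument minus the second.
#'
#' @param x,y numeric samples of length >= 2.
#' @return Cohen's D.
#' @export
cohens_d <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop2("cohens_d needs >= 2 observations per group")
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  if (sp2 == 0) stop2("pooled standard deviation is zero")
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Mann-Whitney U test with normal approximation
#'
#' U statistic of the first group with midrank tie handling, tie-corrected
#' variance, normal approximation without continuity correction, two-sided
#' p-value and the rank effect size r = |Z|/sqrt(N). The worst-case absolute
#' deviation of the approximate p from the exact permutation p over tie-free
#' instances with n1+n2 <= 10 is 0.188 (complete enumeration); it shrinks
#' rapidly with sample size.
#'
#' @param x,y numeric samples.
#' @return list with `U`, `Z`, `p`, `r`, `n1`, `n2`.
#' @export
mann_whitney_u <- function(x, y) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  rk <- rank(c(x, y))
  u <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(rk)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sig2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sig2 <= 0) stop2("Mann-Whitney variance is zero (all values tied)")
  z <- (u - mu) / sqrt(sig2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(U = u, Z = z, p = p, r = abs(z) / sqrt(n), n1 = n1, n2 = n2)
}

#' Rank effect size r from a Mann-Whitney Z statistic
#'
#' `r = |Z| / sqrt(N)` where N is the total number of observations.
#'
#' @param Z normal-approximation test statistic.
#' @param n_total total sample size (>= 2).
#' @return r in \[0, 1\] for any Z attainable at that N.
#' @export
mwu_effect_r <- function(Z, n_total) {
  if (n_total < 2) stop2("n_total must be >= 2")
  abs(Z) / sqrt(n_total)
}

# deterministic quantile-spaced subsample for the normality gate (no RNG)
.gate_subsample <- function(x, cap = 5000L) {
  if (length(x) <= cap) return(x)
  sort(x)[unique(round(seq(1, length(x), length.out = cap)))]
}

#' Normality-gated two-sample comparison
#'
#' Applies a Shapiro-Wilk normality test to each group at `gate_alpha`
#' (on at most 5000 quantile-spaced values per group, since the test
#' degenerates for huge n). If both groups pass, a Welch t-test is used;
#' otherwise a Mann-Whitney U test with normal approximation, midrank tie
#' correction and no continuity correction. Cohen's D is always attached;
#' the rank effect size r = |Z|/sqrt(N) only for the rank branch. Two-sided
#' throughout.
#'
#' @param x,y numeric samples, length >= 3 each.
#' @param gate_alpha significance level of the normality gate (default 0.05).
#' @return An object of class `two_sample_result`: list with `test_used`
#'   ("t" or "mann_whitney"), `statistic`, `p`, `d`, `r`, `n1`, `n2`, and the
#'   per-group Shapiro p-values `shapiro_p`.
#' @export
two_sample_compare <- function(x, y, gate_alpha = 0.05) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 3 || length(y) < 3)
    stop2("two_sample_compare needs >= 3 observations per group")
  if (stats::sd(c(x, y)) == 0)
    stop2("all observations are identical; no comparison possible")
  shapiro_p <- vapply(list(x, y), function(g) {
    g <- .gate_subsample(g)
    if (stats::sd(g) == 0) return(0)  # constant group: certainly non-Gaussian
    stats::shapiro.test(g)$p.value
  }, double(1))
  # d is undefined (NA) when both groups are internally constant yet differ;
  # the rank branch below still applies
  d <- tryCatch(cohens_d(x, y), error = function(e) NA_real_)
  if (all(shapiro_p > gate_alpha)) {
    tt <- stats::t.test(x, y)
    out <- list(test_used = "t", statistic = unname(tt$statistic),
                p = tt$p.value, d = d, r = NA_real_,
                n1 = length(x), n2 = length(y), shapiro_p = shapiro_p)
  } else {
    mw <- mann_whitney_u(x, y)
    out <- list(test_used = "mann_whitney", statistic = mw$U, Z = mw$Z,
                p = mw$p, d = d, r = mw$r,
                n1 = length(x), n2 = length(y), shapiro_p = shapiro_p)
  }
  structure(out, class = "two_sample_result")
}

#' @export
print.two_sample_result <- function(x, ...) {
  cat(sprintf("<two_sample_result> %s test: statistic=%.4g, p=%.4g\n",
              x$test_used, x$statistic, x$p))
  cat(sprintf("  Cohen's D=%.4g", x$d))
  if (!is.na(x$r)) cat(sprintf(", r=%.4g", x$r))
  cat(sprintf("  (n1=%d, n2=%d)\n", x$n1, x$n2))
  invisible(x)
}

#' Poisson-binomial probability mass function
#'
#' Exact distribution of the number of successes among independent Bernoulli
#' trials with heterogeneous probabilities, by dynamic-programming
#' convolution: the mass vector is updated one trial at a time.
#'
#' @param p vector of success probabilities in \[0, 1\].
#' @return numeric vector of length `length(p) + 1`; element k+1 is P(X = k).
#' @export
poisson_binomial_pmf <- function(p) {
  if (length(p) == 0) stop2("empty probability vector")
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop2("probabilities must lie in [0,1]")
  pmf <- 1
  for (pi in p) pmf <- c(pmf * (1 - pi), 0) + c(0, pmf * pi)
  pmf
}

#' Expected-vs-observed diagnostic-yield test
#'
#' Compares the observed number of patients with a pathogenic finding against
#' the per-patient prior probabilities (e.g. CanRisk predictions). Under
#' `mode = "poisson_binomial"` (default) the expected count is `sum(p_i)` with
#' variance `sum(p_i (1 - p_i))`, respecting per-patient heterogeneity; under
#' `mode = "binomial_mean"` the priors are collapsed to their mean p-bar with
#' variance `n * p-bar * (1 - p-bar)`. Both give `z = (observed - mean)/sd`
#' and a two-sided normal p-value. For the Poisson-binomial mode with
#' `n <= exact_limit`, `exact_p` additionally reports the exact tail
#' probability (by DP convolution) in the direction of the deviation:
#' `P(X >= observed)` when observed >= mean, else `P(X <= observed)`.
#'
#' @param priors per-patient prior probabilities in \[0, 1\].
#' @param observed observed integer count of patients with a finding.
#' @param mode "poisson_binomial" or "binomial_mean".
#' @param exact_limit largest n for which the exact tail is computed.
#' @return An object of class `yield_test`: list with `expected_mean`,
#'   `expected_sd`, `observed`, `z`, `p`, `exact_p` (NA when not computed),
#'   `mode`, `n`.
#' @export
expected_yield_test <- function(priors, observed,
                                mode = c("poisson_binomial", "binomial_mean"),
                                exact_limit = 10000L) {
  mode <- match.arg(mode)
  priors <- as.numeric(priors)
  if (length(priors) == 0) stop2("empty prior vector")
  if (any(is.na(priors)) || any(priors < 0 | priors > 1))
    stop2("priors must lie in [0,1]")
  observed <- as.integer(observed)
  if (observed < 0 || observed > length(priors))
    stop2("observed count must lie in [0, n]")
  m <- sum(priors)
  v <- if (mode == "poisson_binomial") sum(priors * (1 - priors))
       else length(priors) * mean(priors) * (1 - mean(priors))
  if (v <= 0) stop2("degenerate prior set: zero variance")
  z <- (observed - m) / sqrt(v)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  exact_p <- NA_real_
  if (mode == "poisson_binomial" && length(priors) <= exact_limit) {
    pmf <- poisson_binomial_pmf(priors)
    exact_p <- if (observed >= m) sum(pmf[(observed + 1L):length(pmf)])
               else sum(pmf[1:(observed + 1L)])
    exact_p <- min(1, max(0, exact_p))
  }
  structure(list(expected_mean = m, expected_sd = sqrt(v), observed = observed,
                 z = z, p = p, exact_p = exact_p, mode = mode,
                 n = length(priors)),
            class = "yield_test")
}

#' @export
print.yield_test <- function(x, ...) {
  cat(sprintf("<yield_test> (%s) expected %.2f +/- %.2f, observed %d\n",
              x$mode, x$expected_mean, x$expected_sd, x$observed))
  cat(sprintf("  z=%.4f, two-sided p=%.4g", x$z, x$p))
  if (!is.na(x$exact_p)) cat(sprintf(", exact tail p=%.4g", x$exact_p))
  cat("\n")
  invisible(x)
}

.lp_p_labels <- c("pathogenic", "likely pathogenic", "p", "lp", "class 5", "class 4")
.acmg_five_tier <- c("benign", "likely benign", "vus", "uncertain significance",
                     "likely pathogenic", "pathogenic", "b", "lb", "p", "lp",
                     "class 1", "class 2", "class 3", "class 4", "class 5")

#' Per-panel pathogenic-finding rate
#'
#' Counts the screened patients carrying at least one variant classified
#' likely pathogenic or pathogenic (LP/P) in a gene of the given panel; a
#' patient is counted once regardless of how many qualifying variants they
#' carry. The denominator is the screened patient list, not the variant table.
#'
#' @param variants data.frame with columns `patient_id`, `gene`,
#'   `classification` (five-tier ACMG labels, case-insensitive).
#' @param panel character vector of gene symbols.
#' @param patients character vector of screened patient ids.
#' @return An object of class `rate_panel`: list with `n_screened`,
#'   `n_with_finding`, `rate`, `panel`, `patients_with_finding`.
#' @export
finding_rate <- function(variants, panel, patients) {
  patients <- unique(as.character(patients))
  if (length(patients) == 0) stop2("empty screened patient list")
  if (nrow(variants) > 0) {
    need <- c("patient_id", "gene", "classification")
    miss <- setdiff(need, names(variants))
    if (length(miss) > 0)
      stop2("variant table lacks column(s): ", paste(miss, collapse = ", "))
    cls <- tolower(trimws(variants$classification))
    unknown <- setdiff(unique(cls), .acmg_five_tier)
    if (length(unknown) > 0)
      stop2("unknown classification label(s): ", paste(unknown, collapse = ", "))
    stray <- setdiff(unique(variants$patient_id), patients)
    if (length(stray) > 0)
      stop2("variant table contains patient(s) not in the screened list: ",
            paste(stray, collapse = ", "))
    hit <- cls %in% .lp_p_labels & variants$gene %in% panel
    found <- unique(variants$patient_id[hit])
  } else {
    found <- character()
  }
  structure(list(n_screened = length(patients), n_with_finding = length(found),
                 rate = length(found) / length(patients), panel = panel,
                 patients_with_finding = found),
            class = "rate_panel")
}

#' @export
print.rate_panel <- function(x, ...) {
  cat(sprintf("<rate_panel> %d/%d patients with an LP/P finding: %.2f%% (%d-gene panel)\n",
              x$n_with_finding, x$n_screened, 100 * x$rate, length(x$panel)))
  invisible(x)
}

#' Percentile-band enrichment per group
#'
#' Tabulates, per group, the number and fraction of samples in the top
#' percentile band (`top_decile` flag from [calibrate()]), and the mean age
#' of onset when supplied.
#'
#' @param records calibrated `prs_scores` rows.
#' @param group character/factor group label per record.
#' @param onset_age optional numeric age of onset per record.
#' @return data.frame with one row per group: `group`, `n`, `n_top`,
#'   `frac_top`, `mean_onset_age`.
#' @export
percentile_enrichment <- function(records, group, onset_age = NULL) {
  stopifnot(!is.null(records$top_decile))
  group <- as.character(group)
  if (length(group) != nrow(records))
    stop2("group labels must align with records")
  gs <- unique(group)
  rows <- lapply(gs, function(g) {
    i <- group == g
    data.frame(group = g, n = sum(i), n_top = sum(records$top_decile[i]),
               frac_top = mean(records$top_decile[i]),
               mean_onset_age = if (is.null(onset_age)) NA_real_
                                else mean(onset_age[i], na.rm = TRUE))
  })
  do.call(rbind, rows)
}
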