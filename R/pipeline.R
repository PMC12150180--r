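#' Build a validated pipeline run configuration
#'
#' Collects file paths and thresholds for the score / stats / coverage
#' subcommands. Every threshold has the diagnostic default (gap below 20
#' reads, reviewable floor 15 reads, coverage threshold 30 reads, normality
#' gate 0.05, top band at the 90th percentile). Referenced files are checked
#' for existence at validation time.
#'
#' @param ... named configuration entries; see Details.
#' @details Recognised keys: `score_model`, `vcf`, `sample_sheet`,
#'   `variants`, `targets`, `depth_manifest`, `out_dir`, `gap_threshold`,
#'   `review_floor`, `coverage_threshold`, `gate_alpha`, `top_band`,
#'   `missing_policy` ("impute_af"/"omit"/"fail"), `yield_mode`
#'   ("poisson_binomial"/"binomial_mean"), `percentile_method`
#'   ("empirical"/"normal"), `canrisk_alpha`, `seed`.
#' @return An object of class `run_config` (named list).
#' @export
run_config <- function(...) {
  cfg <- list(...)
  defaults <- list(gap_threshold = 20, review_floor = 15,
                   coverage_threshold = 30, gate_alpha = 0.05, top_band = 0.9,
                   missing_policy = "impute_af", yield_mode = "poisson_binomial",
                   percentile_method = "empirical", canrisk_alpha = 0.45,
                   out_dir = ".")
  for (k in names(defaults)) cfg[[k]] <- cfg[[k]] %||% defaults[[k]]
  assert_that(cfg$review_floor < cfg$gap_threshold,
              "review_floor must be below gap_threshold")
  assert_that(cfg$gate_alpha > 0 && cfg$gate_alpha < 1,
              "gate_alpha must lie in (0,1)")
  assert_that(cfg$top_band > 0 && cfg$top_band < 1,
              "top_band must lie in (0,1)")
  assert_that(cfg$missing_policy %in% c("impute_af", "omit", "fail"),
              "unknown missing_policy")
  assert_that(cfg$yield_mode %in% c("poisson_binomial", "binomial_mean"),
              "unknown yield_mode")
  for (k in c("score_model", "vcf", "sample_sheet", "variants", "targets",
              "depth_manifest")) {
    if (!is.null(cfg[[k]]) && !file.exists(cfg[[k]]))
      stop2("configured file does not exist: ", k, " = ", cfg[[k]])
  }
  structure(cfg, class = "run_config")
}

#' Read a flat key = value configuration file
#'
#' One `key = value` entry per line; `#` starts a comment; numeric-looking
#' values are coerced. Entries in `...` (e.g. mirrored command-line flags)
#' override file entries.
#'
#' @param path config file path.
#' @param ... overriding entries.
#' @return a [run_config()].
#' @export
read_run_config <- function(path, ...) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  cfg <- list()
  for (ln in lines) {
    k <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    num <- suppressWarnings(as.numeric(val))
    cfg[[k]] <- if (!is.na(num)) num else val
  }
  overrides <- list(...)
  for (k in names(overrides)) cfg[[k]] <- overrides[[k]]
  do.call(run_config, cfg)
}

read_sample_sheet <- function(path) {
  sheet <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("sample_id", "group")
  miss <- setdiff(need, names(sheet))
  if (length(miss) > 0)
    stop2("sample sheet lacks column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(sheet$group), c("case", "control"))
  if (length(bad) > 0)
    stop2("sample sheet group must be case/control; found: ",
          paste(bad, collapse = ", "))
  sheet
}

log_msg <- function(...) message(sprintf("[prspipe] %s", sprintf(...)))

#' Run the scoring arm of the pipeline
#'
#' Extracts dosages for the configured score model from the VCF, computes raw
#' scores under the configured missing policy, calibrates against the control
#' samples of the sample sheet, and writes a per-sample PRS table, one
#' CanRisk PRS block per sample, and a JSON run manifest recording thresholds
#' and per-status variant counts.
#'
#' @param cfg a [run_config()] with `score_model`, `vcf`, `sample_sheet`,
#'   `out_dir`.
#' @return invisible list: calibrated `records`, `calibration`, `dosages`,
#'   `manifest` path.
#' @export
run_score <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  model <- read_score_file(cfg$score_model)
  sheet <- read_sample_sheet(cfg$sample_sheet)
  log_msg("scoring %d samples against %d-variant model '%s'",
          nrow(sheet), nrow(model), attr(model, "name"))
  dm <- extract_dosages(model, cfg$vcf, samples = sheet$sample_id)
  rec <- compute_raw_prs(dm, model, policy = cfg$missing_policy)
  controls <- sheet$sample_id[sheet$group == "control"]
  if (length(controls) == 0)
    stop2("no control samples in the sheet; calibration impossible")
  ref <- build_calibration(rec$raw[rec$sample %in% controls])
  rec <- calibrate(rec, ref, method = cfg$percentile_method,
                   top_band = cfg$top_band)
  prs_path <- file.path(cfg$out_dir, "prs_table.tsv")
  write_prs_table(rec, prs_path)
  canrisk_path <- file.path(cfg$out_dir, "canrisk_blocks.txt")
  writeLines(vapply(seq_len(nrow(rec)), function(i)
    paste0(rec$sample[i], "\t",
           export_canrisk(rec[i, ], alpha = cfg$canrisk_alpha)),
    character(1)), canrisk_path)
  status_counts <- as.list(table(dm$statuses$status))
  manifest <- list(tool = "prspipe", version = as.character(utils::packageVersion("prspipe")),
                   model = attr(model, "name"), n_model_variants = nrow(model),
                   n_samples = nrow(sheet), n_controls = length(controls),
                   missing_policy = cfg$missing_policy,
                   percentile_method = cfg$percentile_method,
                   top_band = cfg$top_band, canrisk_alpha = cfg$canrisk_alpha,
                   variant_status_counts = status_counts,
                   inputs = list(score_model = cfg$score_model, vcf = cfg$vcf,
                                 sample_sheet = cfg$sample_sheet),
                   outputs = list(prs_table = prs_path,
                                  canrisk_blocks = canrisk_path))
  man_path <- file.path(cfg$out_dir, "score_manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  log_msg("wrote %s (statuses: %s)", prs_path,
          paste(names(status_counts), unlist(status_counts),
                sep = "=", collapse = ", "))
  invisible(list(records = rec, calibration = ref, dosages = dm,
                 manifest = man_path))
}

#' Run the cohort-statistics arm of the pipeline
#'
#' Joins the PRS table with the sample sheet and (optionally) a classified-
#' variant table, then emits the cohort comparisons: case vs control z-scores
#' and carrier vs non-carrier z-scores (normality-gated two-sample tests with
#' Cohen's D and rank effect size), the expected-vs-observed diagnostic-yield
#' test from the per-patient priors, percentile-band enrichment per group,
#' and LP/P finding rates for the core and actionable panels.
#'
#' @param cfg a [run_config()] with `prs_table` (or the `records` of a prior
#'   [run_score()] under `out_dir`), `sample_sheet`, optionally `variants`.
#' @return invisible list of results; a JSON and TSV report are written to
#'   `out_dir`.
#' @export
run_stats <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  prs_path <- cfg$prs_table %||% file.path(cfg$out_dir, "prs_table.tsv")
  if (!file.exists(prs_path)) stop2("PRS table not found: ", prs_path)
  prs <- read_prs_table(prs_path)
  sheet <- read_sample_sheet(cfg$sample_sheet)
  d <- merge(prs, sheet, by = "sample_id")
  res <- list()

  z_case <- d$z[d$group == "case"]; z_ctrl <- d$z[d$group == "control"]
  if (length(z_case) >= 3 && length(z_ctrl) >= 3) {
    cc <- two_sample_compare(z_case, z_ctrl, gate_alpha = cfg$gate_alpha)
    res$case_vs_control <- unclass(cc)
  }

  if (!all(is.na(d$carrier))) {
    dc <- d[!is.na(d$carrier), ]
    z_car <- dc$z[dc$carrier == 1]; z_non <- dc$z[dc$carrier == 0]
    if (length(z_car) >= 3 && length(z_non) >= 3) {
      # sign convention: non-carriers first (the group expected to score higher)
      cmp <- two_sample_compare(z_non, z_car, gate_alpha = cfg$gate_alpha)
      res$noncarrier_vs_carrier <- c(unclass(cmp),
                                     list(mean_noncarrier = mean(z_non),
                                          mean_carrier = mean(z_car)))
    }
  }

  if (all(is.na(d$prior_prob))) {
    warning("all priors are NA; yield test omitted", call. = FALSE)
  } else {
    dp <- d[!is.na(d$prior_prob) & !is.na(d$carrier), ]
    if (nrow(dp) > 0) {
      yt <- expected_yield_test(dp$prior_prob, sum(dp$carrier),
                                mode = cfg$yield_mode)
      alt_mode <- setdiff(c("poisson_binomial", "binomial_mean"), cfg$yield_mode)
      yt2 <- expected_yield_test(dp$prior_prob, sum(dp$carrier), mode = alt_mode)
      res$yield <- unclass(yt)
      res$yield_alt <- unclass(yt2)
    }
  }

  res$enrichment <- percentile_enrichment(d, d$group,
                                          onset_age = d$onset_age %||% NULL)

  if (!is.null(cfg$variants)) {
    vt <- utils::read.table(cfg$variants, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    screened <- d$sample_id[d$group == "case"]
    vt_core <- vt[vt$patient_id %in% screened, , drop = FALSE]
    core <- gene_panel("hboc_core")
    res$core_rate <- unclass(finding_rate(vt_core, core, screened))[
      c("n_screened", "n_with_finding", "rate")]
    act <- gene_panel("actionable")
    res$secondary_rate <- unclass(finding_rate(vt_core, act, screened))[
      c("n_screened", "n_with_finding", "rate")]
  }

  json_path <- file.path(cfg$out_dir, "stats_report.json")
  jsonlite::write_json(res, json_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, na = "null")
  tsv <- data.frame(metric = character(), value = numeric())
  flat <- function(prefix, lst)
    for (k in names(lst)) if (is.numeric(lst[[k]]) && length(lst[[k]]) == 1)
      tsv <<- rbind(tsv, data.frame(metric = paste0(prefix, k), value = lst[[k]]))
  for (sec in setdiff(names(res), "enrichment")) flat(paste0(sec, "."), res[[sec]])
  tsv_path <- file.path(cfg$out_dir, "stats_report.tsv")
  utils::write.table(tsv, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  log_msg("wrote %s", json_path)
  invisible(res)
}

#' Run the coverage-QC arm of the pipeline
#'
#' Reads the depth-track manifest (sample, cohort, path), computes per-sample
#' per-gene gap reports over the configured exon targets, and - when two or
#' more cohorts are present - the per-gene cohort comparison table (gene,
#' gap percentage per cohort, p-value). With a single cohort the comparison
#' is skipped with a notice.
#'
#' @param cfg a [run_config()] with `targets`, `depth_manifest`, `out_dir`.
#' @return invisible list with `reports` (stacked per-sample gap reports) and
#'   `comparison` (per-gene table or NULL).
#' @export
run_coverage <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  targets <- read_targets_bed(cfg$targets)
  man <- utils::read.table(cfg$depth_manifest, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  known <- gene_panel("hboc_core")
  unmatched <- setdiff(unique(targets$gene), known)
  if (length(unmatched) > 0)
    warning("target gene(s) not in the core panel fixture: ",
            paste(unmatched, collapse = ", "), call. = FALSE)
  reports <- do.call(rbind, lapply(seq_len(nrow(man)), function(i) {
    rep_i <- gap_report(read_bedgraph(man$path[i]), targets,
                        gap_threshold = cfg$gap_threshold,
                        review_floor = cfg$review_floor,
                        cov_threshold = cfg$coverage_threshold)
    cbind(sample = man$sample[i], cohort = man$cohort[i], rep_i)
  }))
  rep_path <- file.path(cfg$out_dir, "gap_reports.tsv")
  utils::write.table(reports, rep_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cohorts <- unique(man$cohort)
  comparison <- NULL
  if (length(cohorts) >= 2) {
    a <- reports[reports$cohort == cohorts[1], ]
    b <- reports[reports$cohort == cohorts[2], ]
    comparison <- compare_gap_cohorts(a, b, gene_order = unique(targets$gene),
                                      gate_alpha = cfg$gate_alpha)
    names(comparison)[names(comparison) == "gap_pct_a"] <-
      paste0("gap_pct_", cohorts[1])
    names(comparison)[names(comparison) == "gap_pct_b"] <-
      paste0("gap_pct_", cohorts[2])
    cmp_path <- file.path(cfg$out_dir, "gap_comparison.tsv")
    utils::write.table(comparison, cmp_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    log_msg("wrote %s", cmp_path)
  } else {
    log_msg("single cohort '%s': gap comparison skipped", cohorts[1])
  }
  log_msg("wrote %s", rep_path)
  invisible(list(reports = reports, comparison = comparison))
}
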