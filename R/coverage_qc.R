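#' Construct and validate a per-base depth track
#'
#' A depth track is a set of non-overlapping, sorted, 0-based half-open
#' intervals with an integer read depth, i.e. the content of a bedGraph file.
#' Overlapping or unsorted intervals are an error (never silently merged).
#'
#' @param df data.frame with columns `chrom`, `start`, `end`, `depth`.
#' @return An object of class `depth_track` (validated data.frame).
#' @export
depth_track <- function(df) {
  df <- as.data.frame(df)
  need <- c("chrom", "start", "end", "depth")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop2("depth track lacks column(s): ", paste(miss, collapse = ", "))
  df <- df[, need]
  df$chrom <- as.character(df$chrom)
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  df$depth <- as.integer(df$depth)
  if (any(df$end <= df$start)) stop2("depth intervals must satisfy end > start")
  if (any(df$depth < 0)) stop2("negative depth")
  df <- df[order(df$chrom, df$start), ]
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, ]
    if (nrow(sub) > 1 && any(sub$start[-1] < sub$end[-nrow(sub)]))
      stop2("overlapping depth intervals on ", ch)
  }
  rownames(df) <- NULL
  structure(df, class = c("depth_track", "data.frame"))
}

#' Read a bedGraph depth file
#' @param path bedGraph (or 4-column TSV) path.
#' @return a [depth_track()].
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  depth_track(data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                         start = GenomicRanges::start(gr) - 1L,
                         end = GenomicRanges::end(gr),
                         depth = as.integer(S4Vectors::mcols(gr)$score)))
}

#' Write a depth track as bedGraph
#' @param track a [depth_track()].
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_bedgraph <- function(track, path) {
  gr <- GenomicRanges::GRanges(track$chrom,
                               IRanges::IRanges(track$start + 1L, track$end),
                               score = track$depth)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read gene target regions from BED
#'
#' 4-column BED (0-based half-open) whose name column carries the gene
#' symbol; a gene's target is the union of its intervals.
#'
#' @param path BED path.
#' @return data.frame with `chrom`, `start`, `end`, `gene`.
#' @export
read_targets_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  nm <- S4Vectors::mcols(gr)$name
  if (is.null(nm) || any(is.na(nm)))
    stop2("targets BED must carry a gene symbol in column 4")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             gene = as.character(nm), stringsAsFactors = FALSE)
}

#' Write gene target regions as BED
#' @param targets data.frame with `chrom`, `start`, `end`, `gene`.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_targets_bed <- function(targets, path) {
  gr <- GenomicRanges::GRanges(targets$chrom,
                               IRanges::IRanges(targets$start + 1L, targets$end),
                               name = targets$gene)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

# Per gene: widths of target bases at each depth. Targets are merged
# (union of intervals) per gene before counting; target bases not covered by
# any depth interval count at depth 0. Returns a named list of
# data.frames(depth, width) plus total target_bases as attribute per gene.
gene_depth_widths <- function(track, targets) {
  track <- depth_track(track)
  genes <- unique(targets$gene)
  out <- list()
  for (g in genes) {
    tg <- targets[targets$gene == g, , drop = FALSE]
    if (nrow(tg) == 0 || sum(pmax(tg$end - tg$start, 0)) == 0)
      stop2("empty target region for gene ", g)
    pieces <- list()
    total <- 0L
    for (ch in unique(tg$chrom)) {
      tsub <- tg[tg$chrom == ch, ]
      tir <- IRanges::reduce(IRanges::IRanges(tsub$start + 1L, tsub$end))
      total <- total + sum(IRanges::width(tir))
      dsub <- track[track$chrom == ch, , drop = FALSE]
      if (nrow(dsub) > 0) {
        dir_ <- IRanges::IRanges(dsub$start + 1L, dsub$end)
        ov <- IRanges::findOverlaps(tir, dir_)
        if (length(ov) > 0) {
          w <- IRanges::width(IRanges::pintersect(
            tir[S4Vectors::queryHits(ov)], dir_[S4Vectors::subjectHits(ov)]))
          pieces[[length(pieces) + 1L]] <-
            data.frame(depth = dsub$depth[S4Vectors::subjectHits(ov)], width = w)
        }
      }
    }
    dw <- if (length(pieces) > 0) do.call(rbind, pieces)
          else data.frame(depth = integer(), width = integer())
    uncovered <- total - sum(dw$width)
    if (uncovered > 0)
      dw <- rbind(dw, data.frame(depth = 0L, width = uncovered))
    dw <- stats::aggregate(width ~ depth, dw, sum)
    attr(dw, "target_bases") <- total
    out[[g]] <- dw
  }
  out
}

#' Per-gene sequencing-gap fractions
#'
#' A gap base is a target base with read depth strictly below
#' `gap_threshold`. Target bases not covered by any depth interval count at
#' depth 0 (and are therefore gaps).
#'
#' @param track a [depth_track()] (or coercible data.frame).
#' @param targets gene target regions (`chrom`, `start`, `end`, `gene`).
#' @param gap_threshold depth below which a base is a gap (reads, default 20).
#' @return data.frame per gene: `gene`, `target_bases`, `gap_bases`,
#'   `gap_fraction`.
#' @export
gap_fraction <- function(track, targets, gap_threshold = 20) {
  dws <- gene_depth_widths(track, targets)
  do.call(rbind, lapply(names(dws), function(g) {
    dw <- dws[[g]]
    tot <- attr(dw, "target_bases")
    gap <- sum(dw$width[dw$depth < gap_threshold])
    data.frame(gene = g, target_bases = tot, gap_bases = gap,
               gap_fraction = gap / tot, stringsAsFactors = FALSE)
  }))
}

#' Classify target bases into pass / reviewable / fail depth bands
#'
#' Bands per base: pass (depth >= `gap_threshold`), reviewable
#' (`review_floor` <= depth < `gap_threshold`; gap bases that can still be
#' resolved by visual inspection), fail (depth < `review_floor`; would need
#' re-sequencing). The gene-level verdict is "pass" when there are no gap
#' bases, "reviewable" when every gap base lies in the reviewable band, and
#' "fail" otherwise.
#'
#' @inheritParams gap_fraction
#' @param review_floor lower bound of the reviewable band (reads, default 15).
#' @return data.frame per gene: `gene`, `target_bases`, `pass_bases`,
#'   `reviewable_bases`, `fail_bases`, `verdict`.
#' @export
classify_bands <- function(track, targets, review_floor = 15, gap_threshold = 20) {
  if (!(review_floor < gap_threshold))
    stop2("review_floor must be strictly below gap_threshold")
  dws <- gene_depth_widths(track, targets)
  do.call(rbind, lapply(names(dws), function(g) {
    dw <- dws[[g]]
    tot <- attr(dw, "target_bases")
    pass <- sum(dw$width[dw$depth >= gap_threshold])
    rev_ <- sum(dw$width[dw$depth >= review_floor & dw$depth < gap_threshold])
    fail <- sum(dw$width[dw$depth < review_floor])
    verdict <- if (pass == tot) "pass" else if (fail == 0) "reviewable" else "fail"
    data.frame(gene = g, target_bases = tot, pass_bases = pass,
               reviewable_bases = rev_, fail_bases = fail, verdict = verdict,
               stringsAsFactors = FALSE)
  }))
}

#' Fraction of target bases at or above a depth threshold
#'
#' Complement of the gap fraction at the same threshold:
#' `coverage_at(t) = 1 - gap_fraction(t)` per gene, exactly.
#'
#' @inheritParams gap_fraction
#' @param t inclusive depth threshold (reads, default 30).
#' @return data.frame per gene: `gene`, `target_bases`, `frac_ge_t`.
#' @export
coverage_at <- function(track, targets, t = 30) {
  dws <- gene_depth_widths(track, targets)
  do.call(rbind, lapply(names(dws), function(g) {
    dw <- dws[[g]]
    tot <- attr(dw, "target_bases")
    data.frame(gene = g, target_bases = tot,
               frac_ge_t = sum(dw$width[dw$depth >= t]) / tot,
               stringsAsFactors = FALSE)
  }))
}

#' Full per-sample, per-gene gap report
#'
#' Combines gap counting, reviewable-band counting and threshold coverage
#' into one table.
#'
#' @inheritParams classify_bands
#' @param cov_threshold threshold for the coverage column (default 30).
#' @return data.frame per gene: `gene`, `target_bases`, `gap_bases`,
#'   `reviewable_bases`, `gap_fraction`, `frac_ge_30x`, `verdict`.
#' @export
gap_report <- function(track, targets, gap_threshold = 20, review_floor = 15,
                       cov_threshold = 30) {
  gf <- gap_fraction(track, targets, gap_threshold)
  cb <- classify_bands(track, targets, review_floor, gap_threshold)
  cv <- coverage_at(track, targets, cov_threshold)
  data.frame(gene = gf$gene, target_bases = gf$target_bases,
             gap_bases = gf$gap_bases, reviewable_bases = cb$reviewable_bases,
             gap_fraction = gf$gap_fraction, frac_ge_30x = cv$frac_ge_t,
             verdict = cb$verdict, stringsAsFactors = FALSE)
}

#' Compare per-gene gap fractions between two cohorts
#'
#' For every gene, the per-sample gap fractions of the two cohorts are
#' compared with the normality-gated two-sample test
#' ([two_sample_compare()]); gap fractions are reported as cohort means in
#' percent (or pooled base fractions with `pooled = TRUE`). Genes where the
#' pooled values are constant (e.g. no gaps anywhere) get p = 1 and
#' `test_used = "degenerate"`.
#'
#' @param reports_a,reports_b stacked per-sample gap tables (columns `sample`,
#'   `gene`, `gap_fraction`, and for pooled mode `target_bases`, `gap_bases`),
#'   e.g. rbind-ed [gap_report()] rows with a `sample` column.
#' @param gene_order optional gene ordering for the output.
#' @param gate_alpha normality-gate level for the per-gene test.
#' @param pooled if TRUE report pooled-base percentages instead of cohort
#'   means of per-sample fractions.
#' @return data.frame per gene: `gene`, `gap_pct_a`, `gap_pct_b`, `p_value`,
#'   `test_used`, `n_a`, `n_b`.
#' @export
compare_gap_cohorts <- function(reports_a, reports_b, gene_order = NULL,
                                gate_alpha = 0.05, pooled = FALSE) {
  ga <- unique(reports_a$gene); gb <- unique(reports_b$gene)
  only <- c(setdiff(ga, gb), setdiff(gb, ga))
  if (length(only) > 0)
    stop2("gene(s) present in one cohort only: ", paste(only, collapse = ", "))
  genes <- if (is.null(gene_order)) sort(ga) else intersect(gene_order, ga)
  rows <- lapply(genes, function(g) {
    xa <- reports_a[reports_a$gene == g, ]
    xb <- reports_b[reports_b$gene == g, ]
    if (nrow(xa) < 3 || nrow(xb) < 3)
      stop2("need >= 3 samples per cohort for gene ", g)
    pct <- function(x) if (pooled) 100 * sum(x$gap_bases) / sum(x$target_bases)
                       else 100 * mean(x$gap_fraction)
    if (stats::sd(c(xa$gap_fraction, xb$gap_fraction)) == 0) {
      p <- 1; test <- "degenerate"
    } else {
      cmp <- two_sample_compare(xa$gap_fraction, xb$gap_fraction, gate_alpha)
      p <- cmp$p; test <- cmp$test_used
    }
    data.frame(gene = g, gap_pct_a = pct(xa), gap_pct_b = pct(xb),
               p_value = p, test_used = test, n_a = nrow(xa), n_b = nrow(xb),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
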