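#' Construct a polygenic score model
#'
#' A score model is an ordered collection of score variants, each carrying a
#' genomic position, an effect and other allele, a per-allele log-scale weight
#' and (optionally) the effect-allele frequency used for imputation of missing
#' genotypes and for strand resolution of palindromic variants.
#'
#' @param variants data.frame with columns `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `weight` and optionally `eaf`, `rsid`.
#' @param name label for the model.
#' @param build genome build tag; position-based matching requires "GRCh38".
#' @return An object of class `score_model`: the variant data.frame with
#'   `name` and `build` attributes.
#' @export
score_model <- function(variants, name = "unnamed", build = "GRCh38") {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  if (nrow(variants) > 0) {
    if (is.null(variants$eaf))  variants$eaf  <- NA_real_
    if (is.null(variants$rsid)) variants$rsid <- NA_character_
  } else {
    variants <- data.frame(chrom = character(), pos = integer(),
                           effect_allele = character(), other_allele = character(),
                           weight = double(), eaf = double(), rsid = character(),
                           stringsAsFactors = FALSE)
  }
  variants <- variants[, c("chrom", "pos", "effect_allele", "other_allele",
                           "weight", "eaf", "rsid")]
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  variants$weight <- as.numeric(variants$weight)
  variants$eaf <- as.numeric(variants$eaf)
  obj <- structure(variants, class = c("score_model", "data.frame"),
                   name = name, build = build)
  validate_score_model(obj)
  obj
}

#' Validate a score model
#'
#' Checks the invariants every score model must satisfy: alleles over
#' \{A,C,G,T\} and unequal, finite weights, frequencies within \[0,1\], and a
#' unique (chrom, pos, effect, other) key per variant.
#'
#' @param x a `score_model`.
#' @return `x` invisibly; errors describe the first offending row.
#' @export
validate_score_model <- function(x) {
  v <- as.data.frame(x)
  if (nrow(v) == 0) return(invisible(x))
  bad_allele <- !grepl("^[ACGT]+$", v$effect_allele) | !grepl("^[ACGT]+$", v$other_allele)
  if (any(bad_allele))
    stop2("invalid allele string on row ", which(bad_allele)[1])
  same <- v$effect_allele == v$other_allele
  if (any(same))
    stop2("effect and other allele identical on row ", which(same)[1])
  if (any(!is.finite(v$weight)))
    stop2("non-finite weight on row ", which(!is.finite(v$weight))[1])
  bad_eaf <- !is.na(v$eaf) & (v$eaf < 0 | v$eaf > 1)
  if (any(bad_eaf))
    stop2("effect-allele frequency outside [0,1] on row ", which(bad_eaf)[1])
  if (any(is.na(v$pos)) || any(v$pos < 1))
    stop2("positions must be positive 1-based integers")
  key <- paste(v$chrom, v$pos, v$effect_allele, v$other_allele)
  if (anyDuplicated(key))
    stop2("duplicate variant key on row ", which(duplicated(key))[1],
          ": ", key[which(duplicated(key))[1]])
  invisible(x)
}

#' @export
print.score_model <- function(x, ...) {
  cat(sprintf("<score_model> %s: %d variant(s), build %s\n",
              attr(x, "name"), nrow(x), attr(x, "build")))
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ...", nrow(x) - 6, "more\n")
  invisible(x)
}

# required columns of the PGS-Catalog harmonized dialect
.score_cols_required <- c("chr_name", "chr_position", "effect_allele",
                          "other_allele", "effect_weight")

#' Read a PGS-Catalog-style scoring file
#'
#' Tab-separated scoring file: header comment lines starting `#` hold
#' `key=value` metadata (notably `genome_build`), followed by a column header
#' and one data row per variant. Required columns: `chr_name`, `chr_position`,
#' `effect_allele`, `other_allele`, `effect_weight`; optional:
#' `effect_allele_frequency`, `rsID`. Positions are 1-based.
#'
#' Models tagged with a build other than GRCh38 are rejected: lift the file to
#' GRCh38 first (e.g. with the UCSC liftOver tool); rsID-based matching in
#' [overlap_models()] is the fallback for cross-build comparison.
#'
#' @param path scoring file path.
#' @return a [score_model()].
#' @export
read_score_file <- function(path) {
  if (!file.exists(path)) stop2("scoring file not found: ", path)
  lines <- readLines(path)
  meta_lines <- grep("^#", lines)
  meta <- list()
  for (ml in lines[meta_lines]) {
    kv <- sub("^#+\\s*", "", ml)
    if (grepl("=", kv, fixed = TRUE)) {
      k <- trimws(sub("=.*$", "", kv))
      meta[[k]] <- trimws(sub("^[^=]*=", "", kv))
    }
  }
  body <- lines[setdiff(seq_along(lines), meta_lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0) stop2("scoring file has no header row: ", path)
  tab <- utils::read.table(text = body, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  missing_cols <- setdiff(.score_cols_required, names(tab))
  if (length(missing_cols) > 0)
    stop2("scoring file is missing required column(s): ",
          paste(missing_cols, collapse = ", "))
  build <- meta$genome_build %||% "GRCh38"
  if (!identical(build, "GRCh38"))
    stop2("scoring file is on build '", build, "'; position matching requires ",
          "GRCh38 - pre-lift the file (liftover is out of scope here)")
  n <- nrow(tab)
  if (n == 0)
    return(score_model(data.frame(), name = meta$pgs_name %||% basename(path),
                       build = build))
  pos <- suppressWarnings(as.integer(tab$chr_position))
  if (any(is.na(pos)))
    stop2("non-integer chr_position on row ", which(is.na(pos))[1])
  wt <- suppressWarnings(as.numeric(tab$effect_weight))
  if (any(is.na(wt)))
    stop2("missing or non-numeric effect_weight on row ", which(is.na(wt))[1])
  eaf <- rep(NA_real_, n)
  if ("effect_allele_frequency" %in% names(tab)) {
    raw <- tab$effect_allele_frequency
    eaf <- suppressWarnings(as.numeric(raw))
    eaf[raw %in% c("", "NA", ".")] <- NA_real_
  }
  bad <- !is.na(eaf) & (eaf < 0 | eaf > 1)
  if (any(bad))
    stop2("effect_allele_frequency outside [0,1] on row ", which(bad)[1])
  rsid <- if ("rsID" %in% names(tab)) {
    r <- tab$rsID; r[r %in% c("", "NA", ".")] <- NA_character_; r
  } else NA_character_
  score_model(data.frame(chrom = tab$chr_name, pos = pos,
                         effect_allele = tab$effect_allele,
                         other_allele = tab$other_allele,
                         weight = wt, eaf = eaf, rsid = rsid,
                         stringsAsFactors = FALSE),
              name = meta$pgs_name %||% basename(path), build = build)
}

#' Write a score model as a PGS-Catalog-style scoring file
#'
#' Inverse of [read_score_file()]: a round trip reproduces every field.
#'
#' @param model a [score_model()].
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_score_file <- function(model, path) {
  validate_score_model(model)
  v <- as.data.frame(model)
  hdr <- c(paste0("#pgs_name=", attr(model, "name")),
           paste0("#genome_build=", attr(model, "build")))
  tab <- data.frame(chr_name = v$chrom, chr_position = v$pos,
                    effect_allele = v$effect_allele, other_allele = v$other_allele,
                    effect_weight = sprintf("%.17g", v$weight),
                    effect_allele_frequency = ifelse(is.na(v$eaf), "NA",
                                                     sprintf("%.17g", v$eaf)),
                    rsID = ifelse(is.na(v$rsid), "NA", v$rsid),
                    stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(names(tab), collapse = "\t"), con)
  if (nrow(tab) > 0)
    writeLines(do.call(paste, c(unname(tab), sep = "\t")), con)
  invisible(path)
}

#' Match a score variant against an observed genotype record
#'
#' Determines how the effect allele of a score-model variant maps onto the
#' REF/ALT alleles of an observed (biallelic, decomposed) genotype record at
#' the same position. Possible statuses:
#' \describe{
#'   \item{exact}{effect = ALT, other = REF; effect dosage = ALT dosage.}
#'   \item{swap}{effect = REF, other = ALT; effect dosage = 2 - ALT dosage.}
#'   \item{flip}{alleles match after reverse-complement (opposite strand),
#'     effect aligned with ALT; identity transform.}
#'   \item{flip_swap}{reverse-complement match with effect aligned to REF;
#'     complement transform.}
#'   \item{ambiguous}{palindromic (A/T or C/G) variant whose strand cannot be
#'     resolved by the frequency rule; carries no transform and is treated as
#'     missing downstream.}
#'   \item{mismatch}{same position but irreconcilable alleles.}
#' }
#' Palindromic variants are resolved by frequency concordance: when
#' `|eaf - 0.5| > af_margin` and an observed ALT frequency is available, the
#' orientation whose expected ALT frequency is closer to the observed one is
#' chosen; otherwise the variant is ambiguous. Indels are matched by exact
#' allele-string equality only (strand flips are ill-defined for indels).
#'
#' @param sv list or one-row data.frame with `chrom`, `pos`, `effect_allele`,
#'   `other_allele` and optionally `eaf`.
#' @param observed list with `chrom`, `pos`, `ref`, `alt` and optionally `af`
#'   (observed ALT-allele frequency).
#' @param af_margin half-width of the frequency dead zone around 0.5 inside
#'   which palindromic variants are always ambiguous (default 0.08).
#' @return list with `status` and `transform` ("identity", "complement" or NA).
#' @export
match_variant <- function(sv, observed, af_margin = 0.08) {
  if (norm_chrom(sv$chrom) != norm_chrom(observed$chrom) ||
      as.integer(sv$pos) != as.integer(observed$pos))
    stop2("match_variant: positions differ (",
          sv$chrom, ":", sv$pos, " vs ", observed$chrom, ":", observed$pos, ")")
  eff <- toupper(sv$effect_allele); oth <- toupper(sv$other_allele)
  ref <- toupper(observed$ref);     alt <- toupper(observed$alt)
  res <- function(status, transform = NA_character_)
    list(status = status, transform = transform)
  if (!grepl("^[ACGT]+$", ref) || !grepl("^[ACGT]+$", alt))
    return(res("mismatch"))

  snv <- is_snv(eff, oth) && is_snv(ref, alt)
  if (snv && is_palindromic(eff, oth)) {
    if (!setequal(c(eff, oth), c(ref, alt))) return(res("mismatch"))
    eaf <- if (is.null(sv$eaf)) NA_real_ else as.numeric(sv$eaf)
    obs_af <- if (is.null(observed$af)) NA_real_ else as.numeric(observed$af)
    if (is.na(eaf) || abs(eaf - 0.5) <= af_margin || is.na(obs_af))
      return(res("ambiguous"))
    # expected ALT frequency if the file and the VCF are on the same strand
    f_same <- if (eff == alt) eaf else 1 - eaf
    d_same <- abs(obs_af - f_same)
    d_flip <- abs(obs_af - (1 - f_same))
    if (d_same == d_flip) return(res("ambiguous"))
    effect_is_alt <- if (d_same < d_flip) eff == alt else eff != alt
    if (effect_is_alt) res("exact", "identity") else res("swap", "complement")
  } else if (snv) {
    if (eff == alt && oth == ref) return(res("exact", "identity"))
    if (eff == ref && oth == alt) return(res("swap", "complement"))
    if (revcomp(eff) == alt && revcomp(oth) == ref) return(res("flip", "identity"))
    if (revcomp(eff) == ref && revcomp(oth) == alt) return(res("flip_swap", "complement"))
    res("mismatch")
  } else {
    # indel: exact string equality only
    if (eff == alt && oth == ref) return(res("exact", "identity"))
    if (eff == ref && oth == alt) return(res("swap", "complement"))
    res("mismatch")
  }
}

#' Count variants shared between two score models
#'
#' Variants are shared when they agree on rsID, or - when either rsID is
#' absent - when they sit at the same (chrom, pos) with reconcilable alleles
#' (identical, swapped, or reverse-complemented; indels by string equality).
#' Each variant is matched at most once; the count is symmetric.
#'
#' @param a,b non-empty [score_model()]s.
#' @return list with `n_shared` and `mapping`, a data.frame of paired row
#'   indices (`idx_a`, `idx_b`) and the basis of each match (`by`).
#' @export
overlap_models <- function(a, b) {
  va <- as.data.frame(a); vb <- as.data.frame(b)
  if (nrow(va) == 0 || nrow(vb) == 0)
    stop2("overlap_models requires two non-empty models")
  same_build <- identical(attr(a, "build"), attr(b, "build"))
  have_rsids <- any(!is.na(va$rsid)) && any(!is.na(vb$rsid))
  if (!same_build && !have_rsids)
    stop2("models are on different builds (", attr(a, "build"), " vs ",
          attr(b, "build"), ") and carry no rsIDs to match by")
  used_b <- rep(FALSE, nrow(vb))
  idx_a <- integer(); idx_b <- integer(); by <- character()
  for (i in seq_len(nrow(va))) {
    j_hit <- NA_integer_; basis <- NA_character_
    if (!is.na(va$rsid[i])) {
      js <- which(!used_b & !is.na(vb$rsid) & vb$rsid == va$rsid[i])
      if (length(js) > 0) { j_hit <- js[1]; basis <- "rsid" }
    }
    if (is.na(j_hit) && same_build) {
      js <- which(!used_b & norm_chrom(vb$chrom) == norm_chrom(va$chrom[i]) &
                    vb$pos == va$pos[i])
      for (j in js) {
        m <- match_variant(va[i, ],
                           list(chrom = vb$chrom[j], pos = vb$pos[j],
                                ref = vb$other_allele[j],
                                alt = vb$effect_allele[j]))
        # palindromic same-position/same-allele pairs count as shared loci
        if (m$status %in% c("exact", "swap", "flip", "flip_swap") ||
            (m$status == "ambiguous" &&
             setequal(c(va$effect_allele[i], va$other_allele[i]),
                      c(vb$effect_allele[j], vb$other_allele[j])))) {
          j_hit <- j; basis <- "position"; break
        }
      }
    }
    if (!is.na(j_hit)) {
      used_b[j_hit] <- TRUE
      idx_a <- c(idx_a, i); idx_b <- c(idx_b, j_hit); by <- c(by, basis)
    }
  }
  list(n_shared = length(idx_a),
       mapping = data.frame(idx_a = idx_a, idx_b = idx_b, by = by,
                            stringsAsFactors = FALSE))
}
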