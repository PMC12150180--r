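`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom withr with_seed
NULL

# reverse-complement of an allele string; indels pass through unchanged by callers
revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(strsplit(x, ""), function(b) paste(rev(unname(comp[b])), collapse = ""),
         character(1))
}

is_snv <- function(a, b) nchar(a) == 1L && nchar(b) == 1L

# palindromic = A/T or C/G single-nucleotide pair (strand-ambiguous)
is_palindromic <- function(effect, other) {
  is_snv(effect, other) && identical(unname(revcomp(effect)), other)
}

# strip an optional "chr" prefix so chr17 and 17 compare equal
norm_chrom <- function(x) sub("^chr", "", as.character(x), ignore.case = TRUE)

stop2 <- function(...) stop(..., call. = FALSE)

assert_that <- function(ok, ...) if (!isTRUE(ok)) stop2(...)
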