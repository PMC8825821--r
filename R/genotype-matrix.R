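#' Reference genotype panel
#'
#' A `genotype_matrix` holds diploid genotype classes for a panel of candidate
#' samples at a set of SNPs. Calls are one of `"AA"` (non-mutant homozygote),
#' `"AB"` (heterozygote), `"BB"` (mutant homozygote) or `NA` (missing). The
#' per-SNP minor-allele frequency (MAF) is computed from the calls and kept in
#' the `"maf"` attribute, folded so it never exceeds 0.5.
#'
#' @param calls Character matrix of genotype classes, samples in rows and SNPs
#'   in columns, with unique `rownames` (sample ids) and `colnames` (SNP ids,
#'   conventionally `chrom:pos:ref:alt` with 1-based positions).
#'
#' @return An object of class `genotype_matrix`: the call matrix with a `maf`
#'   attribute (named numeric vector, one entry per SNP).
#' @examples
#' calls <- matrix(c("AA", "AB", "AB", "BB"), 2, 2,
#'                 dimnames = list(c("s1", "s2"), c("chr1:100:A:G", "chr1:200:C:T")))
#' gm <- genotype_matrix(calls)
#' maf(gm)
#' @export
genotype_matrix <- function(calls) {
  if (!is.matrix(calls) || !is.character(calls)) {
    abort("`calls` must be a character matrix (samples x SNPs).")
  }
  if (is.null(rownames(calls)) || is.null(colnames(calls))) {
    abort("`calls` must have sample ids as rownames and SNP ids as colnames.")
  }
  if (anyDuplicated(rownames(calls))) abort("Duplicate sample ids in genotype matrix.")
  if (anyDuplicated(colnames(calls))) abort("Duplicate SNP ids in genotype matrix.")
  bad <- !is.na(calls) & !calls %in% GENO_CLASSES
  if (any(bad)) {
    abort(sprintf("Invalid genotype call(s): %s",
                  paste(unique(calls[bad]), collapse = ", ")))
  }
  structure(calls, maf = compute_maf(calls), class = c("genotype_matrix", "matrix"))
}

#' Per-SNP minor-allele frequency from genotype calls
#'
#' MAF is the mutant-allele frequency `(2*#BB + #AB) / (2*#non-missing)`,
#' folded to the minor allele so the result is always in `[0, 0.5]`. SNPs with
#' no non-missing call get `NA`.
#'
#' @param calls Character matrix of genotype classes (samples x SNPs).
#' @return Named numeric vector, one MAF per SNP.
#' @export
compute_maf <- function(calls) {
  apply(calls, 2, function(g) {
    n <- sum(!is.na(g))
    if (n == 0) return(NA_real_)
    p <- (2 * sum(g == "BB", na.rm = TRUE) + sum(g == "AB", na.rm = TRUE)) / (2 * n)
    min(p, 1 - p)
  })
}

#' @rdname genotype_matrix
#' @param x A `genotype_matrix`.
#' @export
maf <- function(x) {
  stopifnot(inherits(x, "genotype_matrix"))
  attr(x, "maf")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d SNPs\n", nrow(x), ncol(x)))
  counts <- table(factor(x, levels = GENO_CLASSES), useNA = "ifany")
  cat("  calls:", paste(sprintf("%s=%d", names(counts), counts), collapse = " "), "\n")
  cat(sprintf("  MAF: median %.3f [%.3f, %.3f]\n",
              median(maf(x), na.rm = TRUE),
              min(maf(x), na.rm = TRUE), max(maf(x), na.rm = TRUE)))
  invisible(x)
}

#' @export
as_tibble.genotype_matrix <- function(x, ...) {
  tibble::tibble(
    sample_id = rep(rownames(x), times = ncol(x)),
    snp_id = rep(colnames(x), each = nrow(x)),
    call = as.vector(unclass(x))
  )
}

#' @export
tidy.genotype_matrix <- function(x, ...) {
  tibble::as_tibble(x)
}

# Integer dosage encoding (AA=0, AB=1, BB=2, NA preserved); used by the
# scoring and simulation hot paths.
geno_to_int <- function(calls) {
  m <- matrix(match(calls, GENO_CLASSES) - 1L, nrow(calls), ncol(calls),
              dimnames = dimnames(calls))
  m
}

int_to_geno <- function(m) {
  out <- matrix(GENO_CLASSES[m + 1L], nrow(m), ncol(m), dimnames = dimnames(m))
  out
}

#' Read a genotype panel from a TSV matrix
#'
#' Expects a tab-delimited file with SNP ids in the first column header
#' `snp_id` and one column per sample; cells are `AA`/`AB`/`BB`, with `.` or
#' empty for missing. (The transpose of the in-memory layout: SNPs in rows
#' travel better in text files.)
#'
#' @param path File path.
#' @return A [genotype_matrix()].
#' @export
read_genotype_tsv <- function(path) {
  tb <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (names(tb)[1] != "snp_id") abort("First column of a genotype TSV must be `snp_id`.")
  snps <- tb$snp_id
  m <- t(as.matrix(tb[, -1, drop = FALSE]))
  m[m %in% c(".", "")] <- NA_character_
  colnames(m) <- snps
  genotype_matrix(m)
}

#' Write a genotype panel to a TSV matrix
#'
#' Inverse of [read_genotype_tsv()]; missing calls are written as `.`.
#'
#' @param x A [genotype_matrix()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_genotype_tsv <- function(x, path) {
  stopifnot(inherits(x, "genotype_matrix"))
  m <- t(unclass(x))
  m[is.na(m)] <- "."
  tb <- tibble::as_tibble(m)
  tb <- dplyr::bind_cols(tibble::tibble(snp_id = colnames(x)), tb)
  readr::write_tsv(tb, path, progress = FALSE)
  invisible(path)
}
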