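#' Read a reference genotype panel from a VCF
#'
#' Parses the GT field of a VCF 4.x file into a [genotype_matrix()]. Diploid
#' genotypes are mapped `0/0 -> AA`, `0/1` or `1/0 -> AB`, `1/1 -> BB`,
#' `./. -> NA`; phased separators (`|`) are accepted and treated as unphased.
#' Multi-allelic records (more than one ALT) are skipped with a warning, since
#' a variant peptide keys on a single alternate allele. SNP ids are built as
#' `chrom:pos:ref:alt` with the VCF's 1-based positions.
#'
#' @param path Path to a VCF (plain or bgzipped).
#' @param sample_subset Optional character vector of sample ids to keep; an
#'   error lists any requested sample absent from the file.
#' @return A [genotype_matrix()] (samples x SNPs) with MAF computed from the
#'   retained samples.
#' @export
read_genotype_vcf <- function(path, sample_subset = NULL) {
  if (!file.exists(path)) abort(sprintf("VCF not found: %s", path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    warn(sprintf("Skipping %d multi-allelic VCF record(s).", sum(multi)))
  }
  keep <- !multi
  if (!any(keep)) abort("No bi-allelic records left after filtering the VCF.")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  snp_ids <- paste(fix[, "CHROM"], fix[, "POS"], fix[, "REF"], fix[, "ALT"], sep = ":")

  if (!is.null(sample_subset)) {
    missing <- setdiff(sample_subset, colnames(gt))
    if (length(missing) > 0) {
      abort(sprintf("Sample(s) not in VCF: %s", paste(missing, collapse = ", ")))
    }
    gt <- gt[, sample_subset, drop = FALSE]
  }

  calls <- apply(gt, c(1, 2), gt_to_class)
  calls <- t(calls)
  colnames(calls) <- snp_ids
  genotype_matrix(calls)
}

# "0/1", "1|0", "./." etc. -> genotype class or NA
gt_to_class <- function(gt) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return(NA_character_)
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (length(alleles) != 2 || any(alleles == ".")) return(NA_character_)
  n_alt <- sum(alleles == "1")
  if (!all(alleles %in% c("0", "1"))) return(NA_character_)
  GENO_CLASSES[n_alt + 1L]
}

#' One multiplexed quantification batch
#'
#' A `quant_batch` bundles the variant-peptide reporter-ion intensities of one
#' TMT batch with its channel manifest and SNP annotations.
#'
#' @param batch_id Batch identifier.
#' @param intensities Numeric peptides x channels matrix; `NA` marks a missing
#'   cell, literal 0 is a recorded zero signal. Must be non-negative.
#' @param peptides Tibble with columns `peptide_id`, `snp_id` (may be `NA` for
#'   unannotated rows) and `n_psm`; one row per intensity row.
#' @param manifest Tibble with columns `channel`, `sample_label`, `is_control`
#'   covering every intensity column exactly once.
#' @param scale Intensity scale, `"raw"` (linear), `"log2"` or `"scaled"`
#'   (min-max, in `[0, 1]`). Preprocessing functions track this.
#'
#' @return An object of class `quant_batch`.
#' @export
quant_batch <- function(batch_id, intensities, peptides, manifest, scale = "raw") {
  stopifnot(is.matrix(intensities), is.numeric(intensities))
  if (scale == "raw" && any(intensities < 0, na.rm = TRUE)) {
    abort("Raw intensities must be non-negative.")
  }
  peptides <- tibble::as_tibble(peptides)
  if (!all(c("peptide_id", "snp_id", "n_psm") %in% names(peptides))) {
    abort("`peptides` needs columns peptide_id, snp_id, n_psm.")
  }
  if (nrow(peptides) != nrow(intensities)) {
    abort("`peptides` must have one row per intensity row.")
  }
  manifest <- tibble::as_tibble(manifest)
  if (!all(c("channel", "sample_label", "is_control") %in% names(manifest))) {
    abort("`manifest` needs columns channel, sample_label, is_control.")
  }
  chans <- colnames(intensities) %||% as.character(seq_len(ncol(intensities)))
  colnames(intensities) <- chans
  if (!setequal(manifest$channel, chans) || anyDuplicated(manifest$channel)) {
    abort("Manifest must cover every intensity channel exactly once.")
  }
  manifest <- manifest[match(chans, manifest$channel), ]
  rownames(intensities) <- peptides$peptide_id
  structure(
    list(batch_id = batch_id, intensities = intensities,
         peptides = peptides, manifest = manifest, scale = scale),
    class = "quant_batch"
  )
}

#' @export
print.quant_batch <- function(x, ...) {
  cat(sprintf("<quant_batch> %s: %d peptides x %d channels (%s scale)\n",
              x$batch_id, nrow(x$intensities), ncol(x$intensities), x$scale))
  nc <- sum(x$manifest$is_control)
  cat(sprintf("  channels: %d sample, %d internal control\n",
              ncol(x$intensities) - nc, nc))
  invisible(x)
}

#' @export
as_tibble.quant_batch <- function(x, ...) {
  dplyr::bind_cols(x$peptides, tibble::as_tibble(x$intensities)) |>
    tidyr::pivot_longer(dplyr::all_of(colnames(x$intensities)),
                        names_to = "channel", values_to = "intensity") |>
    dplyr::left_join(x$manifest, by = "channel") |>
    dplyr::mutate(batch = x$batch_id, .before = 1)
}

#' Read a variant-peptide quantification table and its channel manifest
#'
#' The quantification table is a TSV with columns `peptide_id`, `snp_id`,
#' `n_psm` and then one column per TMT channel holding raw reporter-ion
#' intensities. `.` or an empty cell is a missing value; literal `0` is a
#' recorded zero signal and is preserved as such. The manifest is a TSV with
#' columns `batch`, `channel`, `sample_label`, `is_control`; channels whose
#' `is_control` is true (or whose label is `CONTROL`) are flagged as pooled
#' internal-control channels.
#'
#' @param path Quantification table path.
#' @param manifest_path Manifest path.
#' @param batch_id Batch id; defaults to the manifest's `batch` value.
#' @return A [quant_batch()].
#' @export
read_quant_table <- function(path, manifest_path, batch_id = NULL) {
  tb <- readr::read_tsv(path, na = c(".", "", "NA"), progress = FALSE,
                        col_types = readr::cols(
                          peptide_id = readr::col_character(),
                          snp_id = readr::col_character(),
                          n_psm = readr::col_integer(),
                          .default = readr::col_double()
                        ))
  need <- c("peptide_id", "snp_id", "n_psm")
  if (!all(need %in% names(tb))) {
    abort("Quant table must start with columns peptide_id, snp_id, n_psm.")
  }
  chans <- setdiff(names(tb), need)
  intens <- as.matrix(tb[, chans, drop = FALSE])
  neg <- which(intens < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    abort(sprintf("Negative intensity at row %d, channel %s.",
                  neg[1, 1], chans[neg[1, 2]]))
  }
  man <- read_manifest(manifest_path)
  if (is.null(batch_id)) batch_id <- man$batch[1]
  man <- man[man$batch == batch_id, c("channel", "sample_label", "is_control")]
  missing_chan <- setdiff(chans, man$channel)
  if (length(missing_chan) > 0) {
    abort(sprintf("Channel(s) in quant table absent from manifest: %s",
                  paste(missing_chan, collapse = ", ")))
  }
  quant_batch(batch_id, intens, tb[, need], man[match(chans, man$channel), ])
}

#' Read a batch/channel manifest
#'
#' @param path TSV with columns `batch`, `channel`, `sample_label`,
#'   `is_control` (logical, or 0/1; a `sample_label` of `CONTROL` also flags a
#'   control channel).
#' @return Tibble with those columns, `is_control` as logical.
#' @export
read_manifest <- function(path) {
  man <- readr::read_tsv(path, progress = FALSE,
                         col_types = readr::cols(
                           batch = readr::col_character(),
                           channel = readr::col_character(),
                           sample_label = readr::col_character(),
                           is_control = readr::col_logical()
                         ))
  man$is_control <- man$is_control | man$sample_label == "CONTROL"
  man
}

#' Write a quantification table
#'
#' Inverse of [read_quant_table()] for the table part; missing cells become
#' `.`.
#'
#' @param batch A [quant_batch()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(batch, path) {
  tb <- dplyr::bind_cols(batch$peptides, tibble::as_tibble(batch$intensities))
  readr::write_tsv(tb, path, na = ".", progress = FALSE)
  invisible(path)
}

#' Write a sample-matching report
#'
#' Writes one row per proteomic sample with columns `batch`, `channel`,
#' `original_label`, `best_match`, `cscore`, `delta_cscore`, `status`, ordered
#' by batch then channel.
#'
#' @param report A match report tibble from [match_samples()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_match_report <- function(report, path) {
  cols <- c("batch", "channel", "original_label", "best_match",
            "cscore", "delta_cscore", "status")
  missing <- setdiff(cols, names(report))
  if (length(missing) > 0) {
    abort(sprintf("Report is missing column(s): %s", paste(missing, collapse = ", ")))
  }
  report |>
    dplyr::select(dplyr::all_of(cols)) |>
    dplyr::arrange(.data$batch, .data$channel) |>
    readr::write_tsv(path, na = ".", progress = FALSE)
  invisible(path)
}

#' Read back a sample-matching report
#'
#' @param path TSV written by [write_match_report()].
#' @return Tibble with the report columns.
#' @export
read_match_report <- function(path) {
  readr::read_tsv(path, na = ".", progress = FALSE,
                  col_types = readr::cols(
                    batch = readr::col_character(),
                    channel = readr::col_character(),
                    original_label = readr::col_character(),
                    best_match = readr::col_character(),
                    cscore = readr::col_double(),
                    delta_cscore = readr::col_double(),
                    status = readr::col_character()
                  ))
}
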