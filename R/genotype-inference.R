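#' Genotype classes present at a SNP in the reference panel
#'
#' The reference panel's genotype dosages act as prior knowledge for calling:
#' a class never observed in the panel cannot be assigned. Returns the
#' distinct non-missing classes, ordered by mutant dosage (`AA < AB < BB`).
#'
#' @param ref_calls_at_snp Character vector of panel calls at one SNP.
#' @return Character vector, a subset of `c("AA", "AB", "BB")` of length 1-3.
#' @export
dosage_classes <- function(ref_calls_at_snp) {
  cls <- unique(ref_calls_at_snp[!is.na(ref_calls_at_snp)])
  if (length(cls) == 0) abort("All panel calls at this SNP are missing.")
  GENO_CLASSES[GENO_CLASSES %in% cls]
}

#' Call genotypes from scaled intensities by the quartile rule
#'
#' With all three classes possible, the scaled intensities of one peptide are
#' divided at their own 25th and 75th percentiles (linear-interpolation
#' quantiles): values below the lower quartile are called `AA`, values in the
#' closed interquartile range `AB`, and values above the upper quartile `BB`.
#' When the panel shows only two classes at the SNP, the heterozygote
#' ambiguity disappears and a fixed cutoff of 0.5 separates the lower from
#' the higher class (classes ordered `AA < AB < BB`; a value exactly at 0.5
#' goes to the higher class).
#'
#' @param scaled Numeric vector of min-max scaled intensities in `[0, 1]`
#'   (`NA` allowed, propagated).
#' @param classes Classes present in the panel at this SNP, from
#'   [dosage_classes()]; must have length 2 or 3.
#' @return Character vector of calls, same length as `scaled`, with attribute
#'   `rule` (`"quartile3"` or `"binary05"`).
#' @examples
#' infer_genotypes_quartile(c(0.1, 0.2, 0.3, 0.4), c("AA", "AB", "BB"))
#' infer_genotypes_quartile(c(0.2, 0.7), c("AA", "BB"))
#' @export
infer_genotypes_quartile <- function(scaled, classes) {
  stopifnot(all(classes %in% GENO_CLASSES))
  if (length(classes) == 1) abort("Monomorphic SNPs are excluded from inference.")
  if (any(scaled < 0 | scaled > 1, na.rm = TRUE)) {
    abort("Scaled values must lie in [0, 1].")
  }
  if (length(classes) == 3) {
    q <- quantile(scaled, c(0.25, 0.75), na.rm = TRUE, names = FALSE, type = 7)
    calls <- dplyr::case_when(
      is.na(scaled) ~ NA_character_,
      scaled < q[1] ~ "AA",
      scaled > q[2] ~ "BB",
      .default = "AB"
    )
    attr(calls, "rule") <- "quartile3"
  } else {
    classes <- GENO_CLASSES[GENO_CLASSES %in% classes]
    calls <- dplyr::case_when(
      is.na(scaled) ~ NA_character_,
      scaled < 0.5 ~ classes[1],
      .default = classes[2]
    )
    attr(calls, "rule") <- "binary05"
  }
  calls
}

#' Aggregate per-peptide calls covering the same SNP
#'
#' When several variant peptides quantify one SNP, the per-channel call is the
#' majority vote across peptides; ties (including 1-1) yield a missing call.
#'
#' @param per_peptide_calls List of equal-length character call vectors.
#' @return A single character call vector.
#' @export
aggregate_snp_calls <- function(per_peptide_calls) {
  stopifnot(length(per_peptide_calls) >= 1)
  if (length(per_peptide_calls) == 1) {
    out <- per_peptide_calls[[1]]
    attributes(out) <- NULL
    return(out)
  }
  m <- do.call(rbind, per_peptide_calls)
  apply(m, 2, function(votes) {
    votes <- votes[!is.na(votes)]
    if (length(votes) == 0) return(NA_character_)
    tab <- table(votes)
    winners <- names(tab)[tab == max(tab)]
    if (length(winners) > 1) NA_character_ else winners
  })
}

#' Infer per-channel genotypes for a whole batch
#'
#' For every filtered, scaled variant peptide: look up which genotype classes
#' the reference panel shows at its SNP ([dosage_classes()]), call each
#' channel with [infer_genotypes_quartile()], then combine peptides covering
#' the same SNP by majority vote ([aggregate_snp_calls()]). SNPs that are
#' monomorphic in the panel are skipped (they cannot discriminate samples).
#'
#' @param batch A [quant_batch()] on the scaled scale (see [scale_batch()]).
#' @param genotypes Reference [genotype_matrix()].
#' @return A tibble of class `inferred_genotypes` with one row per channel x
#'   SNP call: columns `batch`, `channel`, `original_label`, `is_control`,
#'   `snp_id`, `call`, `rule`, `n_peptides`. Calls that aggregated to missing
#'   are kept as `NA` rows (they still count as "no evidence" in scoring).
#' @export
infer_batch <- function(batch, genotypes) {
  stopifnot(inherits(batch, "quant_batch"), inherits(genotypes, "genotype_matrix"))
  if (batch$scale != "scaled") abort("Batch must be min-max scaled (see scale_batch()).")
  snps <- intersect(unique(batch$peptides$snp_id), colnames(genotypes))
  if (nrow(batch$intensities) == 0 || length(snps) == 0) {
    warn(sprintf("Batch %s: nothing to infer.", batch$batch_id))
    return(empty_inferred())
  }

  per_snp <- purrr::map(snps, function(s) {
    cls <- dosage_classes(unclass(genotypes)[, s])
    if (length(cls) < 2) return(NULL)  # monomorphic in panel
    rows <- which(batch$peptides$snp_id == s)
    calls_list <- purrr::map(rows, function(r) {
      infer_genotypes_quartile(batch$intensities[r, ], cls)
    })
    rule <- attr(calls_list[[1]], "rule")
    tibble::tibble(
      channel = colnames(batch$intensities),
      snp_id = s,
      call = aggregate_snp_calls(calls_list),
      rule = rule,
      n_peptides = length(rows)
    )
  })
  skipped <- sum(purrr::map_lgl(per_snp, is.null))
  if (skipped > 0) {
    inform(sprintf("Batch %s: skipped %d SNP(s) monomorphic in the panel.",
                   batch$batch_id, skipped))
  }
  out <- dplyr::bind_rows(per_snp)
  if (nrow(out) == 0) {
    warn(sprintf("Batch %s: nothing to infer.", batch$batch_id))
    return(empty_inferred())
  }
  out <- out |>
    dplyr::left_join(
      batch$manifest |> dplyr::rename(original_label = "sample_label"),
      by = "channel"
    ) |>
    dplyr::mutate(batch = batch$batch_id) |>
    dplyr::select("batch", "channel", "original_label", "is_control",
                  "snp_id", "call", "rule", "n_peptides")
  n_geno <- sum(!is.na(out$call) & !out$is_control)
  inform(sprintf("Batch %s: inferred %d genotypes across %d SNP(s).",
                 batch$batch_id, n_geno, dplyr::n_distinct(out$snp_id)))
  class(out) <- c("inferred_genotypes", class(out))
  out
}

empty_inferred <- function() {
  out <- tibble::tibble(batch = character(), channel = character(),
                        original_label = character(), is_control = logical(),
                        snp_id = character(), call = character(),
                        rule = character(), n_peptides = integer())
  class(out) <- c("inferred_genotypes", class(out))
  out
}
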