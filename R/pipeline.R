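#' Run the full sample-matching workflow
#'
#' Executes, per batch: preprocessing (optional isotope-impurity correction,
#' trimmed-median loading normalization, log2 with zero flooring), the
#' two-component mixture fit on per-peptide minimum signals, noise/S-N/MAF
#' peptide filtering, min-max scaling, quartile genotype inference, and
#' finally concordance matching of every channel against the full reference
#' panel. With `cutoff_scope = "global"` the mixture is fit once on the
#' pooled minimum signals of all batches and the same cutoff reused
#' everywhere; `"per_batch"` refits per batch.
#'
#' @param batches A [quant_batch()] or list of them, raw scale.
#' @param genotypes Reference [genotype_matrix()].
#' @param score_cfg A [score_config()].
#' @param filter_cfg A [filter_config()].
#' @param impurity Optional impurity matrix passed to
#'   [correct_isotope_impurity()].
#' @param trim_fraction Trim fraction for loading normalization.
#' @param cutoff_scope `"per_batch"` (default) or `"global"`.
#' @param include_controls Include control channels in min-max scaling.
#' @return A `match_report` tibble covering all batches (see
#'   [match_samples()]), with the fitted mixture(s) in the `"mixture_fits"`
#'   attribute.
#' @export
run_match <- function(batches, genotypes, score_cfg = score_config(),
                      filter_cfg = filter_config(), impurity = NULL,
                      trim_fraction = 0.1,
                      cutoff_scope = c("per_batch", "global"),
                      include_controls = TRUE) {
  cutoff_scope <- match.arg(cutoff_scope)
  if (inherits(batches, "quant_batch")) batches <- list(batches)
  stopifnot(length(batches) >= 1)

  prepped <- purrr::map(batches, preprocess_batch,
                        impurity = impurity, trim_fraction = trim_fraction)

  fits <- if (cutoff_scope == "global") {
    pooled <- unlist(purrr::map(prepped, peptide_min_signal))
    fit <- fit_two_gaussian_em(pooled, max_iter = filter_cfg$em_max_iter,
                               tol = filter_cfg$em_tol)
    rep(list(fit), length(prepped))
  } else {
    purrr::map(prepped, function(b) {
      fit_two_gaussian_em(peptide_min_signal(b),
                          max_iter = filter_cfg$em_max_iter,
                          tol = filter_cfg$em_tol)
    })
  }

  inferred <- purrr::map2(prepped, fits, function(b, fit) {
    b |>
      filter_peptides(genotypes, fit, filter_cfg) |>
      scale_batch(include_controls = include_controls) |>
      infer_batch(genotypes)
  }) |>
    dplyr::bind_rows()

  report <- match_samples(inferred, genotypes, score_cfg)
  attr(report, "mixture_fits") <- fits
  report
}
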