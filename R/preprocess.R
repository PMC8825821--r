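#' Correct reporter-ion isotope impurity
#'
#' Each isobaric labeling reagent leaks a known fraction of its signal into
#' neighbouring mass channels (for example, the 126 reagent produces 91.8%,
#' 7.9% and 0.3% of 126, 127 and 128 m/z ions). Given the reagent impurity
#' matrix `P` with `P[i, j]` the fraction of channel `i`'s signal observed in
#' channel `j`, the observed row `o` of each peptide satisfies `t %*% P = o`;
#' this solves for the true row `t`. Negative solutions (possible with noisy
#' data) are clamped to zero with a warning.
#'
#' @param raw Numeric peptides x channels matrix of observed intensities.
#' @param impurity Square channels x channels impurity matrix; rows must sum
#'   to at most 1 and the matrix must be invertible.
#' @return Corrected matrix, same shape as `raw`.
#' @examples
#' imp <- matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2, byrow = TRUE)
#' correct_isotope_impurity(matrix(c(9.5, 0.5), 1, 2), imp)  # -> (10, 0)
#' @export
correct_isotope_impurity <- function(raw, impurity) {
  stopifnot(is.matrix(raw), is.matrix(impurity),
            nrow(impurity) == ncol(impurity), ncol(raw) == nrow(impurity))
  if (any(impurity < 0 | impurity > 1)) abort("Impurity entries must be in [0, 1].")
  if (any(rowSums(impurity) > 1 + 1e-8)) abort("Impurity rows must sum to <= 1.")
  det_ok <- tryCatch(abs(det(impurity)) > .Machine$double.eps^0.5,
                     error = function(e) FALSE)
  if (!det_ok) abort("Impurity matrix is singular; cannot correct.")
  # t(solve(P)) applied to each observed row: T = O %*% P^{-1}
  corrected <- raw %*% solve(impurity)
  # round-off can leave negligible negatives; only material ones get a warning
  tol <- 1e-8 * max(abs(corrected), 1, na.rm = TRUE)
  material <- sum(corrected < -tol, na.rm = TRUE)
  if (material > 0) {
    warn(sprintf("Clamped %d negative corrected intensity cell(s) to 0.", material))
  }
  corrected[!is.na(corrected) & corrected < 0] <- 0
  dimnames(corrected) <- dimnames(raw)
  corrected
}

#' Remove sample loading bias by trimmed-median normalization
#'
#' Rescales each channel multiplicatively so that its trimmed median matches
#' the grand trimmed median across channels, removing differences in total
#' material loaded per channel while preserving within-channel ratios. The
#' operation is idempotent.
#'
#' @param mat Numeric peptides x channels matrix, strictly positive where
#'   present (raw linear scale).
#' @param trim_fraction Fraction trimmed from each tail before taking the
#'   median (the median is trim-insensitive itself; trimming matters when
#'   missingness is asymmetric). Default 0.1.
#' @return Normalized matrix with a `"loading_factors"` attribute holding the
#'   per-channel multipliers.
#' @export
normalize_loading <- function(mat, trim_fraction = 0.1) {
  stopifnot(is.matrix(mat), trim_fraction >= 0, trim_fraction < 0.5)
  if (any(mat <= 0, na.rm = TRUE)) abort("Loading normalization needs strictly positive intensities.")
  ch_med <- apply(mat, 2, trimmed_median, trim = trim_fraction)
  if (any(!is.finite(ch_med))) {
    abort(sprintf("Channel(s) with no usable values: %s",
                  paste(colnames(mat)[!is.finite(ch_med)], collapse = ", ")))
  }
  target <- trimmed_median(ch_med, trim = 0)
  factors <- target / ch_med
  out <- sweep(mat, 2, factors, `*`)
  attr(out, "loading_factors") <- setNames(factors, colnames(mat))
  out
}

trimmed_median <- function(x, trim) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n == 0) return(NA_real_)
  k <- floor(n * trim)
  if (2 * k >= n) return(median(x))
  median(x[(k + 1):(n - k)])
}

#' Summarize PSM-level intensities to peptides
#'
#' Peptide intensity is the per-channel arithmetic mean of its PSM rows,
#' ignoring missing cells (a channel missing in one PSM is averaged over the
#' remaining PSMs).
#'
#' @param psm_matrix Numeric PSMs x channels matrix.
#' @param psm_to_peptide Character vector mapping each PSM row to a peptide id.
#' @return Peptides x channels matrix, rows ordered by first appearance.
#' @export
summarize_peptides <- function(psm_matrix, psm_to_peptide) {
  stopifnot(is.matrix(psm_matrix))
  if (length(psm_to_peptide) == 0 || length(psm_to_peptide) != nrow(psm_matrix)) {
    abort("`psm_to_peptide` must map every PSM row to exactly one peptide.")
  }
  peps <- unique(psm_to_peptide)
  out <- t(vapply(peps, function(p) {
    colMeans(psm_matrix[psm_to_peptide == p, , drop = FALSE], na.rm = TRUE)
  }, numeric(ncol(psm_matrix))))
  out[is.nan(out)] <- NA_real_
  rownames(out) <- peps
  colnames(out) <- colnames(psm_matrix)
  out
}

#' Min-max scale one peptide's log2 intensities
#'
#' The scaling `y_i = (x_i - min(x)) / (max(x) - min(x))` maps each channel's
#' log2 intensity onto `[0, 1]`: the weakest channel to 0, the strongest to 1.
#' Genotype calling operates on these scaled values. A constant vector carries
#' no genotype signal; it is returned as all-`NA` with attribute
#' `uninformative = TRUE` and dropped from inference downstream.
#'
#' @param x Numeric vector of log2 intensities for one peptide across
#'   channels; needs at least 2 non-missing values.
#' @return Numeric vector of scaled values in `[0, 1]` (`NA` preserved), with
#'   attribute `uninformative` set when the input is constant.
#' @examples
#' scale_minmax(c(10, 20, 30))  # 0, 0.5, 1
#' @export
scale_minmax <- function(x) {
  ok <- is.finite(x)
  if (sum(ok) < 2) abort("scale_minmax needs at least 2 non-missing values.")
  rng <- range(x[ok])
  if (diff(rng) == 0) {
    out <- rep(NA_real_, length(x))
    names(out) <- names(x)
    attr(out, "uninformative") <- TRUE
    return(out)
  }
  out <- (x - rng[1]) / diff(rng)
  attr(out, "uninformative") <- FALSE
  out
}

#' Log2-transform a batch, floor-imputing zeros
#'
#' Zero intensities are legitimate (a variant peptide can be truly absent from
#' a channel) but have no finite log. Zeros are replaced by the smallest
#' positive intensity in the batch before the log2 transform and flagged in
#' the `"floor_imputed"` attribute; `NA` cells stay `NA`.
#'
#' @param batch A [quant_batch()] on the raw scale.
#' @return The batch with log2 intensities (`scale = "log2"`).
#' @export
log2_transform <- function(batch) {
  stopifnot(inherits(batch, "quant_batch"))
  if (batch$scale != "raw") abort("Batch is not on the raw scale.")
  m <- batch$intensities
  pos_min <- suppressWarnings(min(m[m > 0], na.rm = TRUE))
  if (!is.finite(pos_min)) abort("Batch has no positive intensity.")
  floored <- !is.na(m) & m == 0
  m[floored] <- pos_min
  batch$intensities <- log2(m)
  attr(batch$intensities, "floor_imputed") <- floored
  batch$scale <- "log2"
  batch
}

#' Preprocess a raw quantification batch
#'
#' Runs the fixed preprocessing chain on raw reporter-ion intensities:
#' isotope impurity correction (if an impurity matrix is supplied), trimmed-
#' median loading normalization, log2 transform with zero flooring, and PSM
#' averaging if `psm_to_peptide` groups rows. Min-max scaling is applied later
#' (see [scale_batch()]) after noise filtering, which operates on log2 values.
#'
#' @param batch A [quant_batch()] on the raw scale.
#' @param impurity Optional channels x channels impurity matrix.
#' @param trim_fraction Trim fraction for loading normalization.
#' @return The batch on the log2 scale.
#' @export
preprocess_batch <- function(batch, impurity = NULL, trim_fraction = 0.1) {
  stopifnot(inherits(batch, "quant_batch"))
  if (!is.null(impurity)) {
    batch$intensities <- correct_isotope_impurity(batch$intensities, impurity)
  }
  batch$intensities <- normalize_loading(batch$intensities, trim_fraction)
  log2_transform(batch)
}

#' Min-max scale every peptide of a batch
#'
#' Applies [scale_minmax()] row-wise to a log2-scale batch. Peptides with a
#' constant row (no genotype signal) are dropped with a message. When
#' `include_controls = FALSE`, internal-control channels do not contribute to
#' the per-peptide min/max but are still mapped through the same affine
#' transform.
#'
#' @param batch A [quant_batch()] on the log2 scale.
#' @param include_controls Include internal-control channels in the min/max?
#'   Default `TRUE` (pooled controls sit mid-range and do not distort the
#'   extremes).
#' @return The batch with scaled intensities (`scale = "scaled"`).
#' @export
scale_batch <- function(batch, include_controls = TRUE) {
  stopifnot(inherits(batch, "quant_batch"))
  if (batch$scale != "log2") abort("Batch must be on the log2 scale before scaling.")
  m <- batch$intensities
  use <- if (include_controls) rep(TRUE, ncol(m)) else !batch$manifest$is_control
  scaled <- t(apply(m, 1, function(x) {
    ok <- is.finite(x) & use
    if (sum(ok) < 2) return(rep(NA_real_, length(x)))
    rng <- range(x[ok])
    if (diff(rng) == 0) return(rep(NA_real_, length(x)))
    (x - rng[1]) / diff(rng)
  }))
  dimnames(scaled) <- dimnames(m)
  keep <- rowSums(is.finite(scaled)) >= 2
  if (any(!keep)) {
    inform(sprintf("Dropped %d uninformative (constant or near-empty) peptide(s).",
                   sum(!keep)))
  }
  batch$intensities <- scaled[keep, , drop = FALSE]
  batch$peptides <- batch$peptides[keep, , drop = FALSE]
  batch$scale <- "scaled"
  batch
}
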