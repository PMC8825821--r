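#' Peptide filtering configuration
#'
#' Holds the three filter parameters applied before genotype inference: the
#' noise-cutoff multiplier `k` (cutoff = noise mean + k * noise SD, default
#' 1.5), the minimum signal-to-noise ratio (default 3) and the minimum
#' minor-allele frequency (default 0.01, i.e. MAF > 1%), together with the EM
#' stopping controls.
#'
#' @param cutoff_multiplier Multiplier `k` on the noise SD; must be > 0.
#' @param snr_min Minimum S/N ratio to keep a peptide; must be >= 1.
#' @param maf_min Peptides whose SNP has MAF <= `maf_min` are removed; in
#'   `[0, 0.5]`.
#' @param em_max_iter,em_tol EM iteration cap and log-likelihood tolerance.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(cutoff_multiplier = 1.5, snr_min = 3, maf_min = 0.01,
                          em_max_iter = 500, em_tol = 1e-8) {
  stopifnot(cutoff_multiplier > 0, snr_min >= 1, maf_min >= 0, maf_min <= 0.5)
  structure(list(cutoff_multiplier = cutoff_multiplier, snr_min = snr_min,
                 maf_min = maf_min, em_max_iter = em_max_iter, em_tol = em_tol),
            class = "filter_config")
}

#' Fit a two-component Gaussian mixture by EM
#'
#' Separates noise from signal in a set of log2 intensities (typically the
#' per-peptide minimum signals of a batch, see [peptide_min_signal()]) by
#' fitting `w1 * N(mu1, sd1^2) + w2 * N(mu2, sd2^2)` with
#' expectation-maximization. Initialization is deterministic: the data are
#' split at the sample median and each side's mean, SD and proportion seed a
#' component. If an iteration degenerates, the fit restarts from
#' jittered starting values drawn from `seed`. Components are relabeled so
#' that `noise` is the lower-mean component.
#'
#' @param values Numeric vector; at least 20 finite values with non-zero
#'   variance.
#' @param max_iter Maximum EM iterations.
#' @param tol Convergence tolerance on the log-likelihood change.
#' @param seed Seed for the (rarely needed) jittered restarts.
#' @return Object of class `smap_mixture` with elements `weight`, `mean`,
#'   `sd` (each named `noise`/`signal`), `loglik` (per-iteration trace),
#'   `converged`, `n_iter`, `n`, and the input `values` (for plotting).
#' @examples
#' set.seed(1)
#' x <- c(rnorm(200, 14, 1.4), rnorm(200, 18.2, 1.3))
#' fit <- fit_two_gaussian_em(x)
#' tidy(fit)
#' @export
fit_two_gaussian_em <- function(values, max_iter = 500, tol = 1e-8, seed = NULL) {
  x <- values[is.finite(values)]
  if (length(x) < 20) abort("EM needs at least 20 finite values.")
  if (var(x) == 0) abort("EM input has zero variance.")
  sd_floor <- 1e-3 * diff(range(x))

  init_split <- function(jitter_sd = 0) {
    med <- median(x)
    if (jitter_sd > 0) med <- med + rnorm(1, 0, jitter_sd)
    lo <- x[x <= med]; hi <- x[x > med]
    if (length(hi) < 2) { lo <- x[x < med]; hi <- x[x >= med] }
    list(w = c(length(lo), length(hi)) / length(x),
         mu = c(mean(lo), mean(hi)),
         s = pmax(c(sd(lo), sd(hi)), sd_floor))
  }

  run_em <- function(par) {
    trace <- numeric(0)
    converged <- FALSE
    for (iter in seq_len(max_iter)) {
      d1 <- par$w[1] * dnorm(x, par$mu[1], par$s[1])
      d2 <- par$w[2] * dnorm(x, par$mu[2], par$s[2])
      tot <- d1 + d2
      if (any(tot == 0) || any(!is.finite(tot))) return(NULL)
      ll <- sum(log(tot))
      trace <- c(trace, ll)
      r2 <- d2 / tot
      r1 <- 1 - r2
      n1 <- sum(r1); n2 <- sum(r2)
      if (n1 < 1e-10 || n2 < 1e-10) return(NULL)
      par$mu <- c(sum(r1 * x) / n1, sum(r2 * x) / n2)
      par$s <- pmax(c(sqrt(sum(r1 * (x - par$mu[1])^2) / n1),
                      sqrt(sum(r2 * (x - par$mu[2])^2) / n2)), sd_floor)
      par$w <- c(n1, n2) / length(x)
      if (iter > 1 && abs(trace[iter] - trace[iter - 1]) < tol) {
        converged <- TRUE
        break
      }
    }
    list(par = par, trace = trace, converged = converged)
  }

  fit <- run_em(init_split())
  if (is.null(fit)) {
    restart <- function() run_em(init_split(jitter_sd = sd(x) / 4))
    fit <- if (is.null(seed)) restart() else withr::with_seed(seed, restart())
  }
  if (is.null(fit)) abort("EM degenerated; could not fit a two-component mixture.")

  ord <- order(fit$par$mu)  # noise = lower mean
  structure(
    list(weight = setNames(fit$par$w[ord], c("noise", "signal")),
         mean = setNames(fit$par$mu[ord], c("noise", "signal")),
         sd = setNames(fit$par$s[ord], c("noise", "signal")),
         loglik = fit$trace, converged = fit$converged,
         n_iter = length(fit$trace), n = length(x), values = x),
    class = "smap_mixture"
  )
}

#' @export
print.smap_mixture <- function(x, ...) {
  cat(sprintf("<smap_mixture> n = %d, %s after %d iterations\n", x$n,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  cat(sprintf("  noise : w = %.3f, mean = %.3f, sd = %.3f\n",
              x$weight["noise"], x$mean["noise"], x$sd["noise"]))
  cat(sprintf("  signal: w = %.3f, mean = %.3f, sd = %.3f\n",
              x$weight["signal"], x$mean["signal"], x$sd["signal"]))
  invisible(x)
}

#' @export
tidy.smap_mixture <- function(x, ...) {
  tibble::tibble(component = c("noise", "signal"),
                 weight = unname(x$weight),
                 mean = unname(x$mean),
                 sd = unname(x$sd))
}

#' @export
glance.smap_mixture <- function(x, ...) {
  tibble::tibble(loglik = x$loglik[length(x$loglik)],
                 n_iter = x$n_iter, converged = x$converged, n = x$n)
}

#' @export
autoplot.smap_mixture <- function(object, k = 1.5, bins = 60, ...) {
  cutoff <- derive_noise_cutoff(object, k)
  grid <- tibble::tibble(x = seq(min(object$values), max(object$values),
                                 length.out = 400))
  dens <- grid |>
    dplyr::mutate(
      noise = object$weight["noise"] *
        dnorm(.data$x, object$mean["noise"], object$sd["noise"]),
      signal = object$weight["signal"] *
        dnorm(.data$x, object$mean["signal"], object$sd["signal"])
    ) |>
    tidyr::pivot_longer(c("noise", "signal"),
                        names_to = "component", values_to = "density")
  ggplot2::ggplot(tibble::tibble(x = object$values), ggplot2::aes(.data$x)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey85", colour = "grey60") +
    ggplot2::geom_line(data = dens,
                       ggplot2::aes(y = .data$density, colour = .data$component)) +
    ggplot2::geom_vline(xintercept = cutoff, linetype = 2) +
    ggplot2::labs(x = "minimum log2 intensity", y = "density",
                  colour = NULL,
                  subtitle = sprintf("noise cutoff = %.2f (k = %g)", cutoff, k)) +
    ggplot2::theme_minimal()
}

#' Minimum-signal noise cutoff
#'
#' The minimum log2 intensity regarded as signal: `noise mean + k * noise SD`.
#' With the reference fit (noise mean 14.06, SD 1.39) and the default
#' `k = 1.5` this gives 16.145, i.e. 16.14 at two decimals — which coincides
#' with the signal mean minus 1.5 signal SD in that fit.
#'
#' @param fit A [fit_two_gaussian_em()] result.
#' @param k Multiplier on the noise SD (default 1.5).
#' @return The cutoff, in log2-intensity units.
#' @export
derive_noise_cutoff <- function(fit, k = 1.5) {
  stopifnot(inherits(fit, "smap_mixture"))
  unname(fit$mean["noise"] + k * fit$sd["noise"])
}

#' Per-peptide minimum signal
#'
#' For each variant peptide, the minimum log2 intensity across non-control
#' channels. For a peptide whose SNP segregates in the batch, the weakest
#' channel is expected to be a non-carrier (AA) sample, so the distribution of
#' these minima over peptides exposes the noise floor; it is the input to
#' [fit_two_gaussian_em()].
#'
#' @param batch A [quant_batch()] on the log2 scale.
#' @return Named numeric vector (one value per peptide with at least one
#'   finite non-control intensity; all-missing rows are excluded).
#' @export
peptide_min_signal <- function(batch) {
  stopifnot(inherits(batch, "quant_batch"))
  if (batch$scale != "log2") abort("Batch must be on the log2 scale.")
  m <- batch$intensities[, !batch$manifest$is_control, drop = FALSE]
  mins <- apply(m, 1, function(x) if (any(is.finite(x))) min(x, na.rm = TRUE) else NA_real_)
  mins[is.finite(mins)]
}

#' Signal-to-noise ratio of one peptide
#'
#' The linear-scale mean intensity of channels at or above the noise cutoff
#' divided by the linear-scale mean of channels below it. This contrasts the
#' signal mode (mutant-carrier channels, BB at the top) against the noise mode
#' (non-carrier AA channels). Returns 0 when every value is below the cutoff
#' and `Inf` when every value is at or above it.
#'
#' @param peptide_row Numeric vector of log2 intensities.
#' @param cutoff Noise cutoff on the log2 scale.
#' @return A single non-negative ratio (possibly `Inf`).
#' @examples
#' compute_snr(c(14, 14, 18, 18), 16)  # 2^18 / 2^14 = 16
#' @export
compute_snr <- function(peptide_row, cutoff) {
  x <- peptide_row[is.finite(peptide_row)]
  hi <- x[x >= cutoff]
  lo <- x[x < cutoff]
  if (length(hi) == 0) return(0)
  if (length(lo) == 0) return(Inf)
  mean(2^hi) / mean(2^lo)
}

#' Filter variant peptides by noise, S/N and MAF
#'
#' Applies the three reliability filters before genotype inference, in order:
#' peptides whose SNP id is missing or absent from the reference panel are
#' dropped (`unannotated`), then SNPs with panel MAF <= `maf_min` (`maf`),
#' then peptides whose every non-control channel lies below the noise cutoff
#' (`noise`), then peptides with S/N below `snr_min` (`snr`). Counts removed
#' per criterion are reported and attached as the `"filter_counts"` attribute.
#' The result is a row subset of the input, so the operation is idempotent.
#'
#' @param batch A [quant_batch()] on the log2 scale.
#' @param genotypes Reference [genotype_matrix()] supplying per-SNP MAF.
#' @param fit A [fit_two_gaussian_em()] result for the batch (or a global
#'   one reused across batches).
#' @param cfg A [filter_config()].
#' @return The filtered [quant_batch()].
#' @export
filter_peptides <- function(batch, genotypes, fit, cfg = filter_config()) {
  stopifnot(inherits(batch, "quant_batch"), inherits(genotypes, "genotype_matrix"))
  if (batch$scale != "log2") abort("Batch must be on the log2 scale.")
  cutoff <- derive_noise_cutoff(fit, cfg$cutoff_multiplier)
  snps <- batch$peptides$snp_id
  panel_maf <- maf(genotypes)

  annotated <- !is.na(snps) & snps %in% colnames(genotypes)
  maf_ok <- annotated & !is.na(panel_maf[snps]) & panel_maf[snps] > cfg$maf_min
  noncontrol <- !batch$manifest$is_control
  m <- batch$intensities[, noncontrol, drop = FALSE]
  above <- apply(m, 1, function(x) any(x[is.finite(x)] >= cutoff))
  snr <- apply(m, 1, compute_snr, cutoff = cutoff)
  snr_ok <- snr >= cfg$snr_min

  keep <- maf_ok & above & snr_ok
  counts <- c(input = nrow(m),
              unannotated = sum(!annotated),
              maf = sum(annotated & !maf_ok),
              noise = sum(maf_ok & !above),
              snr = sum(maf_ok & above & !snr_ok),
              kept = sum(keep))
  inform(sprintf(
    "Batch %s: kept %d/%d peptides (removed %d unannotated, %d MAF, %d noise, %d S/N).",
    batch$batch_id, counts["kept"], counts["input"], counts["unannotated"],
    counts["maf"], counts["noise"], counts["snr"]))
  if (!any(keep)) warn(sprintf("Batch %s: no peptide passed filtering.", batch$batch_id))
  batch$intensities <- batch$intensities[keep, , drop = FALSE]
  batch$peptides <- batch$peptides[keep, , drop = FALSE]
  attr(batch, "filter_counts") <- counts
  batch
}
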