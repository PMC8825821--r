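test_that("EM recovers the generating noise/signal parameters", {
  gen <- function(n, seed) {
    withr::with_seed(seed, {
      comp <- rbinom(n, 1, 0.5)
      ifelse(comp == 0, rnorm(n, 14.06, 1.39), rnorm(n, 18.22, 1.29))
    })
  }
  fit <- fit_two_gaussian_em(gen(5000, 31))
  expect_true(fit$converged)
  expect_lt(abs(fit$mean["noise"] - 14.06), 0.15)
  expect_lt(abs(fit$mean["signal"] - 18.22), 0.15)
  expect_lt(abs(fit$weight["noise"] - 0.5), 0.05)
  expect_true(fit$mean["noise"] < fit$mean["signal"])

  # accuracy improves (or stays comparable) from n = 500 to n = 5000
  fit500 <- fit_two_gaussian_em(gen(500, 32))
  err <- function(f) abs(f$mean["noise"] - 14.06) + abs(f$mean["signal"] - 18.22)
  expect_lt(err(fit500), 0.6)
  expect_lt(err(fit), err(fit500) + 0.1)

  td <- tidy(fit)
  expect_equal(td$component, c("noise", "signal"))
  expect_equal(td$mean, unname(fit$mean))
})

test_that("EM log-likelihood is nondecreasing along the trace", {
  x <- withr::with_seed(7, c(rnorm(300, 14, 1.5), rnorm(200, 18, 1.2)))
  fit <- fit_two_gaussian_em(x)
  expect_true(all(diff(fit$loglik) > -1e-8))
})

test_that("EM separates far-apart clusters to per-cluster moments", {
  x <- withr::with_seed(9, c(rnorm(400, 0, 1), rnorm(400, 100, 1)))
  fit <- fit_two_gaussian_em(x)
  expect_lt(abs(fit$mean["noise"] - mean(x[x < 50])), 0.2)
  expect_lt(abs(fit$mean["signal"] - mean(x[x >= 50])), 0.2)
  expect_lt(abs(fit$weight["noise"] - 0.5), 0.05)
})

test_that("EM agrees with an independent mixture fitter", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  x <- withr::with_seed(13, c(rnorm(1500, 14.06, 1.39), rnorm(1500, 18.22, 1.29)))
  fit <- fit_two_gaussian_em(x)
  mc <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(unname(fit$mean), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.02)
})

test_that("EM rejects degenerate input", {
  expect_error(fit_two_gaussian_em(rep(5, 100)), "zero variance")
  expect_error(fit_two_gaussian_em(c(1, 2, 3)), "at least 20")
})

test_that("noise cutoff is noise mean + k * noise SD, linear in k", {
  fit <- fake_mixture()
  expect_equal(derive_noise_cutoff(fit, 1.5), 14.06 + 1.5 * 1.39)  # 16.145
  expect_equal(round(derive_noise_cutoff(fit, 1.5), 2), 16.14)
  # in this fit the signal-side mirror lands nearby: 18.22 - 1.5*1.29 = 16.285
  expect_equal(18.22 - 1.5 * 1.29, 16.285)

  expect_equal(derive_noise_cutoff(fake_mixture(0, 1), 1.5), 1.5)
  expect_equal(derive_noise_cutoff(fit, 0), 14.06)
  ks <- c(0.5, 1, 2, 3)
  expect_equal(vapply(ks, derive_noise_cutoff, numeric(1), fit = fit),
               14.06 + ks * 1.39)
})

test_that("per-peptide minimum signal uses non-control channels only", {
  gm <- tiny_panel(6, 10)
  b <- log2_transform(sim_batch(gm, n_channels = 5, loading_sd = 0))
  b$intensities[, !b$manifest$is_control][1, ] <- c(14, 18, 19, 15, 17)
  b$intensities[2, ] <- NA  # all-missing row excluded
  mins <- peptide_min_signal(b)
  expect_equal(unname(mins["pep_1"]), 14)
  expect_false("pep_2" %in% names(mins))
  expect_length(mins, 9)
})

test_that("S/N is the linear-scale signal/noise mean ratio", {
  expect_equal(compute_snr(c(14, 14, 18, 18), 16), 2^18 / 2^14)  # = 16
  expect_equal(compute_snr(c(10, 11, 12), 16), 0)
  expect_identical(compute_snr(c(17, 18), 16), Inf)
  expect_equal(compute_snr(c(14, 16), 16), 2^16 / 2^14)  # boundary goes to signal
})

test_that("peptide filtering applies MAF, noise and S/N rules and is idempotent", {
  calls <- matrix(
    c("AA", "AA", "AA", "AA", "AA", "AB",   # snp1: MAF 1/12 > 1%
      "AA", "AB", "BB", "AB", "AA", "BB",   # snp2: common
      "AA", "AA", "AA", "AA", "AA", "AA",   # snp3: MAF 0
      "AA", "AB", "AB", "AA", "BB", "AA"),  # snp4: common
    nrow = 6,
    dimnames = list(paste0("s", 1:6), paste0("snp", 1:4))
  )
  gm <- genotype_matrix(calls)
  intens <- rbind(
    pepA = c(14, 14, 18, 18, 14, 14),  # snp2: passes everything
    pepB = c(14, 14, 14, 15, 14, 14),  # snp2: all below cutoff -> noise
    pepC = c(14, 14, 18, 18, 14, 14),  # snp3: MAF 0 -> removed
    pepD = c(16.0, 16.3, 16.5, 16.6, 16.0, 16.4),  # snp4: S/N ~1.4 -> removed
    pepE = c(14, 14, 18, 18, 14, 14)   # unannotated SNP -> removed
  )
  peptides <- tibble::tibble(
    peptide_id = rownames(intens),
    snp_id = c("snp2", "snp2", "snp3", "snp4", "snp9"),
    n_psm = 1L
  )
  manifest <- tibble::tibble(channel = paste0("ch", 1:6),
                             sample_label = paste0("s", 1:6),
                             is_control = FALSE)
  colnames(intens) <- manifest$channel
  b <- quant_batch("b1", intens, peptides, manifest, scale = "log2")

  fit <- fake_mixture()  # cutoff 16.145
  out <- suppressMessages(filter_peptides(b, gm, fit))
  expect_equal(rownames(out$intensities), "pepA")
  counts <- attr(out, "filter_counts")
  expect_equal(unname(counts[c("unannotated", "maf", "noise", "snr", "kept")]),
               c(1, 1, 1, 1, 1))

  # idempotent: filtering the filtered batch changes nothing
  again <- suppressMessages(filter_peptides(out, gm, fit))
  expect_equal(again$intensities, out$intensities)
  expect_equal(again$peptides, out$peptides)

  # relaxing MAF below snp3's frequency is impossible (MAF 0), but pepD
  # survives when the S/N requirement is dropped
  relaxed <- suppressMessages(filter_peptides(b, gm, fit, filter_config(snr_min = 1)))
  expect_true("pepD" %in% rownames(relaxed$intensities))
})
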