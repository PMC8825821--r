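test_that("dosage classes are the distinct non-missing panel classes", {
  expect_equal(dosage_classes(c("AA", "AB", "AA")), c("AA", "AB"))
  expect_equal(dosage_classes(c("AA", "AB", "BB")), c("AA", "AB", "BB"))
  expect_equal(dosage_classes(c("BB", NA, "BB")), "BB")
  expect_equal(dosage_classes(c("BB", "AA")), c("AA", "BB"))  # dosage order
  expect_error(dosage_classes(c(NA_character_, NA)), "missing")
})

test_that("three-class quartile rule uses linear-interpolation quantiles", {
  # Q1 = 0.175, Q3 = 0.325 for these four values
  calls <- infer_genotypes_quartile(c(0.1, 0.2, 0.3, 0.4), c("AA", "AB", "BB"))
  expect_equal(as.vector(calls), c("AA", "AB", "AB", "BB"))
  expect_equal(attr(calls, "rule"), "quartile3")

  # values exactly at a quartile fall in the closed interquartile class
  v <- c(0, 0.25, 0.5, 0.75, 1)  # Q1 = 0.25, Q3 = 0.75 exactly
  calls <- infer_genotypes_quartile(v, c("AA", "AB", "BB"))
  expect_equal(as.vector(calls), c("AA", "AB", "AB", "AB", "BB"))

  # NA propagates
  calls <- infer_genotypes_quartile(c(0.1, NA, 0.9), c("AA", "AB", "BB"))
  expect_true(is.na(calls[2]))
})

test_that("quartile-call proportions are 25/50/25 on equally spaced values", {
  for (n in c(8, 12, 100)) {
    v <- seq(0, 1, length.out = n)
    calls <- infer_genotypes_quartile(v, c("AA", "AB", "BB"))
    expect_equal(as.vector(table(factor(calls, c("AA", "AB", "BB")))),
                 c(n / 4, n / 2, n / 4))
  }
})

test_that("two-class rule splits at 0.5 by dosage order", {
  expect_equal(as.vector(infer_genotypes_quartile(c(0.2, 0.7), c("AA", "BB"))),
               c("AA", "BB"))
  expect_equal(attr(infer_genotypes_quartile(c(0.2, 0.7), c("AA", "BB")), "rule"),
               "binary05")
  # generalized to any two observed classes; 0.5 itself goes high
  expect_equal(as.vector(infer_genotypes_quartile(c(0.4, 0.5, 0.6), c("AA", "AB"))),
               c("AA", "AB", "AB"))
  expect_equal(as.vector(infer_genotypes_quartile(c(0.1, 0.9), c("AB", "BB"))),
               c("AB", "BB"))
  expect_error(infer_genotypes_quartile(c(0.2, 0.7), "BB"), "Monomorphic")
  expect_error(infer_genotypes_quartile(c(0.2, 1.7), c("AA", "BB")), "\\[0, 1\\]")
})

test_that("three-class calls depend only on ranks (monotone-transform invariant)", {
  withr::with_seed(33, {
    for (i in 1:15) {
      x <- rnorm(11)
      sx <- scale_minmax(x)
      base <- infer_genotypes_quartile(sx, c("AA", "AB", "BB"))
      # strictly increasing non-linear transforms of the raw values
      for (f in list(function(z) exp(z), function(z) z^3 + 2 * z)) {
        tx <- scale_minmax(f(x))
        expect_equal(as.vector(infer_genotypes_quartile(tx, c("AA", "AB", "BB"))),
                     as.vector(base))
      }
    }
  })
})

test_that("per-SNP aggregation is majority vote with ties missing", {
  expect_equal(aggregate_snp_calls(list(c("AA", "BB"))), c("AA", "BB"))
  expect_equal(
    aggregate_snp_calls(list(c("AA", "AB"), c("AA", "AB"), c("AB", "AB"))),
    c("AA", "AB")
  )
  expect_true(is.na(aggregate_snp_calls(list("AA", "BB"))))
  # NA votes are ignored, not tie-breaking
  expect_equal(aggregate_snp_calls(list(c("AA"), c(NA_character_))), "AA")
})

test_that("noiseless balanced batch round-trips genotypes exactly", {
  gm <- balanced_panel(n_snps = 40)
  b <- simulate_quant_batch(gm, rownames(gm)[1:11], control = FALSE,
                            noise_sd = 0, signal_sd = 0, loading_sd = 0,
                            seed = 1)
  inferred <- suppressMessages(
    b |> preprocess_batch() |> scale_batch() |> infer_batch(gm)
  )
  truth <- tibble::as_tibble(gm) |>
    dplyr::rename(original_label = "sample_id", truth = "call")
  joined <- dplyr::left_join(inferred, truth, by = c("original_label", "snp_id"))
  expect_gt(nrow(joined), 0)
  expect_equal(joined$call, joined$truth)
})

test_that("empty and monomorphic inputs degrade gracefully", {
  gm <- balanced_panel(n_snps = 10)
  b <- simulate_quant_batch(gm, rownames(gm)[1:11], control = FALSE, seed = 2)
  scaled <- scale_batch(preprocess_batch(b))

  empty <- scaled
  empty$intensities <- empty$intensities[0, , drop = FALSE]
  empty$peptides <- empty$peptides[0, ]
  expect_warning(out <- infer_batch(empty, gm), "nothing to infer")
  expect_equal(nrow(out), 0)

  # a SNP monomorphic in the panel emits no calls
  calls <- unclass(gm)
  calls[, 1] <- "AA"
  gm_mono <- genotype_matrix(calls)
  inferred <- suppressMessages(infer_batch(scaled, gm_mono))
  expect_false(colnames(gm)[1] %in% inferred$snp_id)
  expect_true(colnames(gm)[2] %in% inferred$snp_id)
})
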