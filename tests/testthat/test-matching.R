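cfg1 <- score_config(min_compared = 1)

test_that("fraction-mode Cscore is the fraction of matched genotypes", {
  expect_equal(cscore(c("AA", "AB", "BB", "AA"), c("AA", "AB", "BB", "BB"), cfg1),
               0.75)
  v <- c("AA", "AB", "BB", "AB")
  expect_equal(cscore(v, v, cfg1), 1)
  # comparisons restricted to jointly non-missing positions
  expect_equal(cscore(c("AA", NA, "BB"), c("AA", "AB", "AA"), cfg1), 0.5)
  # too few compared positions -> NA
  expect_true(is.na(cscore(c("AA", NA), c("AA", "AB"),
                           score_config(min_compared = 2))))
})

test_that("weighted-mode Cscore credits matched classes by dosage weight", {
  cfgw <- score_config("weighted", min_compared = 1)
  expect_equal(cscore(c("AA", "AB", "BB"), c("AA", "AB", "BB"), cfgw), 2)
  expect_equal(cscore(c("AA", "AB", "BB"), c("AA", "AB", "AA"), cfgw), 1)  # (1+2)/3
  expect_equal(cscore(c("BB", "BB"), c("BB", "BB"), cfgw), 3)
})

test_that("Cscore equals a brute-force counting oracle on random fixtures", {
  withr::with_seed(17, {
    for (i in 1:25) {
      n_snps <- sample(5:20, 1)
      classes <- c("AA", "AB", "BB", NA)
      a <- sample(classes, n_snps, replace = TRUE)
      b <- sample(classes, n_snps, replace = TRUE)
      expect_identical(cscore(a, b, cfg1), brute_force_cscore(a, b))
    }
  })
})

test_that("delta-Cscore measures top-match specificity", {
  expect_equal(delta_cscore(c(0.9, 0.72, 0.5)), 0.2)
  expect_equal(delta_cscore(c(0.5, 0.5)), 0)
  expect_equal(delta_cscore(0.8), 1)  # single candidate: maximal specificity
  expect_true(is.na(delta_cscore(c(0, 0))))
  expect_true(is.na(delta_cscore(NA_real_)))
})

test_that("delta-Cscore is invariant under positive rescaling of all scores", {
  withr::with_seed(23, {
    for (i in 1:20) {
      s <- runif(sample(2:8, 1))
      c_ <- runif(1, 0.01, 50)
      expect_equal(delta_cscore(c_ * s), delta_cscore(s), tolerance = 1e-12)
    }
  })
})

# Build an inferred_genotypes tibble directly from a call matrix, as if
# inference were perfect, with channel labels possibly permuted.
as_inferred <- function(calls, labels = rownames(calls), batch = "b1") {
  tibble::tibble(
    batch = batch,
    channel = rep(sprintf("ch%02d", seq_len(nrow(calls))), each = ncol(calls)),
    original_label = rep(labels, each = ncol(calls)),
    is_control = FALSE,
    snp_id = rep(colnames(calls), times = nrow(calls)),
    call = as.vector(t(calls)),
    rule = "quartile3",
    n_peptides = 1L
  )
}

test_that("match_samples recovers a known label permutation", {
  gm <- tiny_panel(5, 50, seed = 41)
  perm <- c(2, 3, 1, 5, 4)
  inferred <- as_inferred(unclass(gm), labels = rownames(gm)[perm])
  report <- suppressMessages(match_samples(inferred, gm, score_config()))
  # channel i carries sample i's genotypes but is labeled perm[i]:
  # best match must be the true sample, status corrected where labels moved
  expect_equal(report$best_match, rownames(gm))
  expect_true(all(report$status == "corrected"))
  expect_equal(report$cscore, rep(1, 5))
  # delta = (1 - second)/1 against the strongest impostor, via brute force
  for (i in 1:5) {
    others <- setdiff(seq_len(5), i)
    second <- max(vapply(others, function(j) {
      brute_force_cscore(unclass(gm)[i, ], unclass(gm)[j, ])
    }, numeric(1)))
    expect_equal(report$delta_cscore[i], 1 - second)
    expect_equal(report$cscore_second[i], second)
  }
})

test_that("identity fixture yields all matched; thresholds gate assignment", {
  gm <- tiny_panel(5, 50, seed = 43)
  inferred <- as_inferred(unclass(gm))
  report <- suppressMessages(match_samples(inferred, gm))
  expect_true(all(report$status == "matched"))

  # an absurd Cscore threshold makes everything unassignable
  strict <- score_config(cscore_min = 1.01)
  report2 <- suppressMessages(match_samples(inferred, gm, strict))
  expect_true(all(report2$status == "unassignable"))
})

test_that("duplicated reference samples force delta 0 and unassignable", {
  gm <- tiny_panel(4, 40, seed = 47)
  calls <- unclass(gm)
  calls[2, ] <- calls[1, ]  # two identical candidates
  gm_dup <- genotype_matrix(calls)
  inferred <- as_inferred(calls[1, , drop = FALSE], labels = rownames(calls)[1])
  report <- suppressMessages(match_samples(inferred, gm_dup))
  expect_equal(report$delta_cscore, 0)
  expect_equal(report$status, "unassignable")
})

test_that("control channels are always status control", {
  gm <- tiny_panel(4, 30, seed = 49)
  inferred <- as_inferred(unclass(gm)[1, , drop = FALSE])
  inferred$is_control <- TRUE
  inferred$original_label <- "CONTROL"
  report <- suppressMessages(match_samples(inferred, gm))
  expect_equal(report$status, "control")
})

test_that("swap classification identifies reciprocal, one-way and cyclic", {
  rep_tbl <- function(from, to) {
    tibble::tibble(batch = "b1", channel = sprintf("ch%02d", seq_along(from)),
                   original_label = from, best_match = to,
                   cscore = 0.95, cscore_second = 0.4, delta_cscore = 0.5,
                   status = "corrected")
  }
  recip <- classify_swaps(rep_tbl(c("A", "B"), c("B", "A")))
  expect_equal(recip$components$topology, "reciprocal")
  expect_equal(recip$components$size, 2)

  oneway <- classify_swaps(rep_tbl("A", "B"))
  expect_equal(oneway$components$topology, "one-way")

  cyc <- classify_swaps(rep_tbl(c("A", "B", "C"), c("B", "C", "A")))
  expect_equal(cyc$components$topology, "cyclic")
  expect_equal(cyc$components$size, 3)

  # mixed report decomposes into one component per swap group
  mixed <- classify_swaps(rep_tbl(c("A", "B", "X", "P", "Q", "R"),
                                  c("B", "A", "Y", "Q", "R", "P")))
  expect_equal(sort(mixed$components$topology),
               c("cyclic", "one-way", "reciprocal"))
  expect_equal(sum(mixed$components$size), 6 + 1)  # Y enters as target node
  expect_equal(nrow(mixed$edges), 6)

  none <- classify_swaps(rep_tbl(character(0), character(0)))
  expect_equal(nrow(none$components), 0)
})
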