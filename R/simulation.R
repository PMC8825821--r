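#' Generate a synthetic reference genotype panel
#'
#' Draws a samples x SNPs genotype matrix under Hardy-Weinberg equilibrium:
#' each SNP gets a minor-allele frequency from `maf_range` (uniform), and
#' genotypes are sampled i.i.d. across samples with frequencies
#' `((1-p)^2, 2p(1-p), p^2)`. Defaults mirror the scale used to benchmark
#' identity recovery: 420 samples x 500 SNPs with MAF ~ U(0.05, 0.5).
#'
#' @param n_samples,n_snps Panel dimensions.
#' @param maf_range Range of the uniform MAF distribution.
#' @param seed Optional seed; the global RNG state is left untouched.
#' @return A [genotype_matrix()].
#' @export
generate_genotype_matrix <- function(n_samples = 420, n_snps = 500,
                                     maf_range = c(0.05, 0.5), seed = NULL) {
  stopifnot(n_samples >= 2, n_snps >= 1)
  gen <- function() {
    p <- runif(n_snps, maf_range[1], maf_range[2])
    calls <- vapply(p, function(m) {
      sample(GENO_CLASSES, n_samples, replace = TRUE,
             prob = c((1 - m)^2, 2 * m * (1 - m), m^2))
    }, character(n_samples))
    dimnames(calls) <- list(
      sprintf("S%04d", seq_len(n_samples)),
      sprintf("chr1:%d:A:G", 1000L + seq_len(n_snps))
    )
    calls
  }
  calls <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  genotype_matrix(calls)
}

#' Shuffle a fraction of one sample's genotypes
#'
#' Introduces genotype errors into a single sample by the frequency-preserving
#' shuffle: estimate each SNP's genotype-class frequencies across the whole
#' panel, pick `round(alpha/100 * n_snps)` distinct SNP positions of the
#' chosen sample, and replace each position's call with a draw from that
#' SNP's panel frequencies. Under the default `"frequency"` policy the draw
#' comes from the full class distribution, so a replacement can coincide with
#' the original call and the sample's concordance with its true identity
#' decays towards the panel's baseline concordance rather than to zero. The
#' `"different_class"` policy restricts the draw to classes other than the
#' current call (renormalized), making `alpha` the exact realized error rate:
#' every shuffled position is guaranteed to differ. Positions whose SNP shows
#' a single class in the panel cannot change under that policy and are
#' excluded from selection (the count is made up from the remaining
#' positions when possible).
#'
#' @param gm A [genotype_matrix()].
#' @param sample Sample id (or row index) to shuffle.
#' @param alpha Percentage of SNP positions to shuffle, in `[0, 100]`.
#' @param seed Optional seed; global RNG untouched when supplied.
#' @param policy `"frequency"` (default) or `"different_class"`.
#' @return The panel with that sample's calls modified and MAF recomputed.
#' @export
shuffle_genotypes <- function(gm, sample, alpha, seed = NULL,
                              policy = c("frequency", "different_class")) {
  stopifnot(inherits(gm, "genotype_matrix"), alpha >= 0, alpha <= 100)
  policy <- match.arg(policy)
  calls <- unclass(gm)
  if (is.character(sample)) sample <- match(sample, rownames(calls))
  if (is.na(sample) || sample < 1 || sample > nrow(calls)) abort("Unknown sample.")
  n_snps <- ncol(calls)
  k <- round(alpha / 100 * n_snps)
  if (k == 0) return(gm)

  freqs <- apply(calls, 2, function(g) {
    tabulate(match(g, GENO_CLASSES), 3L)
  })  # 3 x n_snps counts

  do_shuffle <- function() {
    eligible <- seq_len(n_snps)
    if (policy == "different_class") {
      # a position is only shufflable if some other class exists in the panel
      cur <- match(calls[sample, ], GENO_CLASSES)
      other <- vapply(seq_len(n_snps), function(j) {
        f <- freqs[, j]
        if (!is.na(cur[j])) f[cur[j]] <- 0L
        sum(f) > 0L
      }, logical(1))
      eligible <- which(other)
    }
    kk <- min(k, length(eligible))
    pos <- sample(eligible, kk)
    new <- calls[sample, ]
    for (j in pos) {
      f <- freqs[, j]
      if (policy == "different_class") {
        cur <- match(new[j], GENO_CLASSES)
        if (!is.na(cur)) f[cur] <- 0L
      }
      new[j] <- GENO_CLASSES[sample.int(3L, 1L, prob = f)]
    }
    new
  }
  new_row <- if (is.null(seed)) do_shuffle() else withr::with_seed(seed, do_shuffle())
  calls[sample, ] <- new_row
  genotype_matrix(calls)
}

#' Identity-recovery curve under increasing genotype shuffling
#'
#' For each shuffling level `alpha` and replicate: pick one panel sample at
#' random, shuffle `alpha`% of its genotype positions with
#' [shuffle_genotypes()], score the shuffled vector against every candidate
#' in the panel with [cscore()], and record whether the true sample still
#' ranks first. This measures how many reliable genotypes the matching
#' procedure needs before identity recovery breaks down.
#'
#' @param genotypes Optional [genotype_matrix()]; generated with
#'   [generate_genotype_matrix()] defaults when `NULL`.
#' @param alphas Vector of shuffling percentages (default 10-100, step 1).
#' @param reps Replicates per alpha (default 50).
#' @param cfg A [score_config()]; the default fraction mode scores plain
#'   genotype concordance.
#' @param policy Shuffle replacement policy, see [shuffle_genotypes()].
#' @param seed Optional seed for the whole experiment.
#' @param n_samples,n_snps Panel dimensions when `genotypes` is `NULL`.
#' @return A tibble of class `recovery_curve`: one row per alpha x replicate
#'   with `alpha`, `replicate`, `shuffled_sample`, `true_cscore`,
#'   `best_cscore`, `true_rank` (1 + number of strictly better candidates)
#'   and `recovered` (true sample strictly top-ranked).
#' @export
run_recovery_curve <- function(genotypes = NULL, alphas = 10:100, reps = 50,
                               cfg = score_config(), policy = "frequency",
                               seed = NULL, n_samples = 420, n_snps = 500) {
  run <- function() {
    gm <- genotypes %||% generate_genotype_matrix(n_samples, n_snps)
    calls <- unclass(gm)
    code <- geno_to_int(calls)
    n <- nrow(code); m <- ncol(code)
    freqs <- apply(calls, 2, function(g) tabulate(match(g, GENO_CLASSES), 3L))
    w <- unname(cfg$weights[GENO_CLASSES])

    score_all <- function(vec_int) {
      eq <- code == matrix(vec_int, n, m, byrow = TRUE)
      eq[is.na(eq)] <- FALSE
      cmp <- (!is.na(code)) & !is.na(matrix(vec_int, n, m, byrow = TRUE))
      ncmp <- rowSums(cmp)
      sc <- if (cfg$mode == "fraction") {
        rowSums(eq) / ncmp
      } else {
        wv <- matrix(w[vec_int + 1L], n, m, byrow = TRUE)
        rowSums(eq * wv) / ncmp
      }
      sc[ncmp < cfg$min_compared] <- NA_real_
      sc
    }

    shuffle_row <- function(vec_int, alpha) {
      k <- round(alpha / 100 * m)
      if (k == 0) return(vec_int)
      pos <- sample.int(m, k)
      for (j in pos) {
        f <- freqs[, j]
        if (policy == "different_class") {
          if (!is.na(vec_int[j])) f[vec_int[j] + 1L] <- 0L
          if (sum(f) == 0L) next
        }
        vec_int[j] <- sample.int(3L, 1L, prob = f) - 1L
      }
      vec_int
    }

    grid <- tidyr::expand_grid(alpha = alphas, replicate = seq_len(reps))
    res <- purrr::pmap(grid, function(alpha, replicate) {
      i <- sample.int(n, 1)
      v <- shuffle_row(code[i, ], alpha)
      sc <- score_all(v)
      true_sc <- sc[i]
      best <- max(sc, na.rm = TRUE)
      rank <- 1L + sum(sc > true_sc, na.rm = TRUE)
      tibble::tibble(shuffled_sample = rownames(code)[i],
                     true_cscore = true_sc, best_cscore = best,
                     true_rank = rank,
                     recovered = is.finite(true_sc) &&
                       sum(sc >= true_sc, na.rm = TRUE) == 1L)
    })
    dplyr::bind_cols(grid, dplyr::bind_rows(res))
  }
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  class(out) <- c("recovery_curve", class(out))
  out
}

#' Summarize a recovery curve per shuffling level
#'
#' @param curve A `recovery_curve` from [run_recovery_curve()].
#' @return Tibble with `alpha`, `intact_pct` (= 100 - alpha), `recovery_rate`,
#'   `mean_true_cscore`, `mean_best_cscore`, `n`.
#' @export
summarize_recovery <- function(curve) {
  curve |>
    dplyr::group_by(.data$alpha) |>
    dplyr::summarize(
      intact_pct = 100 - .data$alpha[1],
      recovery_rate = mean(.data$recovered),
      mean_true_cscore = mean(.data$true_cscore, na.rm = TRUE),
      mean_best_cscore = mean(.data$best_cscore, na.rm = TRUE),
      n = dplyr::n(),
      .groups = "drop"
    )
}

#' @export
autoplot.recovery_curve <- function(object, ...) {
  sm <- summarize_recovery(object)
  long <- object |>
    tidyr::pivot_longer(c("true_cscore", "best_cscore"),
                        names_to = "which", values_to = "cscore")
  ggplot2::ggplot(long, ggplot2::aes(.data$alpha, .data$cscore,
                                     colour = .data$which)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.6) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE) +
    ggplot2::geom_line(data = sm,
                       ggplot2::aes(.data$alpha, .data$recovery_rate),
                       inherit.aes = FALSE, linetype = 2) +
    ggplot2::labs(x = "% genotypes shuffled", y = "Cscore (dashed: recovery rate)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Simulate one multiplexed TMT quantification batch
#'
#' Builds a synthetic batch with one variant-peptide row per SNP. A channel
#' whose sample carries genotype `g` at the SNP draws its log2 reporter
#' intensity from the genotype-dependent mode: `N(noise_mean, noise_sd)` for
#' `AA` (the variant peptide is absent, only background is measured),
#' `N(signal_mean, signal_sd)` for `BB`, and the midpoint mode (mean of the
#' two means, average SD) for `AB`. Defaults are the reference noise/signal
#' modes of the two-component mixture (14.06/1.39 and 18.22/1.29 log2 units).
#' A missing reference genotype also draws from the noise mode. An optional
#' pooled internal-control channel gets the linear-scale mean of the sample
#' channels. Per-channel loading biases (log2-normal, SD `loading_sd`) are
#' applied, to be removed again by [normalize_loading()]; intensities are
#' returned on the raw linear scale so the full preprocessing chain applies.
#'
#' @param genotypes Reference [genotype_matrix()].
#' @param channel_samples Character vector of sample ids, one per channel, in
#'   channel order; must exist in `genotypes`.
#' @param control Add a pooled internal-control channel? Default `TRUE`.
#' @param noise_mean,noise_sd,signal_mean,signal_sd Genotype-mode parameters
#'   (log2 scale).
#' @param loading_sd SD of per-channel log2 loading biases (0 disables).
#' @param batch_id Batch identifier.
#' @param seed Optional seed; global RNG untouched when supplied.
#' @return A [quant_batch()] on the raw scale whose manifest assigns channel
#'   `i` the label `channel_samples[i]`, plus a `CONTROL` channel when
#'   `control` is `TRUE`.
#' @export
simulate_quant_batch <- function(genotypes, channel_samples, control = TRUE,
                                 noise_mean = 14.06, noise_sd = 1.39,
                                 signal_mean = 18.22, signal_sd = 1.29,
                                 loading_sd = 0.2, batch_id = "batch1",
                                 seed = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  missing <- setdiff(channel_samples, rownames(genotypes))
  if (length(missing) > 0) {
    abort(sprintf("Sample(s) not in panel: %s", paste(missing, collapse = ", ")))
  }
  snps <- colnames(genotypes)
  mu <- c(AA = noise_mean, AB = (noise_mean + signal_mean) / 2, BB = signal_mean)
  sdv <- c(AA = noise_sd, AB = (noise_sd + signal_sd) / 2, BB = signal_sd)

  build <- function() {
    g <- unclass(genotypes)[channel_samples, , drop = FALSE]
    g[is.na(g)] <- "AA"  # no variant information: background only
    log2m <- matrix(rnorm(length(g), mu[g], sdv[g]),
                    nrow = length(channel_samples))
    log2m <- t(log2m)  # peptides x channels
    if (control) {
      ctrl <- log2(rowMeans(2^log2m))
      log2m <- cbind(log2m, ctrl)
    }
    if (loading_sd > 0) {
      bias <- rnorm(ncol(log2m), 0, loading_sd)
      log2m <- sweep(log2m, 2, bias, `+`)
    }
    log2m
  }
  log2m <- if (is.null(seed)) build() else withr::with_seed(seed, build())

  n_chan <- length(channel_samples) + as.integer(control)
  chans <- sprintf("ch%02d", seq_len(n_chan))
  colnames(log2m) <- chans
  manifest <- tibble::tibble(
    channel = chans,
    sample_label = c(channel_samples, if (control) "CONTROL"),
    is_control = c(rep(FALSE, length(channel_samples)), if (control) TRUE)
  )
  peptides <- tibble::tibble(peptide_id = paste0("pep_", seq_along(snps)),
                             snp_id = snps, n_psm = 1L)
  quant_batch(batch_id, 2^log2m, peptides, manifest)
}
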