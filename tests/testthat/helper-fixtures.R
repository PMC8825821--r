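# Shared fixture builders. Everything is generated in code; no stored data.

# A small HWE panel.
tiny_panel <- function(n_samples = 6, n_snps = 20, seed = 11) {
  generate_genotype_matrix(n_samples, n_snps, seed = seed)
}

# A panel whose first `n_in_batch` samples carry a balanced class composition
# at every SNP (3 AA, 5 AB, 3 BB across 11 channels by default): the regime
# where the quartile rule is exactly calibrated, used for noiseless
# round-trip and status-level tests. Remaining samples are HWE fill.
balanced_panel <- function(n_snps = 60, n_in_batch = 11, n_extra = 9, seed = 5) {
  withr::with_seed(seed, {
    comp <- c(rep("AA", 3), rep("AB", 5), rep("BB", 3))
    stopifnot(n_in_batch == length(comp))
    core <- vapply(seq_len(n_snps), function(j) sample(comp),
                   character(n_in_batch))
    extra <- vapply(seq_len(n_snps), function(j) {
      sample(c("AA", "AB", "BB"), n_extra, replace = TRUE,
             prob = c(0.3, 0.45, 0.25))
    }, character(n_extra))
    calls <- rbind(core, extra)
    dimnames(calls) <- list(sprintf("S%03d", seq_len(nrow(calls))),
                            sprintf("chr1:%d:A:G", 1000L + seq_len(n_snps)))
    genotype_matrix(calls)
  })
}

# Raw-scale batch over the panel's first channels.
sim_batch <- function(gm, n_channels = 10, seed = 3, control = TRUE, ...) {
  simulate_quant_batch(gm, rownames(gm)[seq_len(n_channels)],
                       control = control, seed = seed, ...)
}

# A hand-built mixture fit with known parameters (for cutoff/filter tests).
fake_mixture <- function(mean_noise = 14.06, sd_noise = 1.39,
                         mean_signal = 18.22, sd_signal = 1.29) {
  structure(
    list(weight = c(noise = 0.5, signal = 0.5),
         mean = c(noise = mean_noise, signal = mean_signal),
         sd = c(noise = sd_noise, signal = sd_signal),
         loglik = 0, converged = TRUE, n_iter = 1L, n = 0L,
         values = numeric(0)),
    class = "smap_mixture"
  )
}

# Exhaustive reference implementation of the fraction-mode concordance score:
# plain double loop over positions, used as an independent oracle.
brute_force_cscore <- function(inferred, reference, min_compared = 1) {
  n_match <- 0L; n_cmp <- 0L
  for (i in seq_along(inferred)) {
    if (!is.na(inferred[i]) && !is.na(reference[i])) {
      n_cmp <- n_cmp + 1L
      if (inferred[i] == reference[i]) n_match <- n_match + 1L
    }
  }
  if (n_cmp < min_compared) return(NA_real_)
  n_match / n_cmp
}

extdata <- function(f) system.file("extdata", f, package = "smapkit")
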