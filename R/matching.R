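#' Concordance scoring configuration
#'
#' Controls how inferred genotypes are scored against reference samples.
#' `"fraction"` mode is the plain fraction of matched genotype calls, in
#' `[0, 1]`, with default acceptance thresholds Cscore >= 0.80 and
#' delta-Cscore >= 0.20. `"weighted"` mode credits each matched call with a
#' class weight (defaults 1/2/3 for AA/AB/BB — matching a rare mutant
#' homozygote is stronger evidence of identity than matching the common
#' non-mutant class) and divides by the number of compared calls, giving
#' scores on a > 1 scale with default thresholds 1.50 / 0.20.
#'
#' @param mode `"fraction"` or `"weighted"`.
#' @param weights Named per-class match weights, used in weighted mode only.
#' @param cscore_min Minimum best Cscore to accept an assignment; defaults to
#'   0.80 (fraction) or 1.50 (weighted).
#' @param delta_min Minimum delta-Cscore to accept an assignment; default 0.20.
#' @param min_compared Minimum number of jointly non-missing calls for a score
#'   to be reported at all (guards against spuriously perfect scores on tiny
#'   overlaps); default 20.
#' @return A list of class `score_config`.
#' @export
score_config <- function(mode = c("fraction", "weighted"),
                         weights = c(AA = 1, AB = 2, BB = 3),
                         cscore_min = NULL, delta_min = 0.2, min_compared = 20) {
  mode <- match.arg(mode)
  stopifnot(all(weights > 0), all(GENO_CLASSES %in% names(weights)),
            delta_min >= 0, min_compared >= 1)
  cscore_min <- cscore_min %||% if (mode == "fraction") 0.80 else 1.50
  stopifnot(cscore_min >= 0)
  structure(list(mode = mode, weights = weights[GENO_CLASSES],
                 cscore_min = cscore_min, delta_min = delta_min,
                 min_compared = min_compared),
            class = "score_config")
}

#' Concordance score between an inferred and a reference call vector
#'
#' Comparisons are restricted to positions where both vectors are
#' non-missing. Fraction mode returns the fraction of exact class matches;
#' weighted mode returns the summed class weights of the matched positions
#' divided by the number compared. Fewer than `min_compared` jointly observed
#' positions yield `NA`.
#'
#' @param inferred,reference Character call vectors aligned on the same SNPs.
#' @param cfg A [score_config()].
#' @return A single score, or `NA` if too few positions could be compared.
#' @examples
#' cscore(c("AA", "AB", "BB", "AA"), c("AA", "AB", "BB", "BB"),
#'        score_config(min_compared = 1))  # 0.75
#' @export
cscore <- function(inferred, reference, cfg = score_config()) {
  stopifnot(length(inferred) == length(reference))
  ok <- !is.na(inferred) & !is.na(reference)
  n <- sum(ok)
  if (n < cfg$min_compared) return(NA_real_)
  matched <- inferred[ok] == reference[ok]
  if (cfg$mode == "fraction") {
    mean(matched)
  } else {
    sum(cfg$weights[inferred[ok][matched]]) / n
  }
}

#' Specificity of the best match (delta-Cscore)
#'
#' `(best - second best) / best` over a vector of candidate scores: how far
#' the top candidate stands above the runner-up, in `[0, 1]` for non-negative
#' scores. A single candidate is maximally specific (returns 1); a best score
#' of 0, or no finite score, yields `NA`.
#'
#' @param scores Numeric vector of candidate Cscores (`NA` allowed).
#' @return A single value in `[0, 1]`, or `NA`.
#' @examples
#' delta_cscore(c(0.9, 0.72, 0.5))  # 0.2
#' @export
delta_cscore <- function(scores) {
  s <- sort(unname(scores[is.finite(scores)]), decreasing = TRUE)
  if (length(s) == 0 || s[1] == 0) return(NA_real_)
  if (length(s) == 1) return(1)
  (s[1] - s[2]) / s[1]
}

#' Match proteomic samples to reference genotype identities
#'
#' Scores every channel's inferred genotype vector against every candidate
#' sample in the reference panel, ranks candidates by Cscore, and assigns a
#' status: `matched` when the best candidate is the originally assigned label
#' and both thresholds pass, `corrected` when the best candidate is a
#' different sample and both thresholds pass, `unassignable` when either
#' threshold fails (including Cscore ties for the top candidate, which force
#' delta-Cscore to 0), and `control` for internal-control channels (scored
#' for reference but never assigned). Every sample is scored against the full
#' panel, not only its own batch's labels, so cross-batch swaps are found.
#'
#' @param inferred An `inferred_genotypes` tibble from [infer_batch()] (one or
#'   several batches row-bound together).
#' @param genotypes Reference [genotype_matrix()] with at least 2 samples.
#' @param cfg A [score_config()].
#' @return A tibble of class `match_report`: one row per batch x channel with
#'   columns `batch`, `channel`, `original_label`, `best_match`, `cscore`,
#'   `cscore_second`, `delta_cscore`, `n_candidates`, `n_calls`, `status`.
#' @export
match_samples <- function(inferred, genotypes, cfg = score_config()) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (nrow(genotypes) < 2) abort("Need at least 2 candidate samples in the panel.")
  candidates <- sort(rownames(genotypes))

  per_channel <- inferred |>
    dplyr::select("batch", "channel", "original_label", "is_control",
                  "snp_id", "call") |>
    tidyr::nest(calls = c("snp_id", "call"))

  score_one <- function(calls) {
    snps <- calls$snp_id[calls$snp_id %in% colnames(genotypes)]
    v <- setNames(calls$call, calls$snp_id)[snps]
    ref <- unclass(genotypes)[candidates, snps, drop = FALSE]
    vapply(candidates, function(cand) cscore(v, ref[cand, ], cfg), numeric(1))
  }

  rows <- purrr::pmap(per_channel, function(batch, channel, original_label,
                                            is_control, calls) {
    scores <- score_one(calls)
    fin <- scores[is.finite(scores)]
    if (length(fin) == 0) {
      return(tibble::tibble(batch = batch, channel = channel,
                            original_label = original_label,
                            best_match = NA_character_, cscore = NA_real_,
                            cscore_second = NA_real_, delta_cscore = NA_real_,
                            n_candidates = length(fin), n_calls = sum(!is.na(calls$call)),
                            status = if (is_control) "control" else "unassignable"))
    }
    best <- max(fin)
    best_ids <- names(fin)[fin == best]  # candidates sorted -> deterministic
    second <- if (length(fin) >= 2) sort(unname(fin), decreasing = TRUE)[2] else NA_real_
    delta <- delta_cscore(fin)
    tied <- length(best_ids) > 1
    passed <- !is.na(delta) && best >= cfg$cscore_min && delta >= cfg$delta_min && !tied
    status <- dplyr::case_when(
      is_control ~ "control",
      !passed ~ "unassignable",
      best_ids[1] == original_label ~ "matched",
      .default = "corrected"
    )
    tibble::tibble(batch = batch, channel = channel,
                   original_label = original_label,
                   best_match = best_ids[1], cscore = best,
                   cscore_second = second, delta_cscore = delta,
                   n_candidates = length(fin), n_calls = sum(!is.na(calls$call)),
                   status = status)
  })

  report <- dplyr::bind_rows(rows) |> dplyr::arrange(.data$batch, .data$channel)
  tallies <- table(factor(report$status,
                          c("matched", "corrected", "unassignable", "control")))
  inform(paste0("Match report: ",
                paste(sprintf("%s=%d", names(tallies), tallies), collapse = ", ")))
  class(report) <- c("match_report", class(report))
  report
}

#' Classify corrected samples into swap topologies
#'
#' Builds the directed graph `original label -> assigned identity` over
#' corrected samples and classifies each weakly connected component:
#' `reciprocal` — two samples exchanged with each other (a 2-cycle);
#' `cyclic` — a closed chain of 3 or more samples; `one-way` — an open chain
#' (the displaced label's own sample was not, or could not be, reassigned).
#'
#' @param report A `match_report` from [match_samples()].
#' @return A list of class `swap_graph` with `edges` (tibble: `from`, `to`,
#'   `component`, `topology`) and `components` (tibble: `component`, `size`,
#'   `n_edges`, `topology`, `members`).
#' @export
classify_swaps <- function(report) {
  corrected <- dplyr::filter(report, .data$status == "corrected")
  if (nrow(corrected) == 0) {
    out <- list(edges = tibble::tibble(from = character(), to = character(),
                                       component = integer(), topology = character()),
                components = tibble::tibble(component = integer(), size = integer(),
                                            n_edges = integer(), topology = character(),
                                            members = character()))
    class(out) <- "swap_graph"
    return(out)
  }
  edges <- tibble::tibble(from = corrected$original_label, to = corrected$best_match)
  g <- igraph::graph_from_data_frame(edges, directed = TRUE)
  comp <- igraph::components(g, mode = "weak")
  membership <- comp$membership

  comps <- purrr::map(seq_len(comp$no), function(i) {
    nodes <- names(membership)[membership == i]
    sub <- igraph::induced_subgraph(g, nodes)
    n <- igraph::vcount(sub); m <- igraph::ecount(sub)
    topology <- if (m == n) {
      if (n == 2) "reciprocal" else "cyclic"
    } else {
      "one-way"
    }
    tibble::tibble(component = i, size = n, n_edges = m, topology = topology,
                   members = paste(sort(nodes), collapse = ","))
  }) |> dplyr::bind_rows()

  edges$component <- membership[edges$from]
  edges$topology <- comps$topology[edges$component]
  out <- list(edges = edges, components = comps)
  class(out) <- "swap_graph"
  out
}

#' @export
print.swap_graph <- function(x, ...) {
  cat(sprintf("<swap_graph> %d corrected sample(s) in %d component(s)\n",
              nrow(x$edges), nrow(x$components)))
  if (nrow(x$components) > 0) {
    tab <- table(x$components$topology)
    cat("  ", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
autoplot.match_report <- function(object, cfg = NULL, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$cscore, .data$delta_cscore,
                               colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "Cscore (best candidate)", y = expression(Delta * "Cscore"),
                  colour = NULL) +
    ggplot2::theme_minimal()
}
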