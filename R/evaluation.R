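#' Positive predictive value of a top-k gene list
#'
#' The PPV (or mutation rate) of the top `k` genes of a ranking is the exact
#' fraction of those genes that are mutated in the reference screen:
#' `|top-k intersect mutated| / k`.
#'
#' @param ranked A ranked list from [rank_genes()] or [combine_strategies()].
#' @param mut A [mutation_set()].
#' @param k Top-list size, at most the length of the ranking.
#' @return PPV in \[0, 1\].
#' @export
ppv <- function(ranked, mut, k) {
  k <- assert_count(k, "k")
  if (k > nrow(ranked)) {
    stop_priorank(sprintf("k = %d exceeds the ranking length (%d).",
                          k, nrow(ranked)),
                  "priorank_error_cutoff")
  }
  sum(ranked$gene_id[seq_len(k)] %in% mut$mutated_genes) / k
}

#' Baseline PPV of a mutation screen
#'
#' The mutation rate of unprioritized sequencing: total mutated genes divided
#' by total genes sequenced. This is the yield a random gene selection attains
#' in expectation.
#'
#' @param mut A [mutation_set()].
#' @return Baseline PPV in \[0, 1\].
#' @export
baseline_ppv <- function(mut) {
  length(mut$mutated_genes) / mut$n_genes_sequenced
}

#' Genes to sequence to find m mutated genes
#'
#' The minimal top-list size whose intersection with the mutation screen
#' contains `m` mutated genes — equivalently, the rank of the m-th mutated
#' gene in the list.
#'
#' @param ranked A ranked list.
#' @param mut A [mutation_set()].
#' @param m Number of mutated genes desired.
#' @return Integer, the minimal k.
#' @export
genes_to_find <- function(ranked, mut, m) {
  m <- assert_count(m, "m")
  hits <- which(ranked$gene_id %in% mut$mutated_genes)
  if (length(hits) < m) {
    stop_priorank(
      sprintf("Ranking contains only %d mutated genes, %d requested.",
              length(hits), m),
      "priorank_error_yield"
    )
  }
  hits[m]
}

#' Genes to sequence under random selection
#'
#' The deterministic expected-yield analogue of [genes_to_find()] for an
#' unprioritized screen: the smallest integer `k` whose expected mutation
#' yield `k * rate` reaches `m`.
#'
#' @param rate Baseline mutation rate in (0, 1\].
#' @param m Number of mutated genes desired.
#' @return Integer, the smallest k with `k * rate >= m`.
#' @export
baseline_genes_to_find <- function(rate, m) {
  assert_scalar_number(rate, "rate", lower = 0, upper = 1)
  if (rate == 0) {
    stop_priorank("Baseline rate must be positive.", "priorank_error_argument")
  }
  m <- assert_count(m, "m")
  k <- as.integer(ceiling(m / rate))
  # guard against floating-point slop on the division
  while (k > 1L && (k - 1L) * rate >= m) k <- k - 1L
  while (k * rate < m) k <- k + 1L
  k
}

#' Mutation-yield curve of a ranking
#'
#' For each target number of mutated genes `m`, the minimal number of
#' top-ranked genes that must be sequenced to find them, next to the baseline
#' analogue for random selection. Curves below the baseline indicate
#' enrichment of mutated genes at the top of the list.
#'
#' @param ranked A ranked list.
#' @param mut A [mutation_set()].
#' @param m_max Largest yield to tabulate; defaults to all mutated genes
#'   present in the ranking.
#' @return A tibble of class `priorank_yield` with columns `m`, `k`
#'   (prioritized) and `k_baseline` (random selection).
#' @export
yield_curve <- function(ranked, mut, m_max = NULL) {
  hits <- which(ranked$gene_id %in% mut$mutated_genes)
  if (length(hits) == 0) {
    stop_priorank("Ranking contains no mutated genes.", "priorank_error_yield")
  }
  m_max <- m_max %||% length(hits)
  m_max <- min(assert_count(m_max, "m_max"), length(hits))
  rate <- baseline_ppv(mut)
  out <- tibble(
    m = seq_len(m_max),
    k = hits[seq_len(m_max)],
    k_baseline = vapply(seq_len(m_max), function(m) {
      baseline_genes_to_find(rate, m)
    }, integer(1))
  )
  attr(out, "strategy") <- strategy_label(ranked)
  class(out) <- c("priorank_yield", class(out))
  out
}

#' PPV at a ladder of top-list cutoffs
#'
#' Evaluates a ranking at the standard cutoff ladder
#' 500-400-300-200-150-100-75-50-25-10 (or any supplied ladder). Cutoffs that
#' exceed the ranking length are reported as unavailable rather than silently
#' dropped; the mean PPV averages the available cutoffs only.
#'
#' @param ranked A ranked list.
#' @param mut A [mutation_set()].
#' @param cutoffs Integer cutoffs (default the standard ladder).
#' @return An object of class `priorank_eval`; see [tidy()] / [glance()] /
#'   [autoplot()] methods.
#' @export
ppv_at_cutoffs <- function(ranked, mut,
                           cutoffs = c(500, 400, 300, 200, 150, 100, 75, 50, 25, 10)) {
  cutoffs <- sort(unique(as.integer(cutoffs)), decreasing = TRUE)
  if (any(cutoffs < 1)) {
    stop_priorank("Cutoffs must be positive integers.", "priorank_error_cutoff")
  }
  available <- cutoffs <= nrow(ranked)
  n_mut <- rep(NA_integer_, length(cutoffs))
  ppv_v <- rep(NA_real_, length(cutoffs))
  mutated <- ranked$gene_id %in% mut$mutated_genes
  cum <- cumsum(mutated)
  n_mut[available] <- cum[cutoffs[available]]
  ppv_v[available] <- n_mut[available] / cutoffs[available]
  structure(
    list(
      table = tibble(cutoff = cutoffs, available = available,
                     n_mutated = n_mut, ppv = ppv_v),
      baseline_ppv = baseline_ppv(mut),
      mean_ppv = mean(ppv_v[available]),
      strategy = strategy_label(ranked),
      n_genes_ranked = nrow(ranked)
    ),
    class = "priorank_eval"
  )
}

#' @export
print.priorank_eval <- function(x, ...) {
  cat("<priorank_eval> strategy: ", x$strategy,
      " (", x$n_genes_ranked, " genes ranked)\n", sep = "")
  cat("  baseline PPV ", format_percent(x$baseline_ppv),
      ", mean PPV over available cutoffs ", format_percent(x$mean_ppv),
      "\n", sep = "")
  print(x$table, ...)
  invisible(x)
}

#' Maximum PPV over all top-list sizes
#'
#' Scans every cutoff `k` between `min_k` and the ranking length and returns
#' the maximum PPV together with the smallest `k` attaining it.
#'
#' @param ranked A ranked list.
#' @param mut A [mutation_set()].
#' @param min_k Smallest cutoff to consider (default 1; a larger value avoids
#'   trivially perfect PPVs on one- or two-gene lists).
#' @return A list with elements `k` and `ppv`.
#' @export
max_ppv <- function(ranked, mut, min_k = 1) {
  min_k <- assert_count(min_k, "min_k")
  n <- nrow(ranked)
  if (min_k > n) {
    stop_priorank("min_k exceeds the ranking length.", "priorank_error_cutoff")
  }
  ks <- seq_len(n)
  curve <- cumsum(ranked$gene_id %in% mut$mutated_genes) / ks
  curve <- curve[ks >= min_k]
  ks <- ks[ks >= min_k]
  i <- which.max(curve)   # first maximum = smallest attaining k
  list(k = ks[i], ppv = curve[i])
}

#' Fold change of a PPV over baseline
#'
#' @param ppv_value PPV of a prioritized list.
#' @param baseline Baseline PPV; must be positive.
#' @return `ppv_value / baseline`.
#' @export
fold_change <- function(ppv_value, baseline) {
  assert_scalar_number(ppv_value, "ppv_value", lower = 0, upper = 1)
  assert_scalar_number(baseline, "baseline", lower = 0, upper = 1)
  if (baseline <= 0) {
    stop_priorank("Baseline PPV must be positive for a fold change.",
                  "priorank_error_argument")
  }
  ppv_value / baseline
}

#' PPV as a function of a prioritization-value cutoff
#'
#' For each threshold `t`, the PPV among genes whose score is strictly above
#' `t`. Mutation data from several screens can be pooled (a gene counts as
#' mutated if any screen reports it), which is how a score threshold is
#' calibrated across tumor entities.
#'
#' @param scores A [score_table()].
#' @param mut A [mutation_set()] or a list of them (pooled).
#' @param thresholds Numeric thresholds; defaults to the 0, 0.05, ..., 0.95
#'   quantiles of the scores.
#' @return A tibble of class `priorank_score_cutoff` with columns `threshold`,
#'   `n_selected`, `n_mutated`, `ppv` (`NA` when no gene exceeds the
#'   threshold).
#' @export
ppv_by_score_cutoff <- function(scores, mut, thresholds = NULL) {
  if (inherits(mut, "priorank_mutations")) mut <- list(mut)
  mutated <- unique(unlist(lapply(mut, function(m) m$mutated_genes)))
  x <- scores[!is.na(scores$score), , drop = FALSE]
  if (is.null(thresholds)) {
    thresholds <- unique(unname(quantile(x$score, seq(0, 0.95, by = 0.05))))
  }
  thresholds <- sort(thresholds)
  is_mut <- x$gene_id %in% mutated
  rows <- lapply(thresholds, function(t) {
    sel <- x$score > t
    n_sel <- sum(sel)
    n_mut <- sum(sel & is_mut)
    tibble(threshold = t, n_selected = n_sel, n_mutated = n_mut,
           ppv = if (n_sel > 0) n_mut / n_sel else NA_real_)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "strategy") <- strategy_label(scores)
  class(out) <- c("priorank_score_cutoff", class(out))
  out
}
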