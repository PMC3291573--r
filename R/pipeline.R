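strategy_order <- c("fitsnp", "expr_variance", "dosage_sensitivity",
                    "loss_frequency")

# all four single score tables computable from a bundle's layers; strategies
# whose layer is missing are skipped with a warning, mirroring entities that
# lack matched profiles
compute_scores <- function(cohort, dataset, loss_cutoff) {
  universe <- cohort$mutations$universe %||% cohort$annotation$gene_id
  scores <- list()
  scores$fitsnp <- der_score(cohort$der, universe)
  if (!is.null(cohort$expression)) {
    scores$expr_variance <- expression_variance(cohort$expression)
  } else {
    warn(sprintf("[%s] no expression layer: skipping expr_variance.", dataset))
  }
  cn <- NULL
  if (!is.null(cohort$segments)) {
    cn <- assign_segment_values(cohort$segments, cohort$annotation)
    scores$loss_frequency <- loss_frequency(cn, loss_cutoff)
  } else {
    warn(sprintf("[%s] no copy-number layer: skipping loss_frequency.", dataset))
  }
  if (!is.null(cohort$expression) && !is.null(cn)) {
    scores$dosage_sensitivity <- tryCatch(
      dosage_sensitivity(cohort$expression, cn),
      priorank_error_too_few_samples = function(e) {
        warn(sprintf("[%s] %s Skipping dosage_sensitivity.", dataset,
                     conditionMessage(e)))
        NULL
      }
    )
  } else if (!is.null(cohort$expression) || !is.null(cn)) {
    warn(sprintf("[%s] layers not matched: skipping dosage_sensitivity.", dataset))
  }
  scores[!vapply(scores, is.null, logical(1))]
}

#' Run the full prioritization pipeline over one or more cohorts
#'
#' For every dataset: computes all single-strategy scores its layers allow
#' (fitSNP DER, expression variance, dosage sensitivity, copy-number-loss
#' frequency), ranks genes within the sequenced universe, builds every
#' pairwise combined list, and evaluates each ranking's PPV at the cutoff
#' ladder against the dataset's mutation screen. Across datasets that carry
#' the full strategy set, strategies (plus the baseline) are then ordered by
#' weighted rank aggregation with mean-PPV importance weights.
#'
#' @param cohorts A `priorank_cohort` or named list of them.
#' @param loss_cutoff Copy-number-loss threshold passed to [loss_frequency()].
#' @param cutoffs Top-list cutoff ladder for [ppv_at_cutoffs()].
#' @param combine Whether to evaluate pairwise-combined strategies.
#' @param aggregate_seed Seed for the heuristic aggregation search.
#' @return A `priorank_report`: per-dataset evaluations (named list of
#'   `priorank_eval`), the strategy `consensus` (or `NULL` if fewer than two
#'   datasets carry the full strategy set), and the observed per-dataset
#'   strategy rankings.
#' @export
run_pipeline <- function(cohorts, loss_cutoff = -0.15,
                         cutoffs = c(500, 400, 300, 200, 150, 100, 75, 50, 25, 10),
                         combine = TRUE, aggregate_seed = 1L) {
  if (inherits(cohorts, "priorank_cohort")) {
    cohorts <- list(dataset1 = cohorts)
  }
  if (is.null(names(cohorts)) || any(names(cohorts) == "")) {
    stop_priorank("`cohorts` must be a named list.", "priorank_error_argument")
  }

  evaluations <- list()
  observed_rankings <- list()
  for (dataset in names(cohorts)) {
    cohort <- cohorts[[dataset]]
    universe <- cohort$mutations$universe %||% cohort$annotation$gene_id
    scores <- compute_scores(cohort, dataset, loss_cutoff)
    rankings <- lapply(scores, rank_genes, universe = universe)

    if (combine && length(rankings) >= 2) {
      pairs <- utils::combn(names(rankings), 2, simplify = FALSE)
      for (pr in pairs) {
        a <- rankings[[pr[1]]]; b <- rankings[[pr[2]]]
        n_target <- min(max(cutoffs), length(intersect(a$gene_id, b$gene_id)))
        if (n_target >= min(cutoffs)) {
          rankings[[paste(pr, collapse = "+")]] <-
            combine_strategies(a, b, n_target)
        }
      }
    }

    evals <- lapply(rankings, ppv_at_cutoffs, mut = cohort$mutations,
                    cutoffs = cutoffs)
    evaluations[[dataset]] <- evals

    # the dataset's own strategy ordering: mean PPV, baseline included as an
    # item; mean PPV doubles as the importance weight
    mean_ppvs <- c(vapply(evals, function(e) e$mean_ppv, numeric(1)),
                   baseline = baseline_ppv(cohort$mutations))
    ord <- order_desc_score(unname(mean_ppvs), names(mean_ppvs))
    observed_rankings[[dataset]] <- strategy_ranking(
      dataset, names(mean_ppvs)[ord], unname(mean_ppvs)[ord]
    )
  }

  # aggregate across datasets carrying the full (identical) strategy set
  all_sets <- lapply(observed_rankings, function(r) sort(r$strategy))
  full_set <- all_sets[[which.max(lengths(all_sets))]]
  eligible <- names(all_sets)[vapply(all_sets, identical, logical(1), full_set)]
  dropped <- setdiff(names(all_sets), eligible)
  if (length(dropped) > 0) {
    warn(paste0("Excluded from aggregation (incomplete strategy set): ",
                paste(dropped, collapse = ", ")))
  }
  consensus <- NULL
  if (length(eligible) >= 2) {
    observed <- dplyr::bind_rows(observed_rankings[eligible])
    consensus <- aggregate_rankings(observed, mode = "auto",
                                    seed = aggregate_seed)
  }

  structure(
    list(evaluations = evaluations,
         observed_rankings = dplyr::bind_rows(observed_rankings),
         consensus = consensus,
         loss_cutoff = loss_cutoff, cutoffs = cutoffs),
    class = "priorank_report"
  )
}

#' @export
print.priorank_report <- function(x, ...) {
  cat("<priorank_report> ", length(x$evaluations), " dataset(s)\n", sep = "")
  for (ds in names(x$evaluations)) {
    evals <- x$evaluations[[ds]]
    base <- evals[[1]]$baseline_ppv
    cat("  ", ds, " (baseline PPV ", format_percent(base), "): ",
        paste0(names(evals), "=", format_percent(
          vapply(evals, function(e) e$mean_ppv, numeric(1))),
          collapse = ", "), "\n", sep = "")
  }
  if (!is.null(x$consensus)) {
    cat("  consensus: ", paste(x$consensus$ordering, collapse = " > "),
        "\n", sep = "")
  }
  invisible(x)
}
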