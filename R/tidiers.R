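#' Tidy a PPV evaluation
#'
#' One row per cutoff of the ladder, with the exact-fraction PPV, the baseline
#' and the fold change over baseline.
#'
#' @param x A `priorank_eval` from [ppv_at_cutoffs()].
#' @param ... Unused.
#' @return A tibble with columns `strategy`, `cutoff`, `available`,
#'   `n_mutated`, `ppv`, `baseline_ppv`, `fold`.
#' @method tidy priorank_eval
#' @export
tidy.priorank_eval <- function(x, ...) {
  dplyr::mutate(
    x$table,
    strategy = x$strategy,
    baseline_ppv = x$baseline_ppv,
    fold = if (x$baseline_ppv > 0) .data$ppv / x$baseline_ppv else NA_real_,
    .before = 1
  ) |>
    dplyr::relocate("strategy", "cutoff", "available", "n_mutated", "ppv",
                    "baseline_ppv", "fold")
}

#' Summarize a PPV evaluation in one row
#'
#' @param x A `priorank_eval`.
#' @param ... Unused.
#' @return A one-row tibble with `strategy`, `n_genes_ranked`, `baseline_ppv`,
#'   `mean_ppv`, `mean_fold`.
#' @method glance priorank_eval
#' @export
glance.priorank_eval <- function(x, ...) {
  tibble(strategy = x$strategy,
         n_genes_ranked = x$n_genes_ranked,
         baseline_ppv = x$baseline_ppv,
         mean_ppv = x$mean_ppv,
         mean_fold = if (x$baseline_ppv > 0) x$mean_ppv / x$baseline_ppv else NA_real_)
}

#' Tidy a strategy consensus
#'
#' @param x A `priorank_consensus` from [aggregate_rankings()].
#' @param ... Unused.
#' @return A tibble with columns `position`, `strategy`.
#' @method tidy priorank_consensus
#' @export
tidy.priorank_consensus <- function(x, ...) {
  tibble(position = seq_along(x$ordering), strategy = x$ordering)
}

#' Summarize a strategy consensus in one row
#'
#' @param x A `priorank_consensus`.
#' @param ... Unused.
#' @return A one-row tibble with `distance`, `mode`, `n_strategies`,
#'   `n_datasets`.
#' @method glance priorank_consensus
#' @export
glance.priorank_consensus <- function(x, ...) {
  tibble(distance = x$distance, mode = x$mode,
         n_strategies = length(x$items), n_datasets = x$n_datasets)
}

#' Tidy a pipeline report
#'
#' Stacks every dataset's per-cutoff evaluation into one long tibble.
#'
#' @param x A `priorank_report` from [run_pipeline()].
#' @param ... Unused.
#' @return A tibble with columns `dataset`, `strategy`, `cutoff`, `available`,
#'   `n_mutated`, `ppv`, `baseline_ppv`, `fold`.
#' @method tidy priorank_report
#' @export
tidy.priorank_report <- function(x, ...) {
  purrr::imap(x$evaluations, function(evals, ds) {
    dplyr::bind_rows(lapply(evals, tidy)) |>
      dplyr::mutate(dataset = ds, .before = 1)
  }) |>
    dplyr::bind_rows()
}

#' Summarize a pipeline report
#'
#' @param x A `priorank_report`.
#' @param ... Unused.
#' @return A tibble with one row per dataset-strategy pair (mean PPV, baseline,
#'   mean fold).
#' @method glance priorank_report
#' @export
glance.priorank_report <- function(x, ...) {
  purrr::imap(x$evaluations, function(evals, ds) {
    dplyr::bind_rows(lapply(evals, glance)) |>
      dplyr::mutate(dataset = ds, .before = 1)
  }) |>
    dplyr::bind_rows()
}
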