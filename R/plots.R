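#' Plot a mutation-yield curve
#'
#' Mirrors the standard presentation: the number of genes that must be
#' sequenced (y) to find a given number of mutated genes (x), with the
#' random-selection baseline as a dashed reference. A prioritization curve
#' below the baseline indicates enrichment.
#'
#' @param object A `priorank_yield` from [yield_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot priorank_yield
#' @export
autoplot.priorank_yield <- function(object, ...) {
  lab <- attr(object, "strategy", exact = TRUE) %||% "prioritized"
  df <- tidyr::pivot_longer(as_tibble(object), c("k", "k_baseline"),
                            names_to = "curve", values_to = "genes")
  df$curve <- ifelse(df$curve == "k", lab, "baseline (random)")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$m, y = .data$genes,
                                   colour = .data$curve,
                                   linetype = .data$curve)) +
    ggplot2::geom_step() +
    ggplot2::scale_linetype_manual(
      values = setNames(c("solid", "dashed"), c(lab, "baseline (random)"))) +
    ggplot2::labs(x = "mutated genes found", y = "genes sequenced",
                  colour = NULL, linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Plot PPV against the top-list cutoff ladder
#'
#' @param object A `priorank_eval` from [ppv_at_cutoffs()].
#' @param ... Unused.
#' @return A ggplot with the baseline PPV as a dashed horizontal line.
#' @method autoplot priorank_eval
#' @export
autoplot.priorank_eval <- function(object, ...) {
  df <- object$table[object$table$available, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cutoff, y = .data$ppv)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$baseline_ppv, linetype = "dashed") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "top-ranked genes sequenced", y = "PPV (mutation rate)",
                  title = object$strategy) +
    ggplot2::theme_minimal()
}

#' Plot PPV as a function of the prioritization-value cutoff
#'
#' @param object A `priorank_score_cutoff` from [ppv_by_score_cutoff()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot priorank_score_cutoff
#' @export
autoplot.priorank_score_cutoff <- function(object, ...) {
  df <- object[!is.na(object$ppv), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold, y = .data$ppv)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "prioritization value cutoff (score > t)",
                  y = "PPV (mutation rate)") +
    ggplot2::theme_minimal()
}
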