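#' Rank genes by a prioritization score
#'
#' Orders genes in descending score (the convention for every strategy: high
#' DER, high variance, high correlation, high loss frequency first). Ties are
#' broken lexicographically by gene id (C-locale byte order), so rankings are
#' deterministic and independent of input row order. Genes with `NA` scores
#' (undefined, e.g. zero-variance correlations) are dropped before ranking.
#'
#' @param scores A [score_table()].
#' @param universe Optional character vector; the ranking is restricted to
#'   these genes first (typically the sequenced universe of the mutation
#'   screen, the only place evaluation is meaningful).
#' @return A ranked list: tibble with columns `rank`, `gene_id`, `score`, the
#'   strategy label carried as an attribute.
#' @export
rank_genes <- function(scores, universe = NULL) {
  x <- scores
  if (!is.null(universe)) x <- x[x$gene_id %in% universe, , drop = FALSE]
  n_na <- sum(is.na(x$score))
  if (n_na > 0) {
    inform(sprintf("Dropping %d gene(s) with undefined score from ranking.", n_na))
    x <- x[!is.na(x$score), , drop = FALSE]
  }
  if (nrow(x) == 0) {
    stop_priorank("No genes left to rank after restriction.",
                  "priorank_error_empty")
  }
  ord <- order_desc_score(x$score, x$gene_id)
  out <- tibble(rank = seq_along(ord),
                gene_id = x$gene_id[ord],
                score = x$score[ord])
  attr(out, "strategy") <- strategy_label(scores)
  class(out) <- c("priorank_ranking", class(out))
  out
}

#' Combine two prioritization strategies by top-list intersection
#'
#' A combined candidate list of size `n` is built by finding the smallest
#' depth `k` such that the top-`k` genes of the two rankings share at least
#' `n` genes, then ordering that intersection by rank sum (position in list a
#' plus position in list b; ties broken by gene id) and truncating to `n`.
#'
#' @param list_a,list_b Ranked lists from [rank_genes()].
#' @param n Target combined list size.
#' @return A ranked list of `n` genes with columns `rank`, `gene_id`,
#'   `rank_a`, `rank_b`, `score` (the rank sum; lower is better, but the
#'   column is stored negated so that "higher score = better" holds like every
#'   other ranking). The selected depth `k` is carried as attribute
#'   `k_selected`.
#' @export
combine_strategies <- function(list_a, list_b, n) {
  n <- assert_count(n, "n")
  pos_a <- setNames(list_a$rank, list_a$gene_id)
  pos_b <- setNames(list_b$rank, list_b$gene_id)
  common <- intersect(list_a$gene_id, list_b$gene_id)
  if (length(common) < n) {
    stop_priorank(
      sprintf("Intersection never reaches %d genes; maximum achievable is %d.",
              n, length(common)),
      "priorank_error_intersection"
    )
  }
  # the smallest k whose top-k lists share >= n genes is the n-th smallest
  # value of max(rank_a, rank_b) over shared genes
  k_gene <- pmax(pos_a[common], pos_b[common])
  k_sel <- sort(k_gene)[n]
  members <- common[k_gene <= k_sel]
  rank_sum <- pos_a[members] + pos_b[members]
  ord <- order(rank_sum, members, method = "radix")
  members <- members[ord][seq_len(n)]
  out <- tibble(rank = seq_len(n),
                gene_id = members,
                rank_a = unname(pos_a[members]),
                rank_b = unname(pos_b[members]),
                score = -as.numeric(pos_a[members] + pos_b[members]))
  lab_a <- strategy_label(list_a)
  lab_b <- strategy_label(list_b)
  attr(out, "strategy") <- paste(lab_a, lab_b, sep = "+")
  attr(out, "k_selected") <- unname(k_sel)
  class(out) <- c("priorank_ranking", class(out))
  out
}
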