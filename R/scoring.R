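#' Construct a score table
#'
#' A score table holds one prioritization strategy's per-gene values. Higher
#' is always "more interesting": DER and loss frequency lie in \[0, 1\],
#' dosage sensitivity in \[-1, 1\], expression variance is a non-negative
#' standard deviation.
#'
#' @param gene_id Character vector of gene ids (unique).
#' @param score Numeric scores (`NA` marks a gene whose score is undefined,
#'   e.g. a zero-variance correlation; such genes are excluded from ranking).
#' @param strategy Strategy label, one of `"fitsnp"`, `"expr_variance"`,
#'   `"dosage_sensitivity"`, `"loss_frequency"` or a custom label.
#' @return A tibble with columns `gene_id`, `score` and a `strategy` attribute.
#' @export
score_table <- function(gene_id, score, strategy) {
  if (anyDuplicated(gene_id)) {
    stop_priorank("Duplicate gene ids in score table.",
                  "priorank_error_duplicate_gene")
  }
  out <- tibble(gene_id = as.character(gene_id), score = as.numeric(score))
  attr(out, "strategy") <- strategy
  out
}

#' Strategy label of a score table or ranking
#'
#' @param x A score table or ranked list.
#' @return The strategy label, or `NA` if none recorded.
#' @export
strategy_label <- function(x) {
  attr(x, "strategy", exact = TRUE) %||% NA_character_
}

#' Assign per-gene copy-number values from segmented profiles
#'
#' Extracts one copy-number (CBS log-ratio) value per gene and sample from
#' piecewise-constant segments. A gene overlapping exactly one segment takes
#' that segment's value; a gene overlapping several takes the value of the
#' segment with the largest overlap length (ties broken toward the segment
#' with the smaller start); a gene overlapping none takes the value of the
#' same-chromosome segment minimizing the interval gap — the nearest value.
#' The fallback is never applied across chromosomes.
#'
#' @param segments Segment tibble as returned by [read_segments()].
#' @param genes Gene annotation tibble.
#' @param allow_missing_chrom If `FALSE` (default), a gene whose chromosome is
#'   absent from a sample's profile is an error; if `TRUE`, the cell is `NA`.
#' @return A gene-by-sample tibble: column `gene_id` plus one numeric column
#'   per sample.
#' @export
assign_segment_values <- function(segments, genes, allow_missing_chrom = FALSE) {
  samples <- unique(segments$sample)
  out <- matrix(NA_real_, nrow = nrow(genes), ncol = length(samples),
                dimnames = list(NULL, samples))
  seg_split <- split(segments, segments$sample)
  gene_chrom_split <- split(seq_len(nrow(genes)), genes$chrom)
  for (s in samples) {
    seg_s <- seg_split[[s]]
    for (chr in names(gene_chrom_split)) {
      gi <- gene_chrom_split[[chr]]
      seg_c <- seg_s[seg_s$chrom == chr, , drop = FALSE]
      if (nrow(seg_c) == 0) {
        if (allow_missing_chrom) next
        stop_priorank(
          paste0("Sample ", s, " has no segments on chromosome ", chr,
                 " (required by ", length(gi), " genes)."),
          "priorank_error_missing_chrom"
        )
      }
      seg_c <- seg_c[order(seg_c$start), , drop = FALSE]
      gs <- genes$start[gi]; ge <- genes$end[gi]
      # overlap length of every gene x segment pair (half-open intervals)
      ov <- outer(ge, seg_c$end, pmin) - outer(gs, seg_c$start, pmax)
      has_ov <- rowSums(ov > 0) > 0
      pick <- integer(length(gi))
      if (any(has_ov)) {
        ovp <- ov[has_ov, , drop = FALSE]
        ovp[ovp < 0] <- 0
        # first max = smallest segment start (segments sorted by start)
        pick[has_ov] <- max.col(ovp, ties.method = "first")
      }
      if (any(!has_ov)) {
        # interval gap; one of the two terms is positive for disjoint intervals
        gap <- pmax(outer(gs[!has_ov], seg_c$end, `-`),
                    -outer(ge[!has_ov], seg_c$start, `-`))
        pick[!has_ov] <- max.col(-gap, ties.method = "first")
      }
      out[gi, s] <- seg_c$value[pick]
    }
  }
  dplyr::bind_cols(tibble(gene_id = genes$gene_id), as_tibble(out))
}

# gene-by-sample tibble -> numeric matrix with gene_id rownames
cn_matrix <- function(x) {
  m <- as.matrix(x[, setdiff(names(x), "gene_id"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- x$gene_id
  m
}

#' Expression-variance score
#'
#' Per gene, the sample standard deviation (n - 1 denominator) of its logged
#' expression values across the cohort. Genes whose expression varies most are
#' hypothesized to be perturbed, e.g. by mutation.
#'
#' @param expr Expression tibble (`gene_id` plus sample columns), logged.
#' @return A [score_table()] with strategy `"expr_variance"`.
#' @export
expression_variance <- function(expr) {
  m <- cn_matrix(expr)
  n <- ncol(m)
  if (n < 2) {
    stop_priorank("Expression variance needs at least 2 samples.",
                  "priorank_error_too_few_samples")
  }
  sdv <- sqrt(rowSums((m - rowMeans(m))^2) / (n - 1))
  score_table(expr$gene_id, sdv, "expr_variance")
}

#' Dosage-sensitivity score
#'
#' Per gene, the Spearman rank correlation between its expression values and
#' its copy-number values over the samples present in both layers (average
#' ranks for ties). Dosage-sensitive genes — whose expression tracks copy
#' number — are hypothesized to be more likely to carry function-altering
#' mutations. A gene with zero variance in either layer has an undefined
#' correlation and is scored `NA` (excluded from ranking).
#'
#' @param expr Expression tibble (`gene_id` plus sample columns).
#' @param cn Gene-level copy-number tibble from [assign_segment_values()].
#' @return A [score_table()] with strategy `"dosage_sensitivity"`.
#' @export
dosage_sensitivity <- function(expr, cn) {
  shared_samples <- intersect(setdiff(names(expr), "gene_id"),
                              setdiff(names(cn), "gene_id"))
  if (length(shared_samples) < 3) {
    stop_priorank(
      sprintf("Dosage sensitivity needs >= 3 matched samples, found %d.",
              length(shared_samples)),
      "priorank_error_too_few_samples"
    )
  }
  shared_genes <- intersect(expr$gene_id, cn$gene_id)
  if (length(shared_genes) == 0) {
    stop_priorank("No genes shared between expression and copy-number layers.",
                  "priorank_error_empty")
  }
  e <- cn_matrix(expr)[shared_genes, shared_samples, drop = FALSE]
  c_ <- cn_matrix(cn)[shared_genes, shared_samples, drop = FALSE]
  re <- t(apply(e, 1, rank))   # average ranks on ties
  rc <- t(apply(c_, 1, rank))
  re <- re - rowMeans(re)
  rc <- rc - rowMeans(rc)
  denom <- sqrt(rowSums(re^2) * rowSums(rc^2))
  rho <- ifelse(denom > 0, rowSums(re * rc) / denom, NA_real_)
  score_table(shared_genes, rho, "dosage_sensitivity")
}

#' Copy-number-loss frequency score
#'
#' Per gene, the fraction of cohort samples whose gene-level copy-number value
#' falls strictly below `loss_cutoff` — the "first hit" of the Knudson two-hit
#' model. The cutoff is dataset-specific (it depends on platform and
#' normalization); the default of -0.15 log2 ratio is a common choice for
#' single-copy loss on noisy array data.
#'
#' @param cn Gene-level copy-number tibble from [assign_segment_values()].
#' @param loss_cutoff Loss threshold on the log-ratio scale; a value exactly
#'   equal to the cutoff does not count as a loss.
#' @return A [score_table()] with strategy `"loss_frequency"`.
#' @export
loss_frequency <- function(cn, loss_cutoff = -0.15) {
  assert_scalar_number(loss_cutoff, "loss_cutoff")
  m <- cn_matrix(cn)
  freq <- rowMeans(m < loss_cutoff, na.rm = TRUE)
  score_table(cn$gene_id, freq, "loss_frequency")
}

#' fitSNP DER score
#'
#' Restricts a DER lookup table to a gene universe. Genes absent from the
#' table carry no score and are excluded from the fitSNP ranking. Optionally
#' only genes with DER strictly above `min_der` are retained (0.55 is the
#' threshold originally proposed for disease-variant association).
#'
#' @param der DER tibble (`gene_id`, `der`).
#' @param universe Character vector of gene ids to score.
#' @param min_der Optional strict lower threshold on DER.
#' @return A [score_table()] with strategy `"fitsnp"`.
#' @export
der_score <- function(der, universe, min_der = NULL) {
  keep <- der[der$gene_id %in% universe, , drop = FALSE]
  if (!is.null(min_der)) {
    assert_scalar_number(min_der, "min_der", lower = 0, upper = 1)
    keep <- keep[keep$der > min_der, , drop = FALSE]
  }
  if (nrow(keep) == 0) {
    stop_priorank("No genes of the universe are present in the DER table.",
                  "priorank_error_empty")
  }
  score_table(keep$gene_id, keep$der, "fitsnp")
}
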