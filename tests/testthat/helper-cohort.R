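# PPV of each single strategy's top-k list on a generated cohort
strategy_top_ppv <- function(cohort, k = 100, loss_cutoff = -0.15) {
  universe <- cohort$annotation$gene_id
  cn <- assign_segment_values(cohort$segments, cohort$annotation)
  scores <- list(
    fitsnp = der_score(cohort$der, universe),
    expr_variance = expression_variance(cohort$expression),
    dosage_sensitivity = dosage_sensitivity(cohort$expression, cn),
    loss_frequency = loss_frequency(cn, loss_cutoff)
  )
  vapply(scores, function(sc) {
    r <- suppressMessages(rank_genes(sc, universe = universe))
    ppv(r, cohort$mutations, k)
  }, numeric(1))
}

null_spec <- function(seed, n_genes = 2000) {
  cohort_spec(n_genes = n_genes, n_samples_expr = 15, n_samples_cn = 22,
              n_matched = 12, baseline_mutation_rate = 0.047,
              der_shift = 0, var_ratio = 1, loss_or = 1, dosage_coupling = 0,
              seed = seed)
}

enriched_spec <- function(seed, n_genes = 2000) {
  cohort_spec(n_genes = n_genes, n_samples_expr = 15, n_samples_cn = 22,
              n_matched = 12, baseline_mutation_rate = 0.047,
              der_shift = 0.25, var_ratio = 3, loss_or = 4,
              dosage_coupling = 0.8, seed = seed)
}
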