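#' Specify a synthetic tumor cohort
#'
#' Parameters of the synthetic multi-omic cohort generator. Defaults emulate a
#' typical published tumor entity: roughly 18,000 sequenced genes with a 4.7%
#' baseline mutation rate, 15 expression profiles, 22 copy-number profiles, 12
#' of them matched. Effect sizes control how strongly mutation status is
#' associated with each prioritization signal; setting all four to their null
#' values (`der_shift = 0`, `var_ratio = 1`, `loss_or = 1`,
#' `dosage_coupling = 0`) produces scores independent of mutation status.
#'
#' @param n_genes Number of genes (all sequenced in the mutation screen).
#' @param n_samples_expr Number of expression samples.
#' @param n_samples_cn Number of copy-number samples.
#' @param n_matched Number of samples present in both layers (may be 0, in
#'   which case dosage sensitivity cannot be computed).
#' @param baseline_mutation_rate Per-gene mutation probability in (0, 1).
#' @param der_shift Additive shift of the mean DER of mutated genes (Beta
#'   family, concentration kept fixed).
#' @param var_ratio Multiplier on the expression SD of mutated genes.
#' @param loss_or Odds multiplier on the per-gene copy-number-loss probability
#'   of mutated genes.
#' @param dosage_coupling In \[0, 1\]: correlation between a mutated gene's
#'   expression and its copy number across matched samples (0 for unmutated
#'   genes).
#' @param n_chromosomes Number of chromosomes genes are spread over.
#' @param segment_length_mean Mean copy-number segment length in base pairs
#'   (genes are spaced 100 kb apart, so the default of 5 Mb spans about 50
#'   genes).
#' @param base_loss_prob Per-gene loss probability of unmutated genes.
#' @param seed Master seed (mandatory); all layers draw from sub-streams
#'   derived from it, so a fixed seed reproduces the bundle bit-identically.
#' @return A `priorank_cohort_spec` list.
#' @export
cohort_spec <- function(n_genes = 18000,
                        n_samples_expr = 15,
                        n_samples_cn = 22,
                        n_matched = 12,
                        baseline_mutation_rate = 0.047,
                        der_shift = 0.25,
                        var_ratio = 3,
                        loss_or = 4,
                        dosage_coupling = 0.8,
                        n_chromosomes = 22,
                        segment_length_mean = 5e6,
                        base_loss_prob = 0.1,
                        seed) {
  if (missing(seed)) {
    stop_priorank("`seed` is mandatory: cohorts must be reproducible.",
                  "priorank_error_argument")
  }
  n_genes <- assert_count(n_genes, "n_genes", lower = 10L)
  n_samples_expr <- assert_count(n_samples_expr, "n_samples_expr", lower = 0L)
  n_samples_cn <- assert_count(n_samples_cn, "n_samples_cn", lower = 0L)
  n_matched <- assert_count(n_matched, "n_matched", lower = 0L)
  if (n_matched > min(n_samples_expr, n_samples_cn)) {
    stop_priorank("`n_matched` cannot exceed either layer's sample count.",
                  "priorank_error_argument")
  }
  assert_scalar_number(baseline_mutation_rate, "baseline_mutation_rate")
  if (baseline_mutation_rate <= 0 || baseline_mutation_rate >= 1) {
    stop_priorank("`baseline_mutation_rate` must lie strictly in (0, 1).",
                  "priorank_error_argument")
  }
  assert_scalar_number(der_shift, "der_shift", lower = 0, upper = 0.7)
  assert_scalar_number(var_ratio, "var_ratio", lower = 0)
  if (var_ratio <= 0) {
    stop_priorank("`var_ratio` must be positive.", "priorank_error_argument")
  }
  assert_scalar_number(loss_or, "loss_or", lower = 0)
  if (loss_or <= 0) {
    stop_priorank("`loss_or` must be positive.", "priorank_error_argument")
  }
  assert_scalar_number(dosage_coupling, "dosage_coupling", lower = 0, upper = 1)
  assert_scalar_number(base_loss_prob, "base_loss_prob", lower = 0.001,
                       upper = 0.5)
  n_chromosomes <- assert_count(n_chromosomes, "n_chromosomes")
  assert_scalar_number(segment_length_mean, "segment_length_mean", lower = 2e5)
  seed <- assert_count(seed, "seed", lower = 0L)
  structure(
    list(n_genes = n_genes, n_samples_expr = n_samples_expr,
         n_samples_cn = n_samples_cn, n_matched = n_matched,
         baseline_mutation_rate = baseline_mutation_rate,
         der_shift = der_shift, var_ratio = var_ratio, loss_or = loss_or,
         dosage_coupling = dosage_coupling, n_chromosomes = n_chromosomes,
         segment_length_mean = segment_length_mean,
         base_loss_prob = base_loss_prob, seed = seed),
    class = "priorank_cohort_spec"
  )
}

# gene layout constants: genes every 100 kb, each 20 kb long, so copy-number
# segment boundaries placed midway between genes never split a gene
GENE_SPACING <- 1e5
GENE_LENGTH <- 2e4

#' Generate a synthetic multi-omic cohort
#'
#' Draws one complete input bundle: gene annotation, per-gene mutation status,
#' a fitSNP-style DER table (Beta-distributed, mean shifted upward for mutated
#' genes), a logged expression matrix (normal per gene, SD inflated for
#' mutated genes), and segmented copy-number profiles (a Markov chain of
#' loss/neutral states along each chromosome with mean run length matching
#' `segment_length_mean`; mutated genes re-draw their state with loss odds
#' multiplied by `loss_or`, and the gene after a mutated gene restarts the
#' chain so unmutated genes keep the base loss probability exactly). For
#' matched samples, a mutated gene's expression is mixed with its standardized
#' copy-number value with weight `dosage_coupling`.
#'
#' All randomness flows from the spec's master seed through fixed sub-streams
#' (one per layer), so equal specs yield bit-identical bundles.
#'
#' @param spec A [cohort_spec()].
#' @return A `priorank_cohort` list with elements `annotation`, `expression`,
#'   `segments`, `der`, `mutations`, `mutated_genes`, and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "priorank_cohort_spec"))
  sub_seeds <- with_preserved_seed(spec$seed, {
    sample.int(.Machine$integer.max - 1L, 4L)
  })

  n <- spec$n_genes
  gene_id <- sprintf("G%05d", seq_len(n))
  chrom_sizes <- rep(n %/% spec$n_chromosomes, spec$n_chromosomes)
  extra <- n - sum(chrom_sizes)
  if (extra > 0) chrom_sizes[seq_len(extra)] <- chrom_sizes[seq_len(extra)] + 1L
  chrom <- rep(paste0("chr", seq_len(spec$n_chromosomes)), chrom_sizes)
  idx_on_chrom <- unlist(lapply(chrom_sizes, seq_len), use.names = FALSE)
  start <- as.integer((idx_on_chrom - 1L) * GENE_SPACING)
  annotation <- tibble(gene_id = gene_id, chrom = chrom, start = start,
                       end = as.integer(start + GENE_LENGTH))

  # --- stream 1: mutation status ---------------------------------------
  mutated <- with_preserved_seed(sub_seeds[1], {
    rbinom(n, 1L, spec$baseline_mutation_rate) == 1L
  })
  # per-sample multiplicity is generated for realism but plays no role in the
  # gene-level PPV evaluation (most genes are mutated in a single sample)
  n_mut_samples <- with_preserved_seed(sub_seeds[1] + 1L, {
    1L + rbinom(sum(mutated), 1L, 0.1)
  })
  mutations <- mutation_set(
    gene_id[mutated], n, universe = gene_id,
    n_samples_mutated = setNames(n_mut_samples, gene_id[mutated])
  )

  # --- stream 2: DER table ----------------------------------------------
  der <- with_preserved_seed(sub_seeds[2], {
    conc <- 7
    mu <- ifelse(mutated, pmin(0.3 + spec$der_shift, 0.98), 0.3)
    round(rbeta(n, mu * conc, (1 - mu) * conc), 6)
  })
  der_tbl <- tibble(gene_id = gene_id, der = der)

  # --- sample ids --------------------------------------------------------
  matched_ids <- if (spec$n_matched > 0) sprintf("M%02d", seq_len(spec$n_matched)) else character()
  expr_only <- if (spec$n_samples_expr > spec$n_matched) {
    sprintf("E%02d", seq_len(spec$n_samples_expr - spec$n_matched))
  } else character()
  cn_only <- if (spec$n_samples_cn > spec$n_matched) {
    sprintf("C%02d", seq_len(spec$n_samples_cn - spec$n_matched))
  } else character()
  expr_samples <- c(matched_ids, expr_only)
  cn_samples <- c(matched_ids, cn_only)

  # --- stream 3: copy number --------------------------------------------
  cn_res <- with_preserved_seed(sub_seeds[3], {
    simulate_copy_number(spec, annotation, mutated, cn_samples)
  })

  # --- stream 4: expression ---------------------------------------------
  expression <- NULL
  if (spec$n_samples_expr > 0) {
    expression <- with_preserved_seed(sub_seeds[4], {
      simulate_expression(spec, gene_id, mutated, expr_samples, matched_ids,
                          cn_res$gene_values)
    })
  }

  structure(
    list(annotation = annotation, expression = expression,
         segments = cn_res$segments, der = der_tbl, mutations = mutations,
         mutated_genes = gene_id[mutated], spec = spec),
    class = "priorank_cohort"
  )
}

# Markov chain of loss/neutral states over genes in chromosome order; state
# changes with probability spacing/segment_length_mean, giving geometric run
# lengths with the requested mean. Mutated genes re-draw with boosted odds and
# the next gene restarts the chain from the base rate.
simulate_copy_number <- function(spec, annotation, mutated, cn_samples) {
  if (length(cn_samples) == 0) {
    return(list(segments = NULL, gene_values = NULL))
  }
  p0 <- spec$base_loss_prob
  odds <- p0 / (1 - p0) * spec$loss_or
  p_mut <- odds / (1 + odds)
  p_new <- GENE_SPACING / spec$segment_length_mean
  n <- nrow(annotation)
  chrom_rle <- rle(annotation$chrom)
  first_of_chrom <- rep(FALSE, n)
  first_of_chrom[cumsum(c(1, head(chrom_rle$lengths, -1)))] <- TRUE

  gene_values <- matrix(NA_real_, n, length(cn_samples),
                        dimnames = list(annotation$gene_id, cn_samples))
  seg_rows <- vector("list", length(cn_samples))
  for (si in seq_along(cn_samples)) {
    # decide where each gene's state is (re)drawn and from which probability
    redraw <- first_of_chrom | mutated | c(FALSE, head(mutated, -1)) |
      (runif(n) < p_new)
    p_draw <- ifelse(mutated, p_mut, p0)
    drawn <- runif(n) < p_draw
    state <- drawn
    keep <- !redraw
    # propagate the previous state across non-redraw positions
    for (i in which(keep)) state[i] <- state[i - 1L]
    # segment values: constant within a run of equal state, drawn per run
    run_id <- cumsum(c(TRUE, (state[-1] != head(state, -1)) |
                         first_of_chrom[-1]))
    run_first <- c(TRUE, run_id[-1] != head(run_id, -1))
    n_runs <- max(run_id)
    run_state <- state[run_first]
    run_value <- rnorm(n_runs, mean = ifelse(run_state, -0.6, 0), sd = 0.08)
    vals <- round(run_value[run_id], 6)
    gene_values[, si] <- vals

    # SEG rows: one segment per run, boundaries midway between genes
    seg_rows[[si]] <- segments_from_runs(annotation, run_id, vals, cn_samples[si])
  }
  segments <- dplyr::bind_rows(seg_rows)
  list(segments = segments, gene_values = gene_values)
}

segments_from_runs <- function(annotation, run_id, vals, sample_id) {
  first <- c(TRUE, run_id[-1] != head(run_id, -1))
  last <- c(first[-1], TRUE)
  i1 <- which(first); i2 <- which(last)
  chrom <- annotation$chrom[i1]
  # segment spans from midway before its first gene to midway after its last;
  # each chromosome's first segment is anchored at coordinate 0
  half_gap <- (GENE_SPACING - GENE_LENGTH) / 2
  start <- ifelse(c(TRUE, chrom[-1] != head(chrom, -1)),
                  0, annotation$start[i1] - half_gap)
  end <- annotation$end[i2] + half_gap
  tibble(sample = sample_id, chrom = chrom,
         start = as.integer(start), end = as.integer(end),
         value = vals[first])
}

simulate_expression <- function(spec, gene_id, mutated, expr_samples,
                                matched_ids, cn_gene_values) {
  n <- length(gene_id)
  mu_g <- rnorm(n, 7, 1.5)
  sd_g <- rgamma(n, shape = 4, rate = 8)    # mean 0.5, realistic spread
  sd_g <- pmax(sd_g, 0.05)
  sd_eff <- ifelse(mutated, sd_g * spec$var_ratio, sd_g)
  m <- matrix(rnorm(n * length(expr_samples)), n, length(expr_samples),
              dimnames = list(gene_id, expr_samples))
  cpl <- spec$dosage_coupling
  if (cpl > 0 && length(matched_ids) >= 2 && !is.null(cn_gene_values)) {
    cn_m <- cn_gene_values[gene_id, matched_ids, drop = FALSE]
    cn_sd <- apply(cn_m, 1, sd)
    couple <- mutated & cn_sd > 0
    if (any(couple)) {
      cn_std <- (cn_m[couple, , drop = FALSE] -
                   rowMeans(cn_m[couple, , drop = FALSE])) / cn_sd[couple]
      m[couple, matched_ids] <- sqrt(1 - cpl^2) * m[couple, matched_ids] +
        cpl * cn_std
    }
  }
  vals <- mu_g + sd_eff * m
  dplyr::bind_cols(tibble(gene_id = gene_id), as_tibble(round(vals, 6)))
}

#' @export
print.priorank_cohort <- function(x, ...) {
  cat("<priorank_cohort> ", nrow(x$annotation), " genes, ",
      length(x$mutated_genes), " mutated (",
      format_percent(baseline_ppv(x$mutations)), " baseline)\n", sep = "")
  cat("  expression: ",
      if (is.null(x$expression)) "absent" else
        paste0(ncol(x$expression) - 1, " samples"),
      "; copy number: ",
      if (is.null(x$segments)) "absent" else
        paste0(length(unique(x$segments$sample)), " samples"),
      "\n", sep = "")
  invisible(x)
}

#' Generate several synthetic cohorts
#'
#' Emulates a multi-entity study design: one bundle per specification, with
#' optional omission of the copy-number layer for named datasets (mirroring
#' entities for which no matched profiles exist).
#'
#' @param specs Named list of [cohort_spec()]s (names become dataset ids).
#' @param omit_copy_number Character vector of dataset names whose copy-number
#'   layer is dropped from the bundle.
#' @return Named list of `priorank_cohort` bundles.
#' @export
generate_multi_dataset <- function(specs, omit_copy_number = character()) {
  if (is.null(names(specs)) || any(names(specs) == "")) {
    stop_priorank("`specs` must be a named list.", "priorank_error_argument")
  }
  bad <- setdiff(omit_copy_number, names(specs))
  if (length(bad) > 0) {
    stop_priorank(paste0("Unknown dataset in omit_copy_number: ",
                         paste(bad, collapse = ", ")),
                  "priorank_error_argument")
  }
  out <- lapply(names(specs), function(nm) {
    b <- generate_cohort(specs[[nm]])
    if (nm %in% omit_copy_number) b$segments <- NULL
    b
  })
  setNames(out, names(specs))
}

#' Write a cohort bundle to disk in the pipeline's input formats
#'
#' Writes `annotation.tsv`, `expression.tsv`, `segments.seg`, `der.tsv` and
#' `mutations.tsv` (whichever layers the bundle carries) so that a generated
#' cohort exercises exactly the same readers as real data.
#'
#' @param cohort A `priorank_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_gene_annotation(cohort$annotation, file.path(dir, "annotation.tsv"))
  write_der_table(cohort$der, file.path(dir, "der.tsv"))
  write_mutations(cohort$mutations, file.path(dir, "mutations.tsv"))
  if (!is.null(cohort$expression)) {
    write_expression(cohort$expression, file.path(dir, "expression.tsv"))
  }
  if (!is.null(cohort$segments)) {
    write_segments(cohort$segments, file.path(dir, "segments.seg"))
  }
  invisible(dir)
}

#' Read a cohort bundle written by [write_cohort()]
#'
#' @param dir Directory containing the bundle files.
#' @return A `priorank_cohort` (without a `spec`; `mutated_genes` is taken
#'   from the mutation file).
#' @export
read_cohort <- function(dir) {
  mut <- read_mutations(file.path(dir, "mutations.tsv"))
  expr_path <- file.path(dir, "expression.tsv")
  seg_path <- file.path(dir, "segments.seg")
  structure(
    list(
      annotation = read_gene_annotation(file.path(dir, "annotation.tsv")),
      expression = if (file.exists(expr_path)) read_expression(expr_path),
      segments = if (file.exists(seg_path)) read_segments(seg_path),
      der = read_der_table(file.path(dir, "der.tsv")),
      mutations = mut,
      mutated_genes = mut$mutated_genes,
      spec = NULL
    ),
    class = "priorank_cohort"
  )
}
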