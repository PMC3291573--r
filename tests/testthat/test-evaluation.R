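# a ranking over ids g001..gN in that order, with mutated ranks as given
ranked_with_hits <- function(n, hit_ranks, n_sequenced = n) {
  ids <- sprintf("g%03d", seq_len(n))
  r <- rank_genes(score_table(ids, seq(n, 1), "fitsnp"))
  list(ranked = r,
       mut = mutation_set(ids[hit_ranks], n_sequenced))
}

test_that("PPV is the exact fraction of mutated genes in the top k", {
  x <- ranked_with_hits(10, c(2, 4))
  expect_equal(ppv(x$ranked, x$mut, 4), 0.5)      # 2 mutated in the top 4
  x2 <- ranked_with_hits(200, sample(1:100, 11))
  expect_equal(ppv(x2$ranked, x2$mut, 100), 0.11) # 11 mutated in the top 100
  expect_equal(ppv(x$ranked, x$mut, 1), 0)
  expect_error(ppv(x$ranked, x$mut, 11), class = "priorank_error_cutoff")
})

test_that("baseline PPV is mutated over sequenced", {
  expect_equal(baseline_ppv(mutation_set(sprintf("m%03d", 1:846), 18000)),
               0.047)
  expect_equal(baseline_ppv(mutation_set(character(), 100)), 0)
  expect_equal(baseline_ppv(mutation_set(letters[1:5], 5)), 1)
})

test_that("genes_to_find is the rank of the m-th mutated gene", {
  x <- ranked_with_hits(10, c(2, 5))
  expect_equal(genes_to_find(x$ranked, x$mut, 2), 5)
  expect_equal(genes_to_find(x$ranked, x$mut, 1), 2)
  y <- ranked_with_hits(5, 1)
  expect_equal(genes_to_find(y$ranked, y$mut, 1), 1)
  expect_error(genes_to_find(x$ranked, x$mut, 3), class = "priorank_error_yield")

  # random instances vs a linear scan
  for (seed in 1:10) {
    set.seed(seed)
    hits <- sort(sample.int(100, 17))
    z <- ranked_with_hits(100, hits)
    for (m in c(1, 5, 17)) {
      scan <- 0; found <- 0
      while (found < m) { scan <- scan + 1; found <- found + (scan %in% hits) }
      expect_equal(genes_to_find(z$ranked, z$mut, m), scan)
    }
  }
})

test_that("baseline yield reproduces the printed random-selection counts", {
  expect_equal(baseline_genes_to_find(0.047, 10), 213)   # colon
  expect_equal(baseline_genes_to_find(0.061, 10), 164)   # breast
  expect_equal(baseline_genes_to_find(1, 5), 5)
  # smallest k with k * rate >= m, checked directly
  for (rate in c(0.003, 0.047, 0.2, 0.5)) {
    for (m in c(1, 7, 10)) {
      k <- baseline_genes_to_find(rate, m)
      expect_true(k * rate >= m)
      if (k > 1) expect_true((k - 1) * rate < m)
    }
  }
})

test_that("yield curves are monotone and paired with their baseline analogue", {
  x <- ranked_with_hits(300, c(3, 10, 11, 50, 200), n_sequenced = 300)
  yc <- yield_curve(x$ranked, x$mut)
  expect_equal(yc$m, 1:5)
  expect_equal(yc$k, c(3, 10, 11, 50, 200))
  expect_true(all(diff(yc$k) > 0))            # strictly increasing in m
  expect_true(all(diff(yc$k_baseline) > 0))
  # baseline yield is non-increasing in the rate
  expect_true(baseline_genes_to_find(0.02, 10) >= baseline_genes_to_find(0.05, 10))
})

test_that("the cutoff ladder reports unavailable cutoffs and the mean over available ones", {
  x <- ranked_with_hits(120, c(1, 3, 30, 90), n_sequenced = 500)
  ev <- ppv_at_cutoffs(x$ranked, x$mut)
  expect_equal(ev$table$cutoff, c(500L, 400L, 300L, 200L, 150L, 100L, 75L, 50L, 25L, 10L))
  expect_equal(sum(!ev$table$available), 5)   # 500..150 exceed 120 genes
  expect_true(all(is.na(ev$table$ppv[!ev$table$available])))
  avail <- ev$table$ppv[ev$table$available]
  expect_equal(ev$mean_ppv, mean(avail))
  expect_equal(ev$table$ppv[ev$table$cutoff == 10], 2 / 10)
  expect_equal(ev$baseline_ppv, 4 / 500)
  # k * PPV is an integer count at every available cutoff
  with_k <- ev$table[ev$table$available, ]
  expect_true(all(abs(with_k$cutoff * with_k$ppv - with_k$n_mutated) < 1e-12))
})

test_that("tidy and glance expose per-cutoff folds and one-row summaries", {
  x <- ranked_with_hits(120, c(1, 3, 30, 90), n_sequenced = 500)
  ev <- ppv_at_cutoffs(x$ranked, x$mut)
  td <- tidy(ev)
  expect_equal(td$fold, td$ppv / ev$baseline_ppv)
  gl <- glance(ev)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$mean_ppv, ev$mean_ppv)
})

test_that("max PPV scans all cutoffs and returns the smallest attaining k", {
  x <- ranked_with_hits(4, c(2, 4))
  mx <- max_ppv(x$ranked, x$mut)
  # enumeration: PPV(k) = 0, 1/2, 1/3, 1/2 -> max 0.5 first attained at k = 2
  expect_equal(mx$ppv, 0.5)
  expect_equal(mx$k, 2)

  first <- ranked_with_hits(5, 1)
  expect_equal(max_ppv(first$ranked, first$mut), list(k = 1L, ppv = 1))
  none <- ranked_with_hits(5, integer())
  expect_equal(max_ppv(none$ranked, none$mut), list(k = 1L, ppv = 0))
  # a minimum cutoff excludes trivially small lists
  expect_equal(max_ppv(x$ranked, x$mut, min_k = 3)$k, 4)
})

test_that("fold change divides PPV by a positive baseline", {
  expect_equal(round(fold_change(0.11, 0.047), 1), 2.3)
  expect_equal(fold_change(0.3, 0.3), 1)
  expect_error(fold_change(0.1, 0), class = "priorank_error_argument")
})

test_that("PPV by score cutoff selects strictly above threshold and pools screens", {
  sc <- score_table(c("a", "b", "c"), c(0.9, 0.6, 0.3), "fitsnp")
  mut <- mutation_set(c("a", "c"), 3)
  curve <- ppv_by_score_cutoff(sc, mut, thresholds = c(0.1, 0.5, 0.95))
  # t = 0.1 keeps all three (baseline over the scored universe); t = 0.5 keeps
  # {a, b}; t = 0.95 keeps nothing
  expect_equal(curve$n_selected, c(3L, 2L, 0L))
  expect_equal(curve$ppv, c(2 / 3, 1 / 2, NA))

  pooled <- ppv_by_score_cutoff(sc, list(mutation_set("a", 3), mutation_set("b", 3)),
                                thresholds = 0.5)
  expect_equal(pooled$ppv, 1)   # both a and b count as mutated somewhere
})

test_that("PPV identities hold on random rankings over a sequenced universe", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 200
    ids <- sprintf("g%03d", 1:n)
    mut <- mutation_set(sample(ids, 23), n, universe = ids)
    r <- rank_genes(score_table(ids, runif(n), "expr_variance"))
    # PPV at the full universe equals the baseline
    expect_equal(ppv(r, mut, n), baseline_ppv(mut))
    for (k in c(1, 7, 50)) {
      expect_true(abs(k * ppv(r, mut, k) - round(k * ppv(r, mut, k))) < 1e-12)
    }
  }
})

test_that("random permutations average to the baseline PPV at any cutoff", {
  set.seed(99)
  n <- 400
  ids <- sprintf("g%03d", 1:n)
  mut <- mutation_set(sample(ids, 40), n, universe = ids)
  ppvs <- replicate(400, {
    r <- rank_genes(score_table(ids, runif(n), "x"))
    ppv(r, mut, 50)
  })
  # Monte-Carlo mean of PPV(top-50) approaches the 10% baseline
  expect_equal(mean(ppvs), baseline_ppv(mut), tolerance = 0.05)
})

test_that("percent formatting rounds half-up to the printed convention", {
  expect_equal(format_percent(2 / 7), "28.6%")
  expect_equal(format_percent(0.047), "4.7%")
  expect_equal(format_percent(0.5), "50.0%")
})
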