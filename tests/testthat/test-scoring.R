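make_segments <- function(...) {
  rows <- list(...)
  tibble::tibble(
    sample = vapply(rows, `[[`, "", 1),
    chrom = vapply(rows, `[[`, "", 2),
    start = as.integer(vapply(rows, function(r) r[[3]], numeric(1))),
    end = as.integer(vapply(rows, function(r) r[[4]], numeric(1))),
    value = vapply(rows, function(r) r[[5]], numeric(1))
  )
}

make_genes <- function(ids, chrom, start, end) {
  tibble::tibble(gene_id = ids, chrom = chrom,
                 start = as.integer(start), end = as.integer(end))
}

test_that("segment values follow containment, max-overlap tie-break and nearest fallback", {
  # containment: gene inside a single segment takes its value
  genes <- make_genes("g1", "chr1", 100, 200)
  segs <- make_segments(list("s1", "chr1", 0, 1000, -0.3))
  cn <- assign_segment_values(segs, genes)
  expect_equal(cn$s1, -0.3)

  # equal overlap (10 bp each side): tie goes to the segment with smaller start
  genes <- make_genes("g1", "chr1", 90, 110)
  segs <- make_segments(list("s1", "chr1", 0, 100, 0.1),
                        list("s1", "chr1", 100, 500, -0.5))
  expect_equal(assign_segment_values(segs, genes)$s1, 0.1)

  # no overlap: nearest same-chromosome segment by interval gap
  genes <- make_genes("g1", "chr1", 2000, 2100)
  segs <- make_segments(list("s1", "chr1", 0, 1000, 0.2),
                        list("s1", "chr1", 5000, 9000, -0.7))
  expect_equal(assign_segment_values(segs, genes)$s1, 0.2)

  # larger overlap wins regardless of order
  genes <- make_genes("g1", "chr1", 50, 250)
  segs <- make_segments(list("s1", "chr1", 0, 100, 1),     # 50 bp
                        list("s1", "chr1", 100, 400, 2))   # 150 bp
  expect_equal(assign_segment_values(segs, genes)$s1, 2)
})

test_that("a chromosome absent from a sample's profile errors unless allowed", {
  genes <- make_genes(c("g1", "g2"), c("chr1", "chr2"), c(0, 0), c(100, 100))
  segs <- make_segments(list("s1", "chr1", 0, 1000, 0.5))
  expect_error(assign_segment_values(segs, genes),
               class = "priorank_error_missing_chrom")
  cn <- assign_segment_values(segs, genes, allow_missing_chrom = TRUE)
  expect_equal(cn$s1, c(0.5, NA))
})

test_that("segment assignment agrees with a brute-force oracle on random genomes", {
  for (seed in 1:25) {
    inst <- random_segment_instance(seed, n_genes = sample(10:50, 1),
                                    n_segs = sample(4:10, 1))
    got <- assign_segment_values(inst$segments, inst$genes)$s1
    want <- vapply(seq_len(nrow(inst$genes)), function(i) {
      oracle_assign_one(inst$genes$start[i], inst$genes$end[i], inst$segments)
    }, numeric(1))
    expect_equal(got, want, info = paste("seed", seed))
  }
})

test_that("expression variance is the n-1 sample SD of logged values", {
  expr <- tibble::tibble(gene_id = c("A", "B", "C"),
                         s1 = c(5, 1, 0), s2 = c(5, 3, 0), s3 = c(5, 8, 0))
  sc <- expression_variance(expr)
  expect_equal(sc$score[sc$gene_id == "A"], 0)
  expect_equal(sc$score[sc$gene_id == "C"], 0)
  expect_equal(sc$score[sc$gene_id == "B"], oracle_sd(c(1, 3, 8)))
  expect_equal(strategy_label(sc), "expr_variance")

  # closed form for two samples: |a - b| / sqrt(2)
  two <- tibble::tibble(gene_id = "A", s1 = 2.5, s2 = 7.5)
  expect_equal(expression_variance(two)$score, 5 / sqrt(2))

  one <- tibble::tibble(gene_id = "A", s1 = 1)
  expect_error(expression_variance(one),
               class = "priorank_error_too_few_samples")
})

test_that("expression variance matches the two-pass oracle on a 200x20 matrix", {
  set.seed(101)
  m <- matrix(rnorm(200 * 20, 7, 2), 200, 20)
  expr <- dplyr::bind_cols(
    tibble::tibble(gene_id = sprintf("g%03d", 1:200)),
    tibble::as_tibble(m, .name_repair = ~ sprintf("s%02d", 1:20))
  )
  got <- expression_variance(expr)$score
  want <- apply(m, 1, oracle_sd)
  expect_equal(got, want, tolerance = 1e-10)
  # linear scaling: multiplying the matrix by a positive constant scales the SD
  expr2 <- dplyr::mutate(expr, dplyr::across(-gene_id, ~ .x * 3.5))
  expect_equal(expression_variance(expr2)$score, got * 3.5, tolerance = 1e-10)
})

test_that("dosage sensitivity is the average-rank Spearman correlation", {
  expr <- tibble::tibble(gene_id = c("up", "down"),
                         s1 = c(1, 9), s2 = c(2, 5), s3 = c(5, 4), s4 = c(8, 1))
  cn <- tibble::tibble(gene_id = c("up", "down"),
                       s1 = c(-1, -1), s2 = c(0, 0), s3 = c(0.5, 0.5), s4 = c(1, 1))
  sc <- dosage_sensitivity(expr, cn)
  expect_equal(sc$score[sc$gene_id == "up"], 1)
  expect_equal(sc$score[sc$gene_id == "down"], -1)
  expect_equal(strategy_label(sc), "dosage_sensitivity")
})

test_that("dosage sensitivity handles ties, matches oracles, and marks zero variance NA", {
  set.seed(202)
  n <- 20
  ids <- sprintf("g%02d", 1:40)
  e <- matrix(sample(1:6, 40 * n, replace = TRUE), 40, n)   # heavy ties
  c_ <- matrix(round(rnorm(40 * n), 1), 40, n)
  c_[3, ] <- 0.25                                           # zero variance row
  samples <- sprintf("s%02d", 1:n)
  expr <- dplyr::bind_cols(tibble::tibble(gene_id = ids),
                           tibble::as_tibble(e, .name_repair = ~samples))
  cn <- dplyr::bind_cols(tibble::tibble(gene_id = ids),
                         tibble::as_tibble(c_, .name_repair = ~samples))
  sc <- dosage_sensitivity(expr, cn)
  for (i in c(1, 2, 4, 10, 40)) {
    expect_equal(sc$score[i], oracle_spearman(e[i, ], c_[i, ]), tolerance = 1e-12)
    expect_equal(sc$score[i], stats::cor(e[i, ], c_[i, ], method = "spearman"),
                 tolerance = 1e-12)
  }
  expect_true(is.na(sc$score[3]))
})

test_that("dosage sensitivity is invariant under strictly increasing transforms", {
  set.seed(303)
  samples <- sprintf("s%d", 1:8)
  e <- matrix(rnorm(5 * 8), 5, 8)
  c_ <- matrix(rnorm(5 * 8), 5, 8)
  ids <- sprintf("g%d", 1:5)
  as_tbl <- function(m) dplyr::bind_cols(tibble::tibble(gene_id = ids),
                                         tibble::as_tibble(m, .name_repair = ~samples))
  base <- dosage_sensitivity(as_tbl(e), as_tbl(c_))
  warped <- dosage_sensitivity(as_tbl(exp(e)), as_tbl(c_^3))
  expect_equal(base$score, warped$score, tolerance = 1e-12)
})

test_that("dosage sensitivity requires three matched samples", {
  expr <- tibble::tibble(gene_id = "g", s1 = 1, s2 = 2)
  cn <- tibble::tibble(gene_id = "g", s1 = 0, s2 = 1, s9 = 2)
  expect_error(dosage_sensitivity(expr, cn),
               class = "priorank_error_too_few_samples")
})

test_that("loss frequency counts strictly-below-cutoff samples as a fraction", {
  cn <- tibble::tibble(gene_id = c("all", "some", "boundary"))
  vals <- rbind(rep(-0.5, 10),
                c(rep(-0.4, 3), rep(0, 7)),
                c(rep(-0.15, 4), rep(0.2, 6)))   # exactly at cutoff: no loss
  cn <- dplyr::bind_cols(cn, tibble::as_tibble(vals, .name_repair = ~sprintf("s%02d", 1:10)))
  sc <- loss_frequency(cn, loss_cutoff = -0.15)
  expect_equal(sc$score, c(1, 0.3, 0))
  expect_equal(strategy_label(sc), "loss_frequency")
  # scores are integer counts over the sample count, inside [0,1]
  expect_true(all(sc$score >= 0 & sc$score <= 1))
  expect_true(all(abs(sc$score * 10 - round(sc$score * 10)) < 1e-12))
})

test_that("DER scores restrict to the universe and support the 0.55 threshold filter", {
  der <- tibble::tibble(gene_id = c("a", "b", "c", "d", "e"),
                        der = c(0.9, 0.55, 0.56, 0.2, 0.7))
  sc <- der_score(der, universe = c("a", "b", "c", "d"))
  expect_equal(nrow(sc), 4)   # e is outside the universe
  expect_equal(strategy_label(sc), "fitsnp")

  # strict threshold: 0.55 itself is excluded
  hi <- der_score(der, universe = der$gene_id, min_der = 0.55)
  expect_setequal(hi$gene_id, c("a", "c", "e"))

  # restriction to the full table is the identity
  all_sc <- der_score(der, universe = der$gene_id)
  expect_equal(all_sc$gene_id, der$gene_id)
  expect_equal(all_sc$score, der$der)

  expect_error(der_score(der, universe = "zzz"), class = "priorank_error_empty")
})
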