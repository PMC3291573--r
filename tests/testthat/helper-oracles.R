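# Independent brute-force oracles. These deliberately share no code with the
# package internals: plain loops and base building blocks only.

# per-gene segment value by scoring every segment: overlap first (largest
# overlap wins, tie -> smaller segment start), else smallest interval gap
oracle_assign_one <- function(g_start, g_end, seg) {
  ov <- numeric(nrow(seg))
  gap <- numeric(nrow(seg))
  for (j in seq_len(nrow(seg))) {
    ov[j] <- min(g_end, seg$end[j]) - max(g_start, seg$start[j])
    gap[j] <- max(g_start - seg$end[j], seg$start[j] - g_end, 0)
  }
  if (any(ov > 0)) {
    cand <- which(ov == max(ov[ov > 0]) & ov > 0)
  } else {
    cand <- which(gap == min(gap))
  }
  if (length(cand) > 1) cand <- cand[which.min(seg$start[cand])]
  seg$value[cand]
}

# two-pass sample standard deviation
oracle_sd <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

# Spearman correlation as Pearson on average ranks, written out
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  rx <- rx - mean(rx); ry <- ry - mean(ry)
  sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
}

# weighted footrule by explicit double loop over datasets and strategies
oracle_footrule <- function(candidate, observed) {
  total <- 0
  for (ds in unique(observed$dataset)) {
    rows <- observed[observed$dataset == ds, ]
    for (i in seq_len(nrow(rows))) {
      pos_c <- which(candidate == rows$strategy[i])
      total <- total + rows$weight[i] * abs(pos_c - rows$rank[i])
    }
  }
  total
}

# combined list by literal scan over k, then rank-sum sort
oracle_combine <- function(a, b, n) {
  for (k in seq_len(min(length(a), length(b)))) {
    inter <- intersect(a[seq_len(k)], b[seq_len(k)])
    if (length(inter) >= n) {
      rs <- match(inter, a) + match(inter, b)
      inter <- inter[order(rs, inter)]
      return(list(k = k, genes = inter[seq_len(n)]))
    }
  }
  NULL
}

# exhaustive footrule minimum by generating permutations recursively
oracle_best_ordering <- function(observed) {
  items <- sort(unique(observed$strategy))
  perm_rec <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perm_rec(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  best <- NULL; best_d <- Inf
  for (p in perm_rec(items)) {
    d <- oracle_footrule(p, observed)
    if (d < best_d) { best_d <- d; best <- p }
  }
  list(ordering = best, distance = best_d)
}

# small random annotation/segment instances for randomized checks
random_segment_instance <- function(seed, n_genes = 30, n_segs = 8) {
  set.seed(seed)
  starts <- sort(sample.int(5000, n_genes))
  genes <- tibble::tibble(
    gene_id = sprintf("g%03d", seq_len(n_genes)),
    chrom = "chr1",
    start = starts,
    end = starts + sample.int(80, n_genes)
  )
  bounds <- sort(sample.int(6000, n_segs + 1))
  # random gaps: drop a couple of segments so some genes need the fallback
  keep <- sort(sample(seq_len(n_segs), max(2, n_segs - 2)))
  segs <- tibble::tibble(
    sample = "s1", chrom = "chr1",
    start = bounds[keep], end = bounds[keep + 1],
    value = round(stats::rnorm(length(keep)), 3)
  )
  list(genes = genes, segments = segs)
}

random_ranking <- function(seed, n, label = "x") {
  set.seed(seed)
  sc <- score_table(sprintf("g%04d", sample.int(9999, n)), stats::runif(n), label)
  rank_genes(sc)
}
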