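#' Build a per-dataset strategy ranking
#'
#' One dataset's ordering of prioritization strategies, best first, together
#' with the importance weight of each strategy (its mean PPV in that dataset).
#'
#' @param dataset Dataset identifier.
#' @param strategies Character vector of strategy labels, best first.
#' @param weights Non-negative weights, one per strategy (mean PPV values).
#' @return A tibble with columns `dataset`, `strategy`, `rank`, `weight`.
#' @export
strategy_ranking <- function(dataset, strategies, weights) {
  if (anyDuplicated(strategies)) {
    stop_priorank("Each strategy may appear once per dataset ranking.",
                  "priorank_error_aggregation")
  }
  if (length(weights) != length(strategies) || any(is.na(weights)) ||
      any(weights < 0)) {
    stop_priorank("Weights must be non-negative, one per strategy.",
                  "priorank_error_aggregation")
  }
  tibble(dataset = dataset, strategy = as.character(strategies),
         rank = seq_along(strategies), weight = as.numeric(weights))
}

check_observed_rankings <- function(observed) {
  need <- c("dataset", "strategy", "rank", "weight")
  if (!all(need %in% names(observed))) {
    stop_priorank("Observed rankings need columns dataset, strategy, rank, weight.",
                  "priorank_error_aggregation")
  }
  sets <- split(observed$strategy, observed$dataset)
  items <- sort(unique(observed$strategy))
  ok <- vapply(sets, function(s) identical(sort(s), items), logical(1))
  if (!all(ok)) {
    stop_priorank(
      paste0("Datasets rank inconsistent strategy sets: ",
             paste(names(sets)[!ok], collapse = ", ")),
      "priorank_error_aggregation"
    )
  }
  items
}

#' Weighted Spearman footrule distance of a candidate ordering
#'
#' The objective of the brute-force rank aggregation: for every dataset and
#' strategy, the absolute difference between the strategy's position in the
#' candidate ordering and its observed position, multiplied by the strategy's
#' importance weight in that dataset, summed over everything.
#'
#' @param candidate Character vector, an ordering of all strategies.
#' @param observed Per-dataset rankings (rows of [strategy_ranking()] tibbles,
#'   bound together).
#' @return The weighted footrule distance (non-negative scalar).
#' @export
weighted_footrule <- function(candidate, observed) {
  items <- check_observed_rankings(observed)
  if (!identical(sort(as.character(candidate)), items)) {
    stop_priorank("Candidate must order exactly the observed strategy set.",
                  "priorank_error_aggregation")
  }
  pos <- setNames(seq_along(candidate), candidate)
  sum(observed$weight * abs(pos[observed$strategy] - observed$rank))
}

# all permutations of seq_len(n) in lexicographic row order
permutations_lex <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_lex(n - 1L)
  blocks <- lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  })
  do.call(rbind, blocks)
}

footrule_all_perms <- function(perms, observed, items) {
  n_perm <- nrow(perms); k <- ncol(perms)
  # position of item j in permutation i
  pos <- matrix(0L, n_perm, k)
  pos[cbind(rep(seq_len(n_perm), k), as.vector(perms))] <-
    rep(seq_len(k), each = n_perm)
  d <- numeric(n_perm)
  for (ds in split(observed, observed$dataset)) {
    obs_pos <- setNames(ds$rank, ds$strategy)[items]
    w <- setNames(ds$weight, ds$strategy)[items]
    d <- d + abs(pos - rep(obs_pos, each = n_perm)) %*% w
  }
  as.numeric(d)
}

#' Aggregate per-dataset strategy rankings into a consensus
#'
#' Finds the ordering of strategies minimizing the [weighted_footrule()]
#' distance to the observed per-dataset rankings. For eight or fewer
#' strategies the optimum is found by exhaustive enumeration (ties resolved
#' toward the lexicographically smallest ordering); for more, a seeded
#' cross-entropy Monte-Carlo search is used, initialized so the result is
#' never worse than the best observed ranking.
#'
#' @param observed Per-dataset rankings ([strategy_ranking()] rows).
#' @param mode `"auto"` (exhaustive up to 8 strategies), `"exhaustive"` or
#'   `"heuristic"`.
#' @param seed Integer seed for the heuristic search (the caller's RNG state
#'   is preserved).
#' @param ce_samples,ce_iter,elite_frac,smoothing Cross-entropy tuning knobs:
#'   sample size per iteration, iteration count, elite fraction, and the
#'   weight of the new elite frequencies in the probability-matrix update.
#' @return An object of class `priorank_consensus` with the consensus
#'   `ordering`, its `distance`, the search `mode`, and per-dataset distances.
#' @export
aggregate_rankings <- function(observed,
                               mode = c("auto", "exhaustive", "heuristic"),
                               seed = 1L,
                               ce_samples = 200L, ce_iter = 60L,
                               elite_frac = 0.1, smoothing = 0.7) {
  mode <- match.arg(mode)
  items <- check_observed_rankings(observed)
  k <- length(items)
  if (mode == "auto") mode <- if (k <= 8) "exhaustive" else "heuristic"
  if (mode == "exhaustive" && k > 8) {
    stop_priorank("Exhaustive search is limited to 8 strategies.",
                  "priorank_error_aggregation")
  }

  if (mode == "exhaustive") {
    perms <- permutations_lex(k)
    d <- footrule_all_perms(perms, observed, items)
    best <- which.min(d)   # first minimum = lexicographically smallest
    ordering <- items[perms[best, ]]
    distance <- d[best]
  } else {
    res <- ce_search(observed, items, seed, ce_samples, ce_iter,
                     elite_frac, smoothing)
    ordering <- res$ordering
    distance <- res$distance
  }

  per_dataset <- observed |>
    dplyr::group_by(.data$dataset) |>
    dplyr::summarise(
      own_distance = weighted_footrule_one(
        setNames(seq_along(ordering), ordering), .data$strategy, .data$rank,
        .data$weight),
      .groups = "drop"
    )
  structure(
    list(ordering = ordering, distance = distance, mode = mode,
         items = items, n_datasets = length(unique(observed$dataset)),
         per_dataset = per_dataset),
    class = "priorank_consensus"
  )
}

weighted_footrule_one <- function(pos, strategy, rank, weight) {
  sum(weight * abs(pos[strategy] - rank))
}

ce_search <- function(observed, items, seed, n_samples, n_iter,
                      elite_frac, smoothing) {
  k <- length(items)
  obs_split <- split(observed, observed$dataset)
  obs_pos <- lapply(obs_split, function(ds) setNames(ds$rank, ds$strategy)[items])
  obs_w <- lapply(obs_split, function(ds) setNames(ds$weight, ds$strategy)[items])
  dist_of <- function(perm) {   # perm: integer vector, item index per position
    pos <- integer(k); pos[perm] <- seq_len(k)
    s <- 0
    for (i in seq_along(obs_pos)) {
      s <- s + sum(obs_w[[i]] * abs(pos - obs_pos[[i]]))
    }
    s
  }
  # seed pool: every observed ordering (guarantees "never worse than observed")
  start_perms <- lapply(obs_split, function(ds) {
    match(ds$strategy[order(ds$rank)], items)
  })
  best_perm <- start_perms[[1]]
  best_d <- dist_of(best_perm)
  for (p in start_perms[-1]) {
    d <- dist_of(p)
    if (d < best_d) { best_d <- d; best_perm <- p }
  }
  with_preserved_seed(seed, {
    prob <- matrix(1 / k, k, k)   # prob[item, position]
    n_elite <- max(2L, ceiling(elite_frac * n_samples))
    for (iter in seq_len(n_iter)) {
      samples <- matrix(0L, n_samples, k)
      dists <- numeric(n_samples)
      for (s in seq_len(n_samples)) {
        perm <- integer(k)
        avail <- rep(TRUE, k)
        for (j in seq_len(k)) {
          p <- prob[, j] * avail
          tot <- sum(p)
          perm[j] <- if (tot <= 0) {
            which(avail)[sample.int(sum(avail), 1L)]
          } else {
            sample.int(k, 1L, prob = p / tot)
          }
          avail[perm[j]] <- FALSE
        }
        samples[s, ] <- perm
        dists[s] <- dist_of(perm)
        if (dists[s] < best_d) { best_d <- dists[s]; best_perm <- perm }
      }
      elite <- samples[order(dists)[seq_len(n_elite)], , drop = FALSE]
      freq <- matrix(0, k, k)
      for (j in seq_len(k)) {
        tab <- tabulate(elite[, j], nbins = k)
        freq[, j] <- tab / n_elite
      }
      prob <- (1 - smoothing) * prob + smoothing * freq
    }
  })
  list(ordering = items[best_perm], distance = best_d)
}

#' @export
print.priorank_consensus <- function(x, ...) {
  cat("<priorank_consensus> ", length(x$items), " strategies, ",
      x$n_datasets, " datasets (", x$mode, " search)\n", sep = "")
  cat("  consensus (best first): ", paste(x$ordering, collapse = " > "),
      "\n  weighted footrule distance: ", format(x$distance), "\n", sep = "")
  invisible(x)
}
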