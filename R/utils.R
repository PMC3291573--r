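stop_priorank <- function(message, class) {
  abort(message, class = c(class, "priorank_error"))
}

# deterministic, locale-independent ordering: score descending, then gene id
# ascending (C-locale byte order via the radix method)
order_desc_score <- function(score, gene_id) {
  order(score, gene_id, method = "radix", decreasing = c(TRUE, FALSE))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_priorank(sprintf("`%s` must be a single number.", name),
                  "priorank_error_argument")
  }
  if (x < lower || x > upper) {
    stop_priorank(
      sprintf("`%s` must be in [%s, %s], got %s.", name,
              format(lower), format(upper), format(x)),
      "priorank_error_argument"
    )
  }
  invisible(x)
}

assert_count <- function(x, name, lower = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < lower) {
    stop_priorank(sprintf("`%s` must be an integer >= %d.", name, lower),
                  "priorank_error_argument")
  }
  invisible(as.integer(x))
}

# run code with a private RNG state seeded from `seed`, restoring the caller's
# state afterwards
with_preserved_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

#' Format a proportion as a printed percentage
#'
#' Rounds half-up (so 2/7 prints as `"28.6%"`), matching the usual convention
#' for reporting mutation rates.
#'
#' @param x Numeric vector of proportions in \[0, 1\].
#' @param digits Number of decimal places (default 1).
#' @return Character vector like `"28.6%"`.
#' @examples
#' format_percent(2 / 7)
#' @export
format_percent <- function(x, digits = 1) {
  scale <- 10^digits
  pct <- floor(x * 100 * scale + 0.5) / scale
  paste0(formatC(pct, format = "f", digits = digits), "%")
}
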