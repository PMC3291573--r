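#' Read a gene annotation table
#'
#' Reads per-gene genomic coordinates, the join key across the expression,
#' copy-number and mutation layers. Two dialects are accepted: a headered TSV
#' with columns `gene_id`, `chrom`, `start`, `end`, or a 4-column BED file
#' (`chrom`, `start`, `end`, `name`). Coordinates are stored 0-based half-open;
#' BED input already uses that convention, while a 1-based TSV can be declared
#' with `one_based = TRUE` and is converted at the boundary.
#'
#' @param path Path to the file.
#' @param format `"auto"` (by file extension), `"tsv"` or `"bed"`.
#' @param one_based Set `TRUE` if a TSV input uses 1-based inclusive starts.
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`.
#' @export
read_gene_annotation <- function(path, format = c("auto", "tsv", "bed"),
                                 one_based = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "tsv"
  }
  if (format == "bed") {
    x <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "gene_id"),
                         col_types = "ciic", progress = FALSE)
    x <- x[, c("gene_id", "chrom", "start", "end")]
  } else {
    x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    need <- c("gene_id", "chrom", "start", "end")
    if (!all(need %in% names(x))) {
      stop_priorank(
        paste0("Annotation TSV must have columns gene_id, chrom, start, end; found: ",
               paste(names(x), collapse = ", ")),
        "priorank_error_format"
      )
    }
    x <- x[, need]
    if (one_based) x$start <- x$start - 1L
  }
  validate_gene_annotation(as_tibble(x))
}

validate_gene_annotation <- function(x) {
  dup <- unique(x$gene_id[duplicated(x$gene_id)])
  if (length(dup) > 0) {
    stop_priorank(
      paste0("Duplicate gene_id in annotation: ",
             paste(head(dup, 5), collapse = ", ")),
      "priorank_error_duplicate_gene"
    )
  }
  bad <- which(!(x$start < x$end) | x$start < 0)
  if (length(bad) > 0) {
    stop_priorank(
      paste0("Malformed coordinates (need 0 <= start < end) at rows: ",
             paste(head(bad, 10), collapse = ", ")),
      "priorank_error_coordinates"
    )
  }
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  x
}

#' Write a gene annotation table as TSV
#'
#' @param x Annotation tibble (`gene_id`, `chrom`, `start`, `end`), 0-based
#'   half-open.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(x, path) {
  readr::write_tsv(x[, c("gene_id", "chrom", "start", "end")], path,
                   progress = FALSE)
  invisible(path)
}

#' Read segmented copy-number profiles (SEG dialect)
#'
#' Reads the piecewise-constant segment values produced by a segmentation
#' algorithm such as circular binary segmentation (CBS). Column names follow
#' either the SEG convention (`ID`/`sample`, `chrom`, `loc.start`, `loc.end`,
#' `seg.mean`) or plain `sample`, `chrom`, `start`, `end`, `value`. Segments
#' must not overlap within a sample and chromosome.
#'
#' @param path Path to the file.
#' @param one_based Set `TRUE` if the file uses 1-based inclusive starts.
#' @return A tibble with columns `sample`, `chrom`, `start`, `end`, `value`
#'   (log-ratio units), sorted by sample, chromosome, start.
#' @export
read_segments <- function(path, one_based = FALSE) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  nm <- tolower(names(x))
  pick <- function(...) {
    for (cand in c(...)) {
      i <- match(cand, nm)
      if (!is.na(i)) return(i)
    }
    NA_integer_
  }
  idx <- c(sample = pick("sample", "id", "sample_id"),
           chrom = pick("chrom", "chromosome", "chr"),
           start = pick("start", "loc.start", "loc_start"),
           end = pick("end", "loc.end", "loc_end"),
           value = pick("value", "seg.mean", "seg_mean", "cbs"))
  if (anyNA(idx)) {
    stop_priorank(
      paste0("SEG file must provide sample/chrom/start/end/value columns; found: ",
             paste(names(x), collapse = ", ")),
      "priorank_error_format"
    )
  }
  x <- setNames(x[, idx], names(idx))
  if (one_based) x$start <- x$start - 1L
  validate_segments(as_tibble(x))
}

validate_segments <- function(x) {
  if (any(!(x$start < x$end) | x$start < 0)) {
    stop_priorank("Segments need 0 <= start < end.", "priorank_error_coordinates")
  }
  x <- dplyr::arrange(x, .data$sample, .data$chrom, .data$start)
  overlap <- x |>
    dplyr::group_by(.data$sample, .data$chrom) |>
    dplyr::filter(dplyr::row_number() > 1 &
                    .data$start < dplyr::lag(.data$end)) |>
    dplyr::ungroup()
  if (nrow(overlap) > 0) {
    stop_priorank(
      paste0("Overlapping segments in sample ", overlap$sample[1],
             ", chromosome ", overlap$chrom[1], "."),
      "priorank_error_overlap"
    )
  }
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  x
}

#' Write segmented copy-number profiles as SEG
#'
#' @param x Segment tibble (`sample`, `chrom`, `start`, `end`, `value`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(x, path) {
  out <- x[, c("sample", "chrom", "start", "end", "value")]
  names(out) <- c("sample", "chrom", "loc.start", "loc.end", "seg.mean")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a logged gene-expression matrix
#'
#' The file is a TSV whose first column is `gene_id` and remaining columns are
#' samples. Values are expected to be already on a log scale (the microarray
#' convention); a raw matrix can be transformed at the boundary by supplying
#' `log2_offset`, which applies `log2(x + offset)`.
#'
#' @param path Path to the file.
#' @param missing How to treat missing cells: `"error"` (default) or
#'   `"row_mean"` imputation.
#' @param log2_offset If non-`NULL`, apply `log2(x + log2_offset)` to all
#'   values (use for raw intensity matrices; typical offset 1).
#' @return A tibble with `gene_id` and one numeric column per sample.
#' @export
read_expression <- function(path, missing = c("error", "row_mean"),
                            log2_offset = NULL) {
  missing <- match.arg(missing)
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(x)[1] != "gene_id") names(x)[1] <- "gene_id"
  if (ncol(x) < 2) {
    stop_priorank("Expression table needs at least one sample column.",
                  "priorank_error_format")
  }
  dup <- unique(x$gene_id[duplicated(x$gene_id)])
  if (length(dup) > 0) {
    stop_priorank(paste0("Duplicate gene_id in expression matrix: ",
                         paste(head(dup, 5), collapse = ", ")),
                  "priorank_error_duplicate_gene")
  }
  vals <- as.matrix(x[, -1])
  storage.mode(vals) <- "double"
  if (anyNA(vals)) {
    if (missing == "error") {
      stop_priorank("Expression matrix contains missing values.",
                    "priorank_error_missing_values")
    }
    rm_ <- rowMeans(vals, na.rm = TRUE)
    idx <- which(is.na(vals), arr.ind = TRUE)
    vals[idx] <- rm_[idx[, 1]]
  }
  if (!is.null(log2_offset)) {
    assert_scalar_number(log2_offset, "log2_offset", lower = 0)
    vals <- log2(vals + log2_offset)
  }
  dplyr::bind_cols(tibble(gene_id = x$gene_id), as_tibble(vals))
}

#' Write an expression matrix as TSV
#'
#' @param x Expression tibble (`gene_id` plus sample columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Construct a mutation set
#'
#' A mutation screen is summarized by the identifiers of the genes found
#' somatically mutated and the total number of genes sequenced, which together
#' define the baseline positive predictive value (PPV) of unprioritized
#' sequencing.
#'
#' @param mutated_genes Character vector of mutated gene ids (de-duplicated).
#' @param n_genes_sequenced Total number of genes sequenced in the screen.
#' @param universe Optional character vector of all sequenced gene ids; when
#'   supplied, mutated genes must be a subset and its length must equal
#'   `n_genes_sequenced`.
#' @param n_samples_mutated Optional named integer vector giving, per mutated
#'   gene, the number of samples in which it was mutated.
#' @return An object of class `priorank_mutations`.
#' @export
mutation_set <- function(mutated_genes, n_genes_sequenced, universe = NULL,
                         n_samples_mutated = NULL) {
  mutated_genes <- unique(as.character(mutated_genes))
  n_genes_sequenced <- assert_count(n_genes_sequenced, "n_genes_sequenced")
  if (length(mutated_genes) > n_genes_sequenced) {
    stop_priorank("More mutated genes than genes sequenced.",
                  "priorank_error_mutations")
  }
  if (!is.null(universe)) {
    universe <- unique(as.character(universe))
    if (length(universe) != n_genes_sequenced) {
      stop_priorank("`universe` length must equal `n_genes_sequenced`.",
                    "priorank_error_mutations")
    }
    if (!all(mutated_genes %in% universe)) {
      stop_priorank("Mutated genes must be a subset of the sequenced universe.",
                    "priorank_error_mutations")
    }
  }
  structure(
    list(mutated_genes = mutated_genes,
         n_genes_sequenced = n_genes_sequenced,
         universe = universe,
         n_samples_mutated = n_samples_mutated),
    class = "priorank_mutations"
  )
}

#' @export
print.priorank_mutations <- function(x, ...) {
  cat("<priorank_mutations> ", length(x$mutated_genes), " mutated of ",
      x$n_genes_sequenced, " genes sequenced (baseline PPV ",
      format_percent(baseline_ppv(x)), ")\n", sep = "")
  invisible(x)
}

#' Read a mutation screen file
#'
#' The file is a TSV with a `gene_id` column (optionally `n_samples`) listing
#' the mutated genes, preceded by a comment header line of the form
#' `# n_genes_sequenced=18000` giving the size of the sequenced gene set.
#'
#' @param path Path to the file.
#' @return A [mutation_set()].
#' @export
read_mutations <- function(path) {
  header <- readLines(path, n = 5L)
  hl <- grep("^#.*n_genes_sequenced\\s*=", header, value = TRUE)
  if (length(hl) == 0) {
    stop_priorank("Mutation file must carry a '# n_genes_sequenced=<int>' header line.",
                  "priorank_error_format")
  }
  n_seq <- as.integer(sub(".*n_genes_sequenced\\s*=\\s*(\\d+).*", "\\1", hl[1]))
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE)
  if (!"gene_id" %in% names(x)) names(x)[1] <- "gene_id"
  counts <- NULL
  if ("n_samples" %in% names(x)) {
    counts <- setNames(as.integer(x$n_samples), x$gene_id)
  }
  mutation_set(x$gene_id, n_seq, n_samples_mutated = counts)
}

#' Write a mutation screen file
#'
#' @param mut A [mutation_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mutations <- function(mut, path) {
  out <- tibble(gene_id = mut$mutated_genes)
  if (!is.null(mut$n_samples_mutated)) {
    out$n_samples <- as.integer(mut$n_samples_mutated[out$gene_id])
  }
  body <- readr::format_tsv(out)
  writeLines(c(sprintf("# n_genes_sequenced=%d", mut$n_genes_sequenced),
               sub("\n$", "", body)), path)
  invisible(path)
}

#' Read a fitSNP DER table
#'
#' The differential expression ratio (DER) of a gene is the fraction of
#' expression studies in which it was called differentially expressed among
#' the studies in which it was evaluated; values lie in \[0, 1\] and are
#' consumed as a lookup table, never recomputed.
#'
#' @param path Path to a TSV with columns `gene_id` and `der`.
#' @return A tibble with columns `gene_id`, `der`.
#' @export
read_der_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("gene_id", "der") %in% names(x))) {
    stop_priorank("DER table must have columns gene_id and der.",
                  "priorank_error_format")
  }
  x <- x[, c("gene_id", "der")]
  if (any(is.na(x$der)) || any(x$der < 0 | x$der > 1)) {
    stop_priorank("DER values must lie in [0, 1].", "priorank_error_der_range")
  }
  dup <- unique(x$gene_id[duplicated(x$gene_id)])
  if (length(dup) > 0) {
    stop_priorank(paste0("Duplicate gene_id in DER table: ",
                         paste(head(dup, 5), collapse = ", ")),
                  "priorank_error_duplicate_gene")
  }
  as_tibble(x)
}

#' Write a fitSNP DER table as TSV
#'
#' @param x Tibble with columns `gene_id`, `der`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_der_table <- function(x, path) {
  readr::write_tsv(x[, c("gene_id", "der")], path, progress = FALSE)
  invisible(path)
}
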