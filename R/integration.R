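# Tri-pronged evidence integration: three-way gene-set intersection and
# hypergeometric over-representation of flat annotation terms.

#' Three-way evidence intersection
#'
#' Intersects the three evidence prongs of the workflow - genes
#' downregulated upon miRNA overexpression, genes downregulated during
#' differentiation, and sequence-predicted targets - after normalizing
#' gene symbols to upper case. The common set is the candidate bona fide
#' target list.
#'
#' @param overexpression_down,differentiation_down,predicted_targets
#'   character vectors of gene ids (one shared namespace; case is
#'   normalized).
#' @return object of class `tri_prong_result`: the three normalized sets,
#'   `common` (sorted three-way intersection) and `pairwise_overlaps`
#'   (named counts `ab`, `ac`, `bc`).
#' @export
tri_prong_intersect <- function(overexpression_down, differentiation_down,
                                predicted_targets) {
  norm <- function(x) sort(unique(toupper(as.character(x))))
  a <- norm(overexpression_down)
  b <- norm(differentiation_down)
  c_ <- norm(predicted_targets)
  structure(list(
    overexpression_down = a,
    differentiation_down = b,
    predicted_targets = c_,
    common = sort(intersect(intersect(a, b), c_)),
    pairwise_overlaps = c(ab = length(intersect(a, b)),
                          ac = length(intersect(a, c_)),
                          bc = length(intersect(b, c_)))),
    class = "tri_prong_result")
}

#' @export
print.tri_prong_result <- function(x, ...) {
  cat("Tri-pronged evidence intersection\n")
  cat(sprintf("  overexpression-down : %d genes\n", length(x$overexpression_down)))
  cat(sprintf("  differentiation-down: %d genes\n", length(x$differentiation_down)))
  cat(sprintf("  predicted targets   : %d genes\n", length(x$predicted_targets)))
  cat(sprintf("  common (3-way)      : %d genes\n", length(x$common)))
  invisible(x)
}

#' Expected chance size of a three-way intersection
#'
#' Under independent uniform draws from a universe of size `n_universe`,
#' the expected three-way overlap is `|a| * |b| * |c| / n_universe^2`.
#' Useful as the null reference for [tri_prong_intersect()].
#'
#' @param n_a,n_b,n_c set sizes.
#' @param n_universe universe size.
#' @return expected common-set size (numeric).
#' @export
tri_prong_expected <- function(n_a, n_b, n_c, n_universe) {
  n_a * n_b * n_c / n_universe^2
}

#' Hypergeometric over-representation of annotation terms
#'
#' For each term (a flat gene set), tests whether the query is enriched
#' for the term's genes with the one-sided upper-tail hypergeometric test,
#' the standard re-implementation of functional-annotation
#' over-representation tools. Benjamini-Hochberg FDR is computed across
#' terms.
#'
#' @param query character vector of gene ids (must be contained in
#'   `universe`).
#' @param annotation named list mapping term id to a character vector of
#'   member genes (each contained in `universe`).
#' @param universe character vector of background gene ids (typically all
#'   genes on the array).
#' @return data frame sorted by ascending P (ties by term): `term`,
#'   `overlap`, `term_size`, `expected`, `fold_enrichment`, `p`, `fdr`.
#' @export
hypergeom_enrich <- function(query, annotation, universe) {
  universe <- unique(toupper(as.character(universe)))
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  query <- unique(toupper(as.character(query)))
  if (!all(query %in% universe)) {
    stop("query genes outside the universe: ",
         paste(utils::head(setdiff(query, universe), 5), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(names(annotation)) && length(annotation)) {
    stop("annotation must be a named list of term gene sets", call. = FALSE)
  }
  rows <- lapply(names(annotation), function(term) {
    genes <- unique(toupper(as.character(annotation[[term]])))
    if (!all(genes %in% universe)) {
      stop("term '", term, "' has genes outside the universe", call. = FALSE)
    }
    k <- length(intersect(query, genes))
    expected <- length(query) * length(genes) / length(universe)
    data.frame(term = term, overlap = k, term_size = length(genes),
               expected = expected,
               fold_enrichment = if (expected > 0) k / expected else NA_real_,
               p = stats::phyper(k - 1, length(genes),
                                 length(universe) - length(genes),
                                 length(query), lower.tail = FALSE))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(term = character(0), overlap = integer(0),
                      term_size = integer(0), expected = numeric(0),
                      fold_enrichment = numeric(0), p = numeric(0),
                      fdr = numeric(0)))
  }
  out$fdr <- bh_adjust(out$p)
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read / write gene-set files
#'
#' Gene lists are newline-delimited id files; annotation term sets use the
#' GMT format (term, description, then member genes, tab-separated).
#' GMT reading goes through [fgsea::gmtPathways()].
#'
#' @param path file path.
#' @return `read_gene_list()`: character vector. `read_gmt()`: named list
#'   of character vectors.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x[nzchar(trimws(x))]
}

#' @param genes character vector of gene ids.
#' @rdname read_gene_list
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

#' @rdname read_gene_list
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @param sets named list of character vectors (term gene sets).
#' @rdname read_gene_list
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(term) {
    paste(c(term, term, sets[[term]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
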