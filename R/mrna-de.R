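# One-channel expression matrices: percentile-shift normalization and the
# fold-change / t-test downregulation screens.

#' One-channel expression matrix container
#'
#' @param values numeric matrix of log2 expression (genes x samples),
#'   finite throughout.
#' @param condition character vector, one condition label per sample.
#' @param gene_ids,sample_ids optional ids; default to dimnames.
#' @return an object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, condition,
                              gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(gene_ids)) gene_ids <- sprintf("gene_%04d", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- sprintf("sample_%02d", seq_len(ncol(values)))
  if (length(condition) != ncol(values) || anyNA(condition)) {
    stop("need one non-missing condition label per sample", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("expression values must be finite", call. = FALSE)
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(list(gene_ids = gene_ids, sample_ids = sample_ids,
                 values = values, condition = as.character(condition)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%s)\n",
              length(x$gene_ids), length(x$sample_ids),
              paste(sprintf("%s x%d", names(table(x$condition)),
                            as.integer(table(x$condition))), collapse = ", ")))
  invisible(x)
}

#' Percentile-shift normalization
#'
#' Subtracts from every sample its own `percentile`-th percentile of log2
#' expression, so that afterwards each sample's chosen percentile is
#' exactly 0 (the GeneSpring convention; the 75th percentile is the usual
#' choice).
#'
#' @param mat an [expression_matrix()].
#' @param percentile percentile rank in (0, 100).
#' @return a normalized [expression_matrix()].
#' @export
percentile_shift_normalize <- function(mat, percentile = 75) {
  stopifnot(inherits(mat, "expression_matrix"))
  if (!is.numeric(percentile) || length(percentile) != 1L ||
      percentile <= 0 || percentile >= 100) {
    stop("percentile must lie strictly between 0 and 100", call. = FALSE)
  }
  shifts <- apply(mat$values, 2, stats::quantile, probs = percentile / 100,
                  names = FALSE)
  expression_matrix(sweep(mat$values, 2, shifts), condition = mat$condition)
}

#' Fold-change / t-test differential-expression screen
#'
#' Per gene, a two-sample two-tailed t-test (pooled variance by default)
#' of treatment versus control plus a linear fold-change gate. A gene is
#' retained when its raw P is below `alpha` *and* its linear fold change
#' passes `fc_thresh` in the requested direction ("down" means linear
#' fold `<= 1/fc_thresh`, i.e. log2 fold change `<= -log2(fc_thresh)`).
#' Benjamini-Hochberg FDR values are attached for all genes for
#' reporting; the retention gate itself uses the raw P.
#'
#' @param mat an [expression_matrix()].
#' @param treat,ctrl condition labels of the treatment and control arms.
#' @param fc_thresh linear fold-change threshold (>= 1).
#' @param alpha raw P-value threshold.
#' @param direction one of `"down"`, `"up"`, `"both"`.
#' @param var_equal pooled-variance t-test (default); `FALSE` for Welch.
#' @return data frame with one row per gene: `gene_id`, `log2fc`
#'   (treatment minus control), `p`, `fdr`, `retained`; sorted by
#'   ascending P (ties by gene id).
#' @export
de_screen <- function(mat, treat, ctrl, fc_thresh = 1.3, alpha = 0.05,
                      direction = c("down", "up", "both"), var_equal = TRUE) {
  stopifnot(inherits(mat, "expression_matrix"))
  direction <- match.arg(direction)
  if (fc_thresh < 1) stop("fc_thresh must be >= 1 (linear fold)", call. = FALSE)
  if (!all(c(treat, ctrl) %in% mat$condition)) {
    stop("unknown condition label(s): ",
         paste(setdiff(c(treat, ctrl), mat$condition), collapse = ", "),
         call. = FALSE)
  }
  x <- mat$values[, mat$condition == treat, drop = FALSE]
  y <- mat$values[, mat$condition == ctrl, drop = FALSE]
  if (ncol(x) < 2L || ncol(y) < 2L) {
    stop(">= 2 samples per condition required", call. = FALSE)
  }
  tt <- pooled_t_rows(x, y, var_equal = var_equal)
  log2fc <- tt$estimate
  thr <- log2(fc_thresh)
  pass_fc <- switch(direction,
                    down = log2fc <= -thr,
                    up = log2fc >= thr,
                    both = abs(log2fc) >= thr)
  out <- data.frame(gene_id = mat$gene_ids, log2fc = log2fc, p = tt$p,
                    fdr = bh_adjust(tt$p),
                    retained = tt$p < alpha & pass_fc,
                    row.names = NULL)
  out <- out[order(out$p, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Retained gene ids of a screen
#'
#' @param screen a data frame as returned by [de_screen()].
#' @return sorted character vector of retained gene ids.
#' @export
screen_hits <- function(screen) {
  stopifnot(all(c("gene_id", "retained") %in% names(screen)))
  sort(screen$gene_id[screen$retained])
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Standard step-up procedure (monotone in the P-value ranks, capped at
#' 1); a thin, validating wrapper over [stats::p.adjust()].
#'
#' @param pvals numeric vector of raw P-values in `[0, 1]`.
#' @return FDR-adjusted values (same order).
#' @export
bh_adjust <- function(pvals) {
  check_pvalues(pvals)
  stats::p.adjust(pvals, method = "BH")
}

#' Read / write expression matrix TSVs
#'
#' Gene x sample TSV (`gene_id` column then one column per sample) with a
#' `sample_id`/`condition` design sidecar.
#'
#' @param path expression TSV path.
#' @param design_path design sidecar path.
#' @return `read_expression_tsv()`: an [expression_matrix()].
#' @export
read_expression_tsv <- function(path, design_path) {
  tab <- read_tsv(path)
  design <- read_tsv(design_path)
  stopifnot("gene_id" %in% names(tab),
            all(c("sample_id", "condition") %in% names(design)))
  vals <- as.matrix(tab[design$sample_id])
  rownames(vals) <- tab$gene_id
  expression_matrix(vals, condition = design$condition)
}

#' @param mat an [expression_matrix()].
#' @rdname read_expression_tsv
#' @export
write_expression_tsv <- function(mat, path, design_path) {
  stopifnot(inherits(mat, "expression_matrix"))
  write_tsv(cbind(data.frame(gene_id = mat$gene_ids),
                  as.data.frame(mat$values)), path)
  write_tsv(data.frame(sample_id = mat$sample_ids, condition = mat$condition),
            design_path)
  invisible(path)
}
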