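# Two-channel miRNA array normalization and time-course differential
# expression: global Lowess on MA coordinates, per-probe one-way ANOVA,
# Bonferroni family-wise correction, Tukey HSD post-hoc.

#' Global Lowess normalization of two-channel log ratios
#'
#' For each sample, computes M = log2(Hy3/Hy5) and A = 0.5*log2(Hy3*Hy5)
#' over all probes and subtracts a robust locally weighted (degree-1)
#' regression of M on A, removing intensity-dependent dye bias. This is
#' the classical global (all-spots) MA-plot normalization for spotted
#' two-colour arrays.
#'
#' @param arr a [two_channel_array()].
#' @param span Lowess smoother span (fraction of points; in (0, 1]).
#' @param iter robustness iterations of the Lowess fit.
#' @return matrix of normalized log2 ratios (probes x samples) with the
#'   per-sample timepoint labels attached as attribute `"timepoint"`.
#' @export
lowess_normalize <- function(arr, span = 0.3, iter = 3L) {
  stopifnot(inherits(arr, "two_channel_array"))
  if (!is.numeric(span) || length(span) != 1L || span <= 0 || span > 1) {
    stop("span must lie in (0, 1]", call. = FALSE)
  }
  m <- log2(arr$hy3) - log2(arr$hy5)
  a <- (log2(arr$hy3) + log2(arr$hy5)) / 2
  norm <- m
  for (j in seq_len(ncol(m))) {
    fit <- stats::lowess(a[, j], m[, j], f = span, iter = iter)
    trend <- stats::approx(fit$x, fit$y, xout = a[, j], rule = 2,
                           ties = mean)$y
    norm[, j] <- m[, j] - trend
  }
  attr(norm, "timepoint") <- arr$timepoint
  norm
}

#' Per-probe one-way fixed-effects ANOVA
#'
#' Classical one-way ANOVA F-test applied independently to every row of a
#' normalized ratio matrix. When a probe has zero between-group and zero
#' within-group variance (all observations identical) its P-value is 1 by
#' convention; zero within-group variance with a real group difference
#' gives P = 0.
#'
#' @param m numeric matrix (probes x samples) of normalized log2 ratios.
#' @param groups group label per sample (e.g. timepoints).
#' @return named numeric vector of raw P-values, one per probe.
#' @export
anova_per_probe <- function(m, groups) {
  m <- as.matrix(m)
  groups <- as.factor(groups)
  if (length(groups) != ncol(m)) {
    stop("need one group label per sample", call. = FALSE)
  }
  if (nlevels(droplevels(groups)) < 2L) stop(">= 2 groups required", call. = FALSE)
  groups <- droplevels(groups)
  sizes <- table(groups)
  if (any(sizes < 2L)) stop(">= 2 samples per group required", call. = FALSE)
  k <- nlevels(groups)
  n <- ncol(m)

  gm <- rowMeans(m)
  group_means <- t(rowsum(t(m), groups) / as.vector(sizes)) # probes x k
  ssb <- as.vector((group_means - gm)^2 %*% as.vector(sizes))
  centered <- m - group_means[, as.integer(groups), drop = FALSE]
  ssw <- rowSums(centered^2)

  f <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- stats::pf(f, k - 1, n - k, lower.tail = FALSE)
  p[ssw == 0 & ssb == 0] <- 1
  p[ssw == 0 & ssb > 0] <- 0
  names(p) <- rownames(m)
  p
}

#' Bonferroni family-wise adjustment
#'
#' `adj_i = min(1, m * p_i)` with `m` the number of tests; a thin,
#' validating wrapper over [stats::p.adjust()].
#'
#' @param pvals numeric vector of raw P-values in `[0, 1]`.
#' @return adjusted P-values (same order).
#' @export
bonferroni_adjust <- function(pvals) {
  check_pvalues(pvals)
  stats::p.adjust(pvals, method = "bonferroni")
}

check_pvalues <- function(pvals) {
  if (!is.numeric(pvals)) stop("P-values must be numeric", call. = FALSE)
  if (any(!is.na(pvals) & (pvals < 0 | pvals > 1))) {
    stop("P-values must lie in [0, 1]", call. = FALSE)
  }
  invisible(TRUE)
}

#' Tukey Honest Significant Difference post-hoc test
#'
#' All-pairs comparisons for one probe's values, with studentized-range
#' adjusted P-values (family-wise level equals the nominal alpha). Wraps
#' [stats::TukeyHSD()] on a one-way [stats::aov()] fit.
#'
#' @param values numeric vector of one probe's normalized ratios.
#' @param groups group label per value.
#' @return data frame with columns `pair` (e.g. `"D13-D0"`), `mean_diff`
#'   and `adjusted_p`, one row per unordered group pair.
#' @export
tukey_hsd <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  if (length(values) != length(groups)) {
    stop("values and groups must have equal length", call. = FALSE)
  }
  if (nlevels(groups) < 2L) stop(">= 2 groups required", call. = FALSE)
  if (any(table(groups) < 2L)) {
    stop(">= 2 observations per group required", call. = FALSE)
  }
  fit <- stats::aov(values ~ groups, data = data.frame(values, groups))
  tk <- stats::TukeyHSD(fit)$groups
  data.frame(pair = rownames(tk), mean_diff = tk[, "diff"],
             adjusted_p = tk[, "p adj"], row.names = NULL)
}

#' Differential-expression table for a miRNA array time course
#'
#' Runs Lowess normalization, per-probe one-way ANOVA over all timepoints
#' and Bonferroni adjustment, and reports per probe the log2 fold change
#' of the contrast timepoint versus the reference, the average normalized
#' log ratio, and the average log2 Hy3 intensity. The exported P-value is
#' the omnibus ANOVA P; a pooled-variance contrast t-test P for the same
#' two timepoints is kept alongside (`p_contrast`) for comparison.
#'
#' @param arr a [two_channel_array()].
#' @param contrast,reference timepoint labels of the contrast (default:
#'   last timepoint vs the first).
#' @param span,iter Lowess parameters, see [lowess_normalize()].
#' @return a data frame of class `mirna_de_table`, sorted by ascending raw
#'   P (ties broken by annotation), with columns `annotation`, `logFC`,
#'   `AvgExpr`, `AvgHy3`, `p_value`, `adj_p_value`, `p_contrast`.
#' @export
mirna_de_table <- function(arr, contrast = NULL, reference = NULL,
                           span = 0.3, iter = 3L) {
  stopifnot(inherits(arr, "two_channel_array"))
  tps <- unique(arr$timepoint)
  if (is.null(reference)) reference <- tps[1]
  if (is.null(contrast)) contrast <- tps[length(tps)]
  if (!all(c(contrast, reference) %in% tps)) {
    stop("contrast/reference must be observed timepoints", call. = FALSE)
  }
  m <- lowess_normalize(arr, span = span, iter = iter)
  in_c <- arr$timepoint == contrast
  in_r <- arr$timepoint == reference
  logfc <- rowMeans(m[, in_c, drop = FALSE]) - rowMeans(m[, in_r, drop = FALSE])
  p <- anova_per_probe(m, arr$timepoint)
  p_contrast <- pooled_t_rows(m[, in_c, drop = FALSE], m[, in_r, drop = FALSE])$p
  tab <- data.frame(annotation = arr$probe_ids,
                    logFC = logfc,
                    AvgExpr = rowMeans(m),
                    AvgHy3 = rowMeans(log2(arr$hy3)),
                    p_value = p,
                    adj_p_value = bonferroni_adjust(p),
                    p_contrast = p_contrast,
                    row.names = NULL)
  tab <- tab[order(tab$p_value, tab$annotation), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("mirna_de_table", "data.frame")
  tab
}

# vectorised pooled-variance two-sample t-test over matrix rows
pooled_t_rows <- function(x, y, var_equal = TRUE) {
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  d <- m1 - m2
  if (var_equal) {
    s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(s2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(d))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- d / se
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  p[se == 0 & d == 0] <- 1
  p[se == 0 & d != 0] <- 0
  list(estimate = d, statistic = t, p = p)
}

#' Retain significantly regulated miRNAs
#'
#' Filters a differential-expression table to records with adjusted
#' P below `alpha`, sorted by ascending raw P (ties by annotation).
#'
#' @param records a `mirna_de_table` or any data frame with `p_value` and
#'   `adj_p_value` columns.
#' @param alpha significance threshold on the adjusted P-value.
#' @return the retained records, same columns.
#' @export
call_de_mirnas <- function(records, alpha = 0.05) {
  stopifnot(is.data.frame(records),
            all(c("p_value", "adj_p_value") %in% names(records)))
  keep <- records[records$adj_p_value < alpha, , drop = FALSE]
  keep <- keep[order(keep$p_value, keep$annotation), , drop = FALSE]
  rownames(keep) <- NULL
  keep
}

#' Linear fold change from a log2 fold change
#'
#' @param logFC numeric vector of log2 fold changes.
#' @return `2^logFC`; values below 1 indicate downregulation.
#' @export
#' @examples
#' fold_change_linear(1.200823) # ~2.3-fold up
fold_change_linear <- function(logFC) {
  stopifnot(is.numeric(logFC), all(is.finite(logFC)))
  2^logFC
}

#' Read / write a differential-expression table TSV
#'
#' The on-disk shape carries the six canonical columns (annotation, logFC,
#' AvgExpr, AvgHy3, P, adjusted P).
#'
#' @param path TSV path.
#' @return `read_mirna_de_tsv()`: a `mirna_de_table` data frame.
#' @export
read_mirna_de_tsv <- function(path) {
  tab <- read_tsv(path)
  need <- c("annotation", "logFC", "AvgExpr", "AvgHy3", "p_value", "adj_p_value")
  if (!all(need %in% names(tab))) {
    stop("expected columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  tab <- tab[need]
  class(tab) <- c("mirna_de_table", "data.frame")
  tab
}

#' @param records a `mirna_de_table`.
#' @rdname read_mirna_de_tsv
#' @export
write_mirna_de_tsv <- function(records, path) {
  cols <- c("annotation", "logFC", "AvgExpr", "AvgHy3", "p_value", "adj_p_value")
  write_tsv(as.data.frame(records)[cols], path)
}
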