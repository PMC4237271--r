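#' Two-channel miRNA array container
#'
#' Holds Hy3 (sample) and Hy5 (common reference) intensity matrices with a
#' timepoint label per sample. All intensities must be strictly positive
#' (they are log-transformed downstream).
#'
#' @param hy3,hy5 numeric matrices (probes x samples) of raw intensities.
#' @param timepoint character vector, one label per sample column.
#' @param probe_ids,sample_ids optional ids; default to the dimnames of
#'   `hy3`.
#' @return an object of class `two_channel_array`.
#' @export
two_channel_array <- function(hy3, hy5, timepoint,
                              probe_ids = rownames(hy3),
                              sample_ids = colnames(hy3)) {
  hy3 <- as.matrix(hy3); hy5 <- as.matrix(hy5)
  if (!all(dim(hy3) == dim(hy5))) {
    stop("hy3 and hy5 must have identical dimensions", call. = FALSE)
  }
  if (is.null(probe_ids)) probe_ids <- sprintf("probe_%03d", seq_len(nrow(hy3)))
  if (is.null(sample_ids)) sample_ids <- sprintf("sample_%02d", seq_len(ncol(hy3)))
  if (length(timepoint) != ncol(hy3)) {
    stop("need one timepoint label per sample", call. = FALSE)
  }
  if (anyNA(timepoint)) stop("missing timepoint labels", call. = FALSE)
  check_positive_intensities(hy3, "hy3", probe_ids, sample_ids)
  check_positive_intensities(hy5, "hy5", probe_ids, sample_ids)
  dimnames(hy3) <- dimnames(hy5) <- list(probe_ids, sample_ids)
  structure(list(probe_ids = probe_ids, sample_ids = sample_ids,
                 hy3 = hy3, hy5 = hy5, timepoint = as.character(timepoint)),
            class = "two_channel_array")
}

check_positive_intensities <- function(m, channel, probe_ids, sample_ids) {
  bad <- which(!is.finite(m) | m <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-positive %s intensity at probe '%s', sample '%s'",
                 channel, probe_ids[bad[1, 1]], sample_ids[bad[1, 2]]),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.two_channel_array <- function(x, ...) {
  cat(sprintf("two_channel_array: %d probes x %d samples (%s)\n",
              length(x$probe_ids), length(x$sample_ids),
              paste(sprintf("%s x%d", names(table(x$timepoint)),
                            as.integer(table(x$timepoint))), collapse = ", ")))
  invisible(x)
}

#' Read / write two-channel array TSVs
#'
#' The array TSV has a `probe_id` column followed by `<sample>_Hy3` /
#' `<sample>_Hy5` column pairs; the design sidecar maps `sample_id` to
#' `timepoint`.
#'
#' @param path array TSV path.
#' @param design_path design sidecar TSV path.
#' @return `read_two_channel_tsv()` returns a [two_channel_array()];
#'   `write_two_channel_tsv()` returns `path` invisibly.
#' @export
read_two_channel_tsv <- function(path, design_path) {
  tab <- read_tsv(path)
  design <- read_tsv(design_path)
  stopifnot("probe_id" %in% names(tab),
            all(c("sample_id", "timepoint") %in% names(design)))
  samples <- design$sample_id
  hy3 <- as.matrix(tab[paste0(samples, "_Hy3")])
  hy5 <- as.matrix(tab[paste0(samples, "_Hy5")])
  colnames(hy3) <- colnames(hy5) <- samples
  rownames(hy3) <- rownames(hy5) <- tab$probe_id
  two_channel_array(hy3, hy5, timepoint = design$timepoint)
}

#' @param arr a [two_channel_array()].
#' @rdname read_two_channel_tsv
#' @export
write_two_channel_tsv <- function(arr, path, design_path) {
  stopifnot(inherits(arr, "two_channel_array"))
  out <- data.frame(probe_id = arr$probe_ids)
  for (s in arr$sample_ids) {
    out[[paste0(s, "_Hy3")]] <- arr$hy3[, s]
    out[[paste0(s, "_Hy5")]] <- arr$hy5[, s]
  }
  write_tsv(out, path)
  write_tsv(data.frame(sample_id = arr$sample_ids, timepoint = arr$timepoint),
            design_path)
  invisible(path)
}
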