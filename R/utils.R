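# Internal helpers: sequence plumbing, validation, TSV conventions.

#' Reverse complement of DNA strings
#'
#' Input case is ignored; output is upper case.
#'
#' @param x character vector of DNA sequences (A/C/G/T).
#' @return character vector of reverse complements.
#' @export
#' @examples
#' dna_revcomp("CAGCTTT")
dna_revcomp <- function(x) {
  stopifnot(is.character(x))
  vapply(chartr("ACGT", "TGCA", toupper(x)), function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Convert between RNA and DNA alphabets
#'
#' Mature miRNAs are handled as RNA (U), UTRs and primers as DNA (T).
#' All conversions in the package funnel through these two helpers.
#'
#' @param x character vector of sequences.
#' @return character vector in the other alphabet, upper case.
#' @export
rna_to_dna <- function(x) chartr("u", "T", chartr("U", "T", toupper(x)))

#' @rdname rna_to_dna
#' @export
dna_to_rna <- function(x) chartr("t", "U", chartr("T", "U", toupper(x)))

# validate a character scalar over an alphabet; returns the upper-cased string
check_alphabet <- function(x, alphabet, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop(what, " must be a single character string", call. = FALSE)
  }
  xu <- toupper(x)
  if (grepl(paste0("[^", paste(alphabet, collapse = ""), "]"), xu)) {
    bad <- setdiff(unique(strsplit(xu, "")[[1]]), alphabet)
    stop(what, " contains characters outside {",
         paste(alphabet, collapse = ","), "}: ",
         paste(bad, collapse = ","), call. = FALSE)
  }
  xu
}

# all start positions of `motif` in `x` (overlapping, exact, N never
# matches). Motifs are plain ACGT literals, so a zero-width lookahead
# finds every overlapping occurrence.
motif_starts <- function(x, motif) {
  if (nchar(x) < nchar(motif)) return(integer(0))
  g <- gregexpr(paste0("(?=", motif, ")"), x, perl = TRUE)[[1]]
  as.integer(g[g > 0])
}

# TRUE when `x` contains no occurrence of any motif (fast rejection test;
# emptiness does not depend on the 8mer subsumption rule)
motif_free <- function(x, motifs) {
  !grepl(motifs$m7m8, x, fixed = TRUE) && !grepl(motifs$m7A1, x, fixed = TRUE)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# deterministic child seed for a named pipeline stage (kept below 2^31)
stage_seed <- function(seed, stage) {
  offs <- c(simulate = 101L, mirna_de = 211L, mrna_de = 307L,
            predict = 401L, integrate = 503L, assay = 601L, utr = 701L)
  (as.integer(seed) + offs[[stage]]) %% .Machine$integer.max
}
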