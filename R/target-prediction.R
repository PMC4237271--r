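# Canonical seed-match target prediction: seed extraction, site motifs,
# UTR scanning with the 8mer / 7mer-m8 / 7mer-A1 taxonomy, family
# grouping and inverse-correlation (host-gene) candidate ranking.

#' Seed region of a mature miRNA
#'
#' The seed is nucleotides 2-8 of the mature sequence (1-based,
#' inclusive) - the primary determinant of canonical target recognition.
#'
#' @param sequence mature miRNA sequence, RNA 5'->3' (>= 8 nt).
#' @return the 7-nt seed (RNA).
#' @export
#' @examples
#' seed_of("AAAAGCUGGGUUGAGAGGGU") # miR-320 family seed: AAAGCUG
seed_of <- function(sequence) {
  seq <- check_alphabet(dna_to_rna(sequence), c("A", "C", "G", "U"),
                        "mature miRNA sequence")
  if (nchar(seq) < 8L) {
    stop("mature sequence must be >= 8 nt to have a seed", call. = FALSE)
  }
  unname(substr(seq, 2L, 8L))
}

#' Canonical target-site motifs of a seed
#'
#' The three canonical site types on the target (DNA) strand:
#' * `m7m8` (7mer-m8): reverse complement of the full seed (miRNA
#'   positions 2-8);
#' * `m8site` (8mer): the 7mer-m8 followed by an A opposite miRNA
#'   position 1;
#' * `m7A1` (7mer-A1): reverse complement of miRNA positions 2-7 followed
#'   by an A.
#'
#' @param seed 7-nt miRNA seed (RNA; DNA accepted and converted).
#' @return named list of DNA motifs: `m8site` (8 nt), `m7m8` (7 nt),
#'   `m7A1` (7 nt).
#' @export
#' @examples
#' site_motifs("AAAGCUG")
site_motifs <- function(seed) {
  seed <- check_alphabet(dna_to_rna(seed), c("A", "C", "G", "U"), "seed")
  if (nchar(seed) != 7L) stop("seed must be 7 nt", call. = FALSE)
  m7m8 <- dna_revcomp(rna_to_dna(seed))
  list(m8site = paste0(m7m8, "A"),
       m7m8 = m7m8,
       m7A1 = paste0(dna_revcomp(rna_to_dna(substr(seed, 1L, 6L))), "A"))
}

#' Scan a 3'UTR for canonical seed sites
#'
#' Reports every 8mer match, every 7mer-m8 match not contained in a
#' counted 8mer, and every 7mer-A1 match not contained in a counted 8mer
#' (the subsumption rule prevents double-counting one locus). Overlapping
#' distinct sites are all reported. `N` never matches.
#'
#' @param utr UTR sequence, DNA over `{A,C,G,T,N}`.
#' @param seed 7-nt miRNA seed (RNA; DNA accepted).
#' @param utr_id optional id recorded in the result.
#' @return data frame with columns `utr_id`, `site_type`, `start`, `end`
#'   (1-based inclusive), sorted by `start`.
#' @export
scan_utr <- function(utr, seed, utr_id = NA_character_) {
  utr <- check_alphabet(utr, c("A", "C", "G", "T", "N"), "UTR")
  scan_core(utr, site_motifs(seed), utr_id)
}

# scanning workhorse with precomputed motifs (hot path: called once per
# UTR in prediction and repeatedly during rejection sampling)
scan_core <- function(utr, motifs, utr_id = NA_character_) {
  if (nchar(utr) == 0L) {
    return(data.frame(utr_id = character(0), site_type = character(0),
                      start = integer(0), end = integer(0)))
  }
  s8 <- motif_starts(utr, motifs$m8site)
  s7m8 <- setdiff(motif_starts(utr, motifs$m7m8), s8)
  s7a1 <- setdiff(motif_starts(utr, motifs$m7A1), s8 + 1L)
  n_tot <- length(s8) + length(s7m8) + length(s7a1)
  out <- data.frame(
    utr_id = rep(utr_id, n_tot),
    site_type = c(rep("8mer", length(s8)), rep("7mer-m8", length(s7m8)),
                  rep("7mer-A1", length(s7a1))),
    start = c(s8, s7m8, s7a1),
    end = c(s8 + 7L, s7m8 + 6L, s7a1 + 6L))
  out <- out[order(out$start, out$site_type), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Group mature miRNAs into seed families
#'
#' Partitions miRNAs by identical seed; members of a family share one
#' target-site motif set (as miR-320a-e do).
#'
#' @param mirnas named character vector of mature RNA sequences (names are
#'   miRNA ids).
#' @return list of families, each a list with `family_key` (the seed) and
#'   `members` (lexicographically sorted ids); families sorted by seed.
#' @export
group_families <- function(mirnas) {
  if (length(mirnas) == 0L) return(list())
  if (is.null(names(mirnas)) || anyNA(names(mirnas)) || any(names(mirnas) == "")) {
    stop("mirnas must be a named character vector", call. = FALSE)
  }
  seeds <- vapply(mirnas, seed_of, character(1))
  keys <- sort(unique(seeds))
  lapply(keys, function(k) {
    list(family_key = k, members = sort(names(mirnas)[seeds == k]))
  })
}

#' Predict family targets by canonical seed match
#'
#' A gene is a predicted target when its 3'UTR carries at least
#' `min_sites` canonical sites for the family seed.
#'
#' @param fam a family from [group_families()], or directly a 7-nt seed.
#' @param utrs named character vector of UTR sequences (DNA), one per
#'   gene; duplicate ids are rejected.
#' @param min_sites minimum total canonical sites.
#' @return data frame of predicted targets, sorted by gene id: `gene_id`,
#'   `n_sites`, `n_8mer`, `n_7mer_m8`, `n_7mer_A1`.
#' @export
predict_targets <- function(fam, utrs, min_sites = 1L) {
  seed <- if (is.list(fam)) fam$family_key else fam
  if (anyDuplicated(names(utrs))) {
    stop("duplicate UTR ids: ",
         paste(unique(names(utrs)[duplicated(names(utrs))]), collapse = ", "),
         call. = FALSE)
  }
  motifs <- site_motifs(seed)
  counts <- lapply(names(utrs), function(g) {
    sites <- scan_core(toupper(utrs[[g]]), motifs, utr_id = g)
    data.frame(gene_id = g,
               n_sites = nrow(sites),
               n_8mer = sum(sites$site_type == "8mer"),
               n_7mer_m8 = sum(sites$site_type == "7mer-m8"),
               n_7mer_A1 = sum(sites$site_type == "7mer-A1"))
  })
  out <- do.call(rbind, counts)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), n_sites = integer(0),
                      n_8mer = integer(0), n_7mer_m8 = integer(0),
                      n_7mer_A1 = integer(0))
  }
  out <- out[out$n_sites >= min_sites, , drop = FALSE]
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Inverse-correlation ranking of candidate targets
#'
#' Host-gene co-expression ranking: Pearson correlation of each candidate
#' gene with a proxy expression vector for the miRNA (its host gene, or
#' the miRNA itself), ranked most-negative first. A true target is
#' expected near the top (small percentile). Zero-variance vectors have
#' undefined correlation; they are flagged and ranked last.
#'
#' @param host_expr numeric vector, the miRNA/host proxy expression over
#'   samples (>= 3 samples).
#' @param candidates numeric matrix (genes x samples, same sample order)
#'   or an [expression_matrix()].
#' @return data frame sorted by ascending correlation (ties by gene id,
#'   flagged records last): `gene`, `correlation`, `percentile`
#'   (rank / total, in (0, 1]), `flagged`.
#' @export
hoctar_rank <- function(host_expr, candidates) {
  vals <- if (inherits(candidates, "expression_matrix")) candidates$values
          else as.matrix(candidates)
  if (length(host_expr) < 3L) stop(">= 3 paired samples required", call. = FALSE)
  if (ncol(vals) != length(host_expr)) {
    stop("candidates must have one column per host sample", call. = FALSE)
  }
  if (is.null(rownames(vals))) rownames(vals) <- sprintf("gene_%04d", seq_len(nrow(vals)))
  host_sd <- stats::sd(host_expr)
  r <- if (host_sd == 0) rep(NA_real_, nrow(vals)) else
    suppressWarnings(as.vector(stats::cor(t(vals), host_expr)))
  flagged <- !is.finite(r)
  ord <- order(flagged, r, rownames(vals))
  out <- data.frame(gene = rownames(vals)[ord], correlation = r[ord],
                    percentile = seq_len(nrow(vals)) / nrow(vals),
                    flagged = flagged[ord], row.names = NULL)
  out
}

#' Read mature miRNA / UTR FASTA files
#'
#' Thin wrappers over Biostrings FASTA readers returning named character
#' vectors in the alphabets the rest of the package expects (RNA for
#' mature miRNAs, DNA for UTRs). FASTA ids are truncated at the first
#' whitespace.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_mirna_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(dna_to_rna(as.character(x)), sub("\\s.*$", "", names(x)))
}

#' @rdname read_mirna_fasta
#' @export
read_utr_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}

#' Write seed sites / prediction tables
#'
#' @param sites data frame from [scan_utr()] (possibly row-bound over
#'   UTRs).
#' @param path TSV path.
#' @export
write_sites_tsv <- function(sites, path) write_tsv(sites, path)
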