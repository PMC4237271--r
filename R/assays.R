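# Quantification math for the validation experiments: overlap-extension
# assembly of reporter inserts from printed primer pairs, inference of the
# mutated seed-match motif, delta-delta-Ct qPCR quantification, dual
# luciferase normalization and generic plate quantification.

#' Primer pair for overlap-extension cloning
#'
#' Both primers are written 5'->3' on opposite strands; they share an
#' exact reverse-complement overlap at their 3' ends through which the
#' insert is assembled. Lower-case letters conventionally flag mutated
#' positions and are preserved verbatim.
#'
#' @param forward,reverse primer sequences 5'->3' (DNA, case preserved).
#' @param name optional identifier.
#' @return object of class `primer_pair`.
#' @export
primer_pair <- function(forward, reverse, name = NA_character_) {
  chk <- function(x, what) {
    check_alphabet(x, c("A", "C", "G", "T"), what)  # validates; case-folded copy unused
    x
  }
  structure(list(forward = chk(forward, "forward primer"),
                 reverse = chk(reverse, "reverse primer"),
                 name = name),
            class = "primer_pair")
}

#' @export
print.primer_pair <- function(x, ...) {
  cat(sprintf("primer_pair%s\n  F (%d nt): %s\n  R (%d nt): %s\n",
              if (is.na(x$name)) "" else paste0(" ", x$name),
              nchar(x$forward), x$forward, nchar(x$reverse), x$reverse))
  invisible(x)
}

#' Assemble an insert from a partially complementary primer pair
#'
#' Overlap-extension assembly: the insert is the forward primer followed
#' by the reverse complement of the reverse primer, with the maximal exact
#' 3'-terminal overlap merged once. With `trim_adapters = TRUE`, terminal
#' adapter tails up to and including a leading SpeI site (`ACTAGT`) and
#' from a trailing HindIII site (`AAGCTT`) onwards are removed when
#' present (the restriction sites used for directional cloning).
#'
#' @param pp a [primer_pair()].
#' @param min_overlap minimum accepted exact overlap (nt).
#' @param trim_adapters drop restriction-site adapter tails (default
#'   `FALSE`, so printed sequences round-trip verbatim).
#' @return the assembled insert, upper-case DNA.
#' @export
assemble_insert <- function(pp, min_overlap = 15L, trim_adapters = FALSE) {
  stopifnot(inherits(pp, "primer_pair"))
  fwd <- toupper(pp$forward)
  rrc <- dna_revcomp(pp$reverse)
  best <- 0L
  for (k in seq_len(min(nchar(fwd), nchar(rrc)))) {
    if (substring(fwd, nchar(fwd) - k + 1L) == substring(rrc, 1L, k)) best <- k
  }
  if (best < min_overlap) {
    stop(sprintf(
      "no exact 3' overlap >= %d nt between the primers (best found: %d nt)",
      min_overlap, best), call. = FALSE)
  }
  insert <- paste0(fwd, substring(rrc, best + 1L))
  if (trim_adapters) {
    spe <- regexpr("ACTAGT", insert, fixed = TRUE)
    if (spe > 0) insert <- substring(insert, spe + attr(spe, "match.length"))
    hind <- regexpr("AAGCTT", insert, fixed = TRUE)
    if (hind > 0) insert <- substring(insert, 1L, hind - 1L)
  }
  insert
}

#' Infer the mutated seed-match motif from wild-type/mutant primer pairs
#'
#' Assembles both inserts, locates the replaced blocks (maximal runs of
#' mismatching positions between the equal-length inserts) and returns
#' the unique wild-type 7-mer that covers every replaced block - the
#' seed-match motif that the mutagenesis destroyed. This lets the
#' family's target-site motif be recovered from the printed primer table
#' alone, with no external sequence database.
#'
#' @param wt,mut [primer_pair()]s of the wild-type and mutant construct.
#' @return the 7-nt DNA motif.
#' @export
infer_mutated_motif <- function(wt, mut) {
  wt_ins <- assemble_insert(wt)
  mut_ins <- assemble_insert(mut)
  if (nchar(wt_ins) != nchar(mut_ins)) {
    stop("wild-type and mutant inserts differ in length; ",
         "block-replacement structure required", call. = FALSE)
  }
  wt_ch <- strsplit(wt_ins, "")[[1]]
  diff <- wt_ch != strsplit(mut_ins, "")[[1]]
  if (!any(diff)) stop("no replaced blocks: inserts are identical", call. = FALSE)
  runs <- rle(diff)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  blocks <- cbind(start = starts[runs$values], end = ends[runs$values])
  # candidate motifs per block: every wt 7-window fully containing the run
  cand <- apply(blocks, 1, function(b) {
    lo <- max(1L, b["end"] - 6L)
    hi <- min(nchar(wt_ins) - 6L, b["start"])
    if (hi < lo) return(character(0))
    vapply(lo:hi, function(s) substr(wt_ins, s, s + 6L), character(1))
  }, simplify = FALSE)
  common <- Reduce(intersect, cand)
  if (length(common) != 1L) {
    stop("no unique common 7-mer across replaced blocks; candidates: ",
         paste(unlist(common), collapse = ", "), call. = FALSE)
  }
  common
}

#' Relative expression by the delta-delta-Ct method
#'
#' Livak quantification: per sample, `dCt = Ct_target - mean(reference
#' Cts)` (the arithmetic mean of reference Cts equals geometric-mean
#' normalization in concentration space); the fold change of the
#' measurement relative to the calibrator is `2^-(dCt_m - dCt_cal)`.
#'
#' @param m,calibrator lists (or one-row data frames) with fields `gene`,
#'   `ct` and `reference_cts` (named numeric vector of reference-gene
#'   Cts, e.g. GAPDH and beta-actin).
#' @param reference optional single reference-gene name to use instead of
#'   averaging all shared references.
#' @return linear fold change (numeric scalar).
#' @export
#' @examples
#' m <- list(gene = "RUNX2", ct = 25, reference_cts = c(GAPDH = 18, ACTB = 19))
#' cal <- list(gene = "RUNX2", ct = 26, reference_cts = c(GAPDH = 18, ACTB = 19))
#' ddct_fold(m, cal) # one cycle earlier: 2-fold up
ddct_fold <- function(m, calibrator, reference = NULL) {
  as_meas <- function(x, what) {
    if (is.data.frame(x)) x <- as.list(x[1, , drop = FALSE])
    if (!all(c("gene", "ct", "reference_cts") %in% names(x))) {
      stop(what, " needs fields gene, ct, reference_cts", call. = FALSE)
    }
    if (is.null(names(x$reference_cts)) || length(x$reference_cts) < 1L) {
      stop(what, " needs >= 1 named reference Ct", call. = FALSE)
    }
    x
  }
  m <- as_meas(m, "measurement")
  calibrator <- as_meas(calibrator, "calibrator")
  if (!identical(m$gene, calibrator$gene)) {
    stop("measurement and calibrator must quantify the same gene", call. = FALSE)
  }
  refs <- if (is.null(reference)) {
    shared <- intersect(names(m$reference_cts), names(calibrator$reference_cts))
    if (length(shared) == 0L) stop("no shared reference genes", call. = FALSE)
    shared
  } else {
    if (!reference %in% names(m$reference_cts) ||
        !reference %in% names(calibrator$reference_cts)) {
      stop("reference gene '", reference, "' missing from a measurement",
           call. = FALSE)
    }
    reference
  }
  dct_m <- m$ct - mean(m$reference_cts[refs])
  dct_c <- calibrator$ct - mean(calibrator$reference_cts[refs])
  2^-(dct_m - dct_c)
}

#' Per-construct repression from a dual-luciferase plate
#'
#' Per well, firefly luminescence is normalized to renilla (transfection
#' control); per construct, repression is `1 - mean(ratio | treatment
#' miRNA) / mean(ratio | control miRNA)`, with a two-tailed two-sample
#' t-test on the per-well ratios.
#'
#' @param wells data frame with columns `construct`, `mir`, `firefly`,
#'   `renilla` (renilla > 0); every (construct, mir) cell needs >= 2
#'   replicate wells.
#' @param control_mir,treat_mir the control and treatment miRNA labels.
#' @return data frame, one row per construct: `construct`, `repression`,
#'   `p`, `n_treat`, `n_ctrl`.
#' @export
luciferase_repression <- function(wells, control_mir = "pre-miR-Neg",
                                  treat_mir = "pre-miR-320c") {
  need <- c("construct", "mir", "firefly", "renilla")
  if (!all(need %in% names(wells))) {
    stop("wells needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(wells$renilla <= 0)) stop("renilla must be > 0", call. = FALSE)
  wells$ratio <- wells$firefly / wells$renilla
  out <- lapply(sort(unique(wells$construct)), function(cst) {
    tr <- wells$ratio[wells$construct == cst & wells$mir == treat_mir]
    ct <- wells$ratio[wells$construct == cst & wells$mir == control_mir]
    if (length(tr) < 2L || length(ct) < 2L) {
      stop("construct '", cst, "' needs >= 2 wells for both '",
           control_mir, "' and '", treat_mir, "'", call. = FALSE)
    }
    p <- if (stats::sd(tr) == 0 && stats::sd(ct) == 0) {
      if (mean(tr) == mean(ct)) 1 else 0
    } else {
      stats::t.test(tr, ct)$p.value
    }
    data.frame(construct = cst, repression = 1 - mean(tr) / mean(ct),
               p = p, n_treat = length(tr), n_ctrl = length(ct))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Blank-corrected plate quantification with relative activity
#'
#' Per well, the value is the mean of its replicate readings (e.g. the
#' nine scan reads of a fluorescence well-scan) minus the mean blank;
#' relative activity divides by the mean of the control wells.
#'
#' @param readings named list of numeric vectors, one per well (>= 1
#'   reading each).
#' @param blanks numeric vector of blank readings; if empty, a blank of 0
#'   is used with a warning.
#' @param control character vector of control-well names (must be present
#'   in `readings`).
#' @return data frame: `well`, `value` (blank-corrected mean),
#'   `relative` (value / mean control value).
#' @export
plate_quantify <- function(readings, blanks, control) {
  if (!is.list(readings) || is.null(names(readings))) {
    stop("readings must be a named list of per-well reading vectors",
         call. = FALSE)
  }
  if (any(lengths(readings) < 1L)) {
    stop(">= 1 reading per well required", call. = FALSE)
  }
  blank <- if (length(blanks) == 0L) {
    warning("no blank readings supplied; using blank = 0")
    0
  } else mean(blanks)
  if (!all(control %in% names(readings))) {
    stop("control wells missing from readings: ",
         paste(setdiff(control, names(readings)), collapse = ", "),
         call. = FALSE)
  }
  value <- vapply(readings, mean, numeric(1)) - blank
  ctrl_mean <- mean(value[control])
  data.frame(well = names(readings), value = unname(value),
             relative = unname(value) / ctrl_mean, row.names = NULL)
}
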