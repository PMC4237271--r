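#' Configuration for the synthetic study generator
#'
#' Bundles every knob of the synthetic-data module into one validated
#' object. The defaults describe a plausible small differentiation study:
#' a 200-probe two-channel miRNA array measured at three timepoints with
#' four replicates, 20 truly regulated miRNAs shifting by 1.0-1.5 log2
#' units (the day-13 magnitudes seen on real arrays), replicate noise of
#' 0.15 log2 units, a 2000-gene expression study in which 50 true targets
#' are knocked down two-fold, and 3'UTRs of 500-2000 nt carrying three
#' planted canonical seed sites per true target.
#'
#' @param n_mirnas number of miRNA probes on the simulated array.
#' @param n_de_mirnas number of truly regulated miRNAs (<= `n_mirnas`).
#' @param timepoints character vector of timepoint labels; the first is
#'   the reference (baseline) group.
#' @param reps_per_timepoint arrays per timepoint (>= 2; ANOVA needs
#'   within-group replication).
#' @param de_log2fc_range length-2 numeric, magnitude range (log2 units)
#'   from which each regulated miRNA's shift is drawn uniformly.
#' @param prop_up probability that a regulated miRNA is shifted up rather
#'   than down (day-13 arrays are dominated by upregulation).
#' @param noise_sd replicate standard deviation of log2 ratios /
#'   log2 expression (> 0).
#' @param dye_bias_amplitude amplitude of the smooth intensity-dependent
#'   dye bias (log2 units at the extremes of the intensity range); set to
#'   0 for bias-free arrays.
#' @param n_genes number of genes in the simulated expression study.
#' @param n_true_targets number of planted true targets (<= `n_genes`).
#' @param target_log2fc log2 fold change planted for true targets in both
#'   expression screens (negative = downregulated; default -1, i.e. a
#'   two-fold knockdown typical of validated miRNA targets).
#' @param decoy_frac fraction of non-target genes downregulated in only
#'   one of the two screens (per screen, disjoint sets).
#' @param reps_per_condition replicate samples per condition in the
#'   expression study.
#' @param utr_length_range length-2 integer, 3'UTR length range in nt
#'   (>= 30).
#' @param sites_per_target canonical seed sites planted per true-target
#'   UTR.
#' @param max_utr_attempts rejection-sampling cap per UTR before erroring.
#' @param assay_reps replicate wells per assay condition.
#' @param assay_cv lognormal coefficient of variation of luminescence and
#'   plate readings.
#' @param assay_ct_sd replicate standard deviation of qPCR Ct values
#'   (cycles).
#' @param rng_seed integer seed; identical configs (including the seed)
#'   generate identical data.
#'
#' @return an object of class `sim_config` (a validated named list).
#' @seealso [gen_mirna_arrays()], [gen_expression_study()], [gen_utrs()],
#'   [gen_assay_tables()]
#' @export
#' @examples
#' cfg <- sim_config(n_mirnas = 50, n_de_mirnas = 5, rng_seed = 1)
#' cfg$noise_sd
sim_config <- function(n_mirnas = 200L,
                       n_de_mirnas = 20L,
                       timepoints = c("D0", "D7", "D13"),
                       reps_per_timepoint = 4L,
                       de_log2fc_range = c(1.0, 1.5),
                       prop_up = 0.8,
                       noise_sd = 0.15,
                       dye_bias_amplitude = 0.3,
                       n_genes = 2000L,
                       n_true_targets = 50L,
                       target_log2fc = -1,
                       decoy_frac = 0.05,
                       reps_per_condition = 4L,
                       utr_length_range = c(500L, 2000L),
                       sites_per_target = 3L,
                       max_utr_attempts = 1000L,
                       assay_reps = 6L,
                       assay_cv = 0.1,
                       assay_ct_sd = 0.15,
                       rng_seed = 1L) {
  cfg <- list(
    n_mirnas = as.integer(n_mirnas),
    n_de_mirnas = as.integer(n_de_mirnas),
    timepoints = as.character(timepoints),
    reps_per_timepoint = as.integer(reps_per_timepoint),
    de_log2fc_range = as.numeric(de_log2fc_range),
    prop_up = as.numeric(prop_up),
    noise_sd = as.numeric(noise_sd),
    dye_bias_amplitude = as.numeric(dye_bias_amplitude),
    n_genes = as.integer(n_genes),
    n_true_targets = as.integer(n_true_targets),
    target_log2fc = as.numeric(target_log2fc),
    decoy_frac = as.numeric(decoy_frac),
    reps_per_condition = as.integer(reps_per_condition),
    utr_length_range = as.integer(utr_length_range),
    sites_per_target = as.integer(sites_per_target),
    max_utr_attempts = as.integer(max_utr_attempts),
    assay_reps = as.integer(assay_reps),
    assay_cv = as.numeric(assay_cv),
    assay_ct_sd = as.numeric(assay_ct_sd),
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with(cfg, {
    if (n_mirnas < 1L) stop("n_mirnas must be >= 1", call. = FALSE)
    if (n_de_mirnas < 0L || n_de_mirnas > n_mirnas) {
      stop("n_de_mirnas must lie in [0, n_mirnas]", call. = FALSE)
    }
    if (length(timepoints) < 2L || anyDuplicated(timepoints)) {
      stop("timepoints must be >= 2 distinct labels", call. = FALSE)
    }
    if (length(de_log2fc_range) != 2L || any(de_log2fc_range < 0) ||
        diff(de_log2fc_range) < 0) {
      stop("de_log2fc_range must be a non-decreasing non-negative interval",
           call. = FALSE)
    }
    if (prop_up < 0 || prop_up > 1) stop("prop_up must be in [0,1]", call. = FALSE)
    if (noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
    if (n_true_targets < 0L || n_true_targets > n_genes) {
      stop("n_true_targets must lie in [0, n_genes]", call. = FALSE)
    }
    if (decoy_frac < 0 || decoy_frac > 1) {
      stop("decoy_frac must be in [0,1]", call. = FALSE)
    }
    if (length(utr_length_range) != 2L || utr_length_range[1] < 30L ||
        diff(utr_length_range) < 0) {
      stop("utr_length_range must be a non-decreasing interval with minimum >= 30 nt",
           call. = FALSE)
    }
    if (sites_per_target < 0L) stop("sites_per_target must be >= 0", call. = FALSE)
    if (assay_cv < 0 || assay_ct_sd < 0) {
      stop("assay noise parameters must be >= 0", call. = FALSE)
    }
  })
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic study configuration (sim_config)\n")
  cat(sprintf("  miRNA array : %d probes (%d regulated), %s x %d reps, noise sd %.3g\n",
              x$n_mirnas, x$n_de_mirnas, paste(x$timepoints, collapse = "/"),
              x$reps_per_timepoint, x$noise_sd))
  cat(sprintf("  expression  : %d genes (%d true targets at log2FC %.3g), %d reps\n",
              x$n_genes, x$n_true_targets, x$target_log2fc, x$reps_per_condition))
  cat(sprintf("  UTRs        : %d-%d nt, %d planted sites per target\n",
              x$utr_length_range[1], x$utr_length_range[2], x$sites_per_target))
  cat(sprintf("  rng_seed    : %d\n", x$rng_seed))
  invisible(x)
}

# evaluate expr under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

# the true-target id set is derived from the seed alone so that
# gen_expression_study() and gen_utrs() agree on it for the same config
gene_ids <- function(n) sprintf("GENE%04d", seq_len(n))

pick_true_targets <- function(cfg) {
  with_seed(cfg$rng_seed + 13L,
            sort(sample(gene_ids(cfg$n_genes), cfg$n_true_targets)))
}
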