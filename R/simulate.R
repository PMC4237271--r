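# Synthetic-data generators. Every downstream stage of the pipeline can be
# exercised against these with known planted truth.

#' Simulate a two-channel miRNA array time course
#'
#' Emulates a common-reference two-channel design: every sample's Hy5
#' channel measures the same reference pool, the Hy3 channel the sample
#' itself. Regulated probes have their mean log2(Hy3/Hy5) shifted at every
#' non-baseline timepoint by a magnitude drawn from
#' `cfg$de_log2fc_range` (sign up with probability `cfg$prop_up`).
#' A smooth cubic intensity-dependent dye bias (amplitude
#' `cfg$dye_bias_amplitude`) is added so that Lowess normalization has a
#' real signal to remove; replicate noise is additive Gaussian on the log2
#' ratio.
#'
#' @param cfg a [sim_config()].
#' @return a list with components `array` (a [two_channel_array()]) and
#'   `truth` (class `ground_truth`: `de_mirna_ids` and the named vector of
#'   planted shifts `de_log2fc`).
#' @export
#' @examples
#' sim <- gen_mirna_arrays(sim_config(n_mirnas = 20, n_de_mirnas = 2))
#' dim(sim$array$hy3)
gen_mirna_arrays <- function(cfg) {
  cfg <- validate_sim_config(cfg)
  if (cfg$reps_per_timepoint < 2L) {
    stop("reps_per_timepoint must be >= 2 (one-way ANOVA needs replication)",
         call. = FALSE)
  }
  with_seed(cfg$rng_seed, {
    probes <- sprintf("sim-miR-%03d", seq_len(cfg$n_mirnas))
    tp <- rep(cfg$timepoints, each = cfg$reps_per_timepoint)
    samples <- paste0(tp, "_r", rep(seq_len(cfg$reps_per_timepoint),
                                    times = length(cfg$timepoints)))
    n_s <- length(samples)

    de_ids <- sort(sample(probes, cfg$n_de_mirnas))
    shift <- stats::runif(cfg$n_de_mirnas,
                          cfg$de_log2fc_range[1], cfg$de_log2fc_range[2]) *
      ifelse(stats::runif(cfg$n_de_mirnas) < cfg$prop_up, 1, -1)
    names(shift) <- de_ids

    # planted log2-ratio signal: 0 at baseline, shift elsewhere
    signal <- matrix(0, cfg$n_mirnas, n_s, dimnames = list(probes, samples))
    if (cfg$n_de_mirnas > 0L) {
      signal[de_ids, tp != cfg$timepoints[1]] <- shift
    }

    # per-probe reference abundance (log2), per-spot wobble
    a_ref <- stats::rnorm(cfg$n_mirnas, mean = 8, sd = 1.5)
    a_spot <- matrix(a_ref, cfg$n_mirnas, n_s) +
      matrix(stats::rnorm(cfg$n_mirnas * n_s, 0, 0.1), cfg$n_mirnas, n_s)

    bias <- dye_bias(a_spot, cfg$dye_bias_amplitude)
    m_obs <- signal + bias +
      matrix(stats::rnorm(cfg$n_mirnas * n_s, 0, cfg$noise_sd), cfg$n_mirnas, n_s)

    hy5 <- 2^a_spot
    hy3 <- hy5 * 2^m_obs
    arr <- two_channel_array(hy3, hy5, timepoint = tp,
                             probe_ids = probes, sample_ids = samples)
    truth <- structure(list(de_mirna_ids = de_ids, de_log2fc = shift),
                       class = "ground_truth")
    list(array = arr, truth = truth)
  })
}

# banana-shaped dye bias: cubic in the (centred, scaled) mean log intensity
dye_bias <- function(a, amplitude) {
  if (amplitude == 0) return(0 * a)
  z <- (a - 8) / 4
  amplitude * (z^3 - 0.5 * z)
}

#' Simulate the two expression screens of a tri-pronged target study
#'
#' Generates a miRNA-overexpression-vs-control matrix and a
#' differentiated-vs-control matrix over the same genes. Planted true
#' targets are downregulated by `cfg$target_log2fc` in the treatment arm
#' of *both* matrices; a fraction `cfg$decoy_frac` of the remaining genes
#' is downregulated in only one matrix each (disjoint decoy sets), so the
#' three-way intersection has realistic single-prong contamination.
#'
#' @param cfg a [sim_config()].
#' @return list with components `overexpression` and `differentiation`
#'   (each an [expression_matrix()] with conditions `treatment`/`control`)
#'   and `truth` (`true_target_ids`, `decoy_overexpression`,
#'   `decoy_differentiation`).
#' @export
gen_expression_study <- function(cfg) {
  cfg <- validate_sim_config(cfg)
  genes <- gene_ids(cfg$n_genes)
  targets <- pick_true_targets(cfg)
  with_seed(cfg$rng_seed + 1L, {
    non_targets <- setdiff(genes, targets)
    n_decoy <- round(cfg$decoy_frac * length(non_targets))
    decoys <- sample(non_targets, min(2L * n_decoy, length(non_targets)))
    decoy1 <- sort(utils::head(decoys, n_decoy))
    decoy2 <- sort(utils::tail(decoys, length(decoys) - n_decoy))

    base <- stats::rnorm(cfg$n_genes, mean = 8, sd = 2)
    make_mat <- function(down_ids) {
      cond <- rep(c("treatment", "control"), each = cfg$reps_per_condition)
      smp <- paste0(cond, "_r", rep(seq_len(cfg$reps_per_condition), 2))
      eff <- matrix(0, cfg$n_genes, length(cond), dimnames = list(genes, smp))
      eff[down_ids, cond == "treatment"] <- cfg$target_log2fc
      vals <- matrix(base, cfg$n_genes, length(cond)) + eff +
        matrix(stats::rnorm(cfg$n_genes * length(cond), 0, cfg$noise_sd),
               cfg$n_genes, length(cond))
      dimnames(vals) <- list(genes, smp)
      expression_matrix(vals, condition = cond)
    }
    over <- make_mat(c(targets, decoy1))
    diff <- make_mat(c(targets, decoy2))
    truth <- structure(list(true_target_ids = targets,
                            decoy_overexpression = decoy1,
                            decoy_differentiation = decoy2),
                       class = "ground_truth")
    list(overexpression = over, differentiation = diff, truth = truth)
  })
}

#' Simulate 3'UTR sequences with planted canonical seed sites
#'
#' True-target UTRs carry exactly `cfg$sites_per_target` planted canonical
#' sites for the given seed (cycling through 8mer, 7mer-m8 and 7mer-A1);
#' all other UTRs are rejection-sampled until they contain no canonical
#' site for that seed. UTRs are DNA (T, not U); the miRNA seed is RNA and
#' is converted explicitly.
#'
#' @param cfg a [sim_config()].
#' @param seed_heptamer the 7-nt miRNA seed (RNA; DNA input is converted).
#' @return list with `utrs` (named character vector of DNA sequences, one
#'   per gene) and `truth` (`true_target_ids` plus `planted_sites`, a
#'   data frame of utr_id/site_type/start/end).
#' @export
gen_utrs <- function(cfg, seed_heptamer) {
  cfg <- validate_sim_config(cfg)
  seed <- check_alphabet(dna_to_rna(seed_heptamer), c("A", "C", "G", "U"),
                         "seed heptamer")
  if (nchar(seed) != 7L) stop("seed heptamer must be 7 nt", call. = FALSE)
  motifs <- site_motifs(seed)
  genes <- gene_ids(cfg$n_genes)
  targets <- pick_true_targets(cfg)
  with_seed(cfg$rng_seed + 2L, {
    utrs <- character(cfg$n_genes)
    names(utrs) <- genes
    planted <- vector("list", length(targets))
    names(planted) <- targets
    for (g in genes) {
      len <- sample(seq(cfg$utr_length_range[1], cfg$utr_length_range[2]), 1L)
      if (g %in% targets) {
        res <- plant_sites(len, motifs, cfg$sites_per_target,
                           cfg$max_utr_attempts, g)
        utrs[[g]] <- res$utr
        planted[[g]] <- res$sites
      } else {
        utrs[[g]] <- clean_utr(len, motifs, cfg$max_utr_attempts, g)
      }
    }
    truth <- structure(
      list(true_target_ids = targets,
           planted_sites = do.call(rbind, c(planted, list(make.row.names = FALSE)))),
      class = "ground_truth")
    list(utrs = utrs, truth = truth)
  })
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# a UTR guaranteed free of canonical sites for the motif set
clean_utr <- function(len, motifs, max_attempts, what) {
  for (i in seq_len(max_attempts)) {
    utr <- random_dna(len)
    if (motif_free(utr, motifs)) return(utr)
  }
  stop("failed to rejection-sample a site-free UTR for ", what,
       " in ", max_attempts, " attempts", call. = FALSE)
}

# plant n sites (cycling site types) into a clean backbone, re-verifying
# that the scanner sees exactly the planted sites
plant_sites <- function(len, motifs, n_sites, max_attempts, what) {
  types <- rep(c("8mer", "7mer-m8", "7mer-A1"), length.out = n_sites)
  for (i in seq_len(max_attempts)) {
    utr <- clean_utr(len, motifs, max_attempts, what)
    if (n_sites == 0L) {
      return(list(utr = utr, sites = scan_core(utr, motifs, utr_id = what)))
    }
    # non-overlapping slots of 9 nt, away from the ends
    max_start <- len - 9L
    if (max_start < n_sites * 10L) {
      stop("UTR too short to plant ", n_sites, " sites", call. = FALSE)
    }
    starts <- sort(sample(seq(2L, max_start, by = 10L), n_sites))
    for (k in seq_len(n_sites)) {
      m <- motifs[[c("8mer" = "m8site", "7mer-m8" = "m7m8",
                     "7mer-A1" = "m7A1")[types[k]]]]
      # pad 7mer-m8 with a non-A tail so it is not silently an 8mer
      ins <- if (types[k] == "7mer-m8") paste0(m, "C") else m
      substr(utr, starts[k], starts[k] + nchar(ins) - 1L) <- ins
    }
    found <- scan_core(utr, motifs, utr_id = what)
    if (nrow(found) == n_sites && all(sort(found$start) == starts)) {
      return(list(utr = utr, sites = found))
    }
    # insertion created a spurious junction site: resample
  }
  stop("failed to plant sites into UTR for ", what, call. = FALSE)
}

#' Simulate validation-assay tables
#'
#' Produces a dual-luciferase plate and a qPCR Ct table with a known
#' planted effect. Wild-type reporter wells co-transfected with the miRNA
#' have firefly luminescence reduced by `effect` relative to the negative
#' control; mutant-reporter wells are unaffected. In the Ct table the
#' target gene of the treated sample is shifted by
#' `-log2(1 - effect)` cycles so that delta-delta-Ct recovers a fold of
#' `1 - effect`.
#'
#' @param effect fractional repression in `[0, 1)`.
#' @param cfg a [sim_config()]; uses `assay_reps`, `assay_cv`,
#'   `assay_ct_sd` and `rng_seed`.
#' @return list of two data frames: `luciferase` (construct, mir, firefly,
#'   renilla) and `qpcr` (sample, replicate, gene, ct, ref_GAPDH,
#'   ref_ACTB).
#' @export
gen_assay_tables <- function(effect, cfg) {
  cfg <- validate_sim_config(cfg)
  if (effect < 0 || effect >= 1) stop("effect must be in [0, 1)", call. = FALSE)
  with_seed(cfg$rng_seed + 3L, {
    reps <- cfg$assay_reps
    grid <- expand.grid(construct = c("wt", "mut", "let7_control"),
                        mir = c("pre-miR-Neg", "pre-miR-320c"),
                        rep = seq_len(reps),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    # per-well transfection efficiency scales both reporters
    eff_well <- exp(stats::rnorm(nrow(grid), 0, cfg$assay_cv))
    repressed <- grid$construct == "wt" & grid$mir == "pre-miR-320c"
    firefly <- 10000 * eff_well * ifelse(repressed, 1 - effect, 1) *
      exp(stats::rnorm(nrow(grid), 0, cfg$assay_cv))
    renilla <- 5000 * eff_well * exp(stats::rnorm(nrow(grid), 0, cfg$assay_cv))
    luc <- data.frame(construct = grid$construct, mir = grid$mir,
                      firefly = firefly, renilla = renilla)

    dct_shift <- -log2(1 - effect)
    qgrid <- expand.grid(sample = c("calibrator", "treated"),
                         replicate = seq_len(reps),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    base_ct <- 24
    qpcr <- data.frame(
      sample = qgrid$sample, replicate = qgrid$replicate, gene = "TARGET",
      ct = base_ct + ifelse(qgrid$sample == "treated", dct_shift, 0) +
        stats::rnorm(nrow(qgrid), 0, cfg$assay_ct_sd),
      ref_GAPDH = 18 + stats::rnorm(nrow(qgrid), 0, cfg$assay_ct_sd),
      ref_ACTB = 19 + stats::rnorm(nrow(qgrid), 0, cfg$assay_ct_sd))
    list(luciferase = luc, qpcr = qpcr)
  })
}

#' Write a simulated study to disk
#'
#' Writes the miRNA array (TSV + design sidecar), both expression matrices,
#' the UTR FASTA and the ground-truth manifests into `outdir`, in the same
#' plain-text formats the readers of the individual modules consume.
#'
#' @param cfg a [sim_config()].
#' @param seed_heptamer miRNA seed used for the UTR set (RNA).
#' @param outdir output directory (created if needed).
#' @return invisibly, the list of generated objects.
#' @export
write_simulation <- function(cfg, seed_heptamer, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  mir <- gen_mirna_arrays(cfg)
  expr <- gen_expression_study(cfg)
  utr <- gen_utrs(cfg, seed_heptamer)

  write_two_channel_tsv(mir$array, file.path(outdir, "mirna_arrays.tsv"),
                        file.path(outdir, "mirna_design.tsv"))
  write_expression_tsv(expr$overexpression,
                       file.path(outdir, "expr_overexpression.tsv"),
                       file.path(outdir, "design_overexpression.tsv"))
  write_expression_tsv(expr$differentiation,
                       file.path(outdir, "expr_differentiation.tsv"),
                       file.path(outdir, "design_differentiation.tsv"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(utr$utrs),
                              file.path(outdir, "utrs.fasta"))
  write_tsv(data.frame(de_mirna_id = mir$truth$de_mirna_ids,
                       de_log2fc = unname(mir$truth$de_log2fc)),
            file.path(outdir, "truth_de_mirnas.tsv"))
  write_tsv(data.frame(true_target_id = expr$truth$true_target_ids),
            file.path(outdir, "truth_targets.tsv"))
  write_tsv(utr$truth$planted_sites, file.path(outdir, "truth_sites.tsv"))
  invisible(list(mirna = mir, expression = expr, utrs = utr))
}
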