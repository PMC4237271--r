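# End-to-end orchestration: a serializable run configuration and a
# deterministic simulate -> miRNA DE -> mRNA screens -> predict ->
# integrate -> assay pipeline with a machine-readable summary.

#' Pipeline run configuration
#'
#' Collects stage toggles and every module parameter into one
#' serializable object. `load_run_config(save_run_config(cfg))`
#' round-trips exactly; every random stage derives its seed from the
#' single `seed` field.
#'
#' @param seed integer master seed.
#' @param outdir output directory for per-stage files; `NULL` keeps the
#'   run in memory only.
#' @param stages named logical vector toggling `simulate`, `mirna_de`,
#'   `mrna_de`, `predict`, `integrate`, `assay`.
#' @param mirna_seq mature miRNA sequence driving UTR simulation and
#'   target prediction (default: miR-320c).
#' @param sim named list of [sim_config()] overrides.
#' @param mirna_de list: `span`, `alpha` for the array stage.
#' @param mrna_de list: `fc_thresh`, `alpha`, `direction` for the screens.
#' @param predict list: `min_sites`.
#' @param assay list: `effect` (planted repression fraction).
#' @return object of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       outdir = NULL,
                       stages = c(simulate = TRUE, mirna_de = TRUE,
                                  mrna_de = TRUE, predict = TRUE,
                                  integrate = TRUE, assay = TRUE),
                       mirna_seq = "AAAAGCUGGGUUGAGAGGGU",
                       sim = list(),
                       mirna_de = list(span = 0.3, alpha = 0.05),
                       mrna_de = list(fc_thresh = 1.3, alpha = 0.05,
                                      direction = "down"),
                       predict = list(min_sites = 1L),
                       assay = list(effect = 0.5)) {
  all_stages <- c("simulate", "mirna_de", "mrna_de", "predict",
                  "integrate", "assay")
  st <- stats::setNames(rep(TRUE, length(all_stages)), all_stages)
  st[names(stages)] <- as.logical(stages)
  cfg <- list(
    seed = as.integer(seed),
    outdir = if (is.null(outdir)) NULL else as.character(outdir),
    stages = as.list(st),
    mirna_seq = toupper(as.character(mirna_seq)),
    sim = sim,
    mirna_de = utils::modifyList(list(span = 0.3, alpha = 0.05), mirna_de),
    mrna_de = utils::modifyList(list(fc_thresh = 1.3, alpha = 0.05,
                                     direction = "down"), mrna_de),
    predict = utils::modifyList(list(min_sites = 1L), predict),
    assay = utils::modifyList(list(effect = 0.5), assay)
  )
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param cfg a `run_config`.
#' @param path YAML file path.
#' @export
save_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname run_config
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  run_config(seed = raw$seed, outdir = raw$outdir,
             stages = unlist(raw$stages), mirna_seq = raw$mirna_seq,
             sim = raw$sim,
             mirna_de = raw$mirna_de, mrna_de = raw$mrna_de,
             predict = raw$predict, assay = raw$assay)
}

#' Run the full synthetic-study pipeline
#'
#' Executes the enabled stages in dependency order on data generated with
#' the configured [sim_config()], and collects a machine-readable summary
#' of every stage against the planted ground truth: differential calls
#' and sensitivity on the miRNA array, recovery of planted targets
#' through both downregulation screens, seed-site predictions, the
#' three-way intersection, and the assay estimates. Identical
#' configurations produce identical summaries.
#'
#' @param cfg a [run_config()].
#' @return object of class `run_report`: `config`, per-stage `outputs`
#'   and the `summary` list. If `cfg$outdir` is set, per-stage TSVs and a
#'   `summary.yaml` are also written there.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  st <- cfg$stages
  needs <- list(mirna_de = "simulate", mrna_de = "simulate",
                predict = "simulate", integrate = c("mrna_de", "predict"),
                assay = "simulate")
  for (stage in names(needs)) {
    if (isTRUE(st[[stage]])) {
      missing <- needs[[stage]][!vapply(needs[[stage]],
                                        function(s) isTRUE(st[[s]]), logical(1))]
      if (length(missing)) {
        stop("stage '", stage, "' requires disabled stage(s): ",
             paste(missing, collapse = ", "), call. = FALSE)
      }
    }
  }
  outputs <- list()
  summary <- list()
  sc <- do.call(sim_config, utils::modifyList(list(rng_seed = cfg$seed),
                                              cfg$sim))
  seed7 <- seed_of(cfg$mirna_seq)

  if (isTRUE(st$simulate)) {
    outputs$mirna <- gen_mirna_arrays(sc)
    outputs$expression <- gen_expression_study(sc)
    outputs$utrs <- gen_utrs(sc, seed7)
    summary$n_mirna_probes <- sc$n_mirnas
    summary$n_genes <- sc$n_genes
  }
  if (isTRUE(st$mirna_de)) {
    tab <- mirna_de_table(outputs$mirna$array, span = cfg$mirna_de$span)
    hits <- call_de_mirnas(tab, alpha = cfg$mirna_de$alpha)
    truth <- outputs$mirna$truth$de_mirna_ids
    outputs$mirna_de <- tab
    outputs$mirna_de_hits <- hits
    summary$n_de_mirnas_called <- nrow(hits)
    summary$de_mirna_sensitivity <-
      if (length(truth)) mean(truth %in% hits$annotation) else NA_real_
    summary$de_mirna_false_positives <- sum(!hits$annotation %in% truth)
  }
  if (isTRUE(st$mrna_de)) {
    scr <- lapply(outputs$expression[c("overexpression", "differentiation")],
                  function(m) de_screen(m, "treatment", "control",
                                        fc_thresh = cfg$mrna_de$fc_thresh,
                                        alpha = cfg$mrna_de$alpha,
                                        direction = cfg$mrna_de$direction))
    outputs$screens <- scr
    truth <- outputs$expression$truth$true_target_ids
    summary$n_down_overexpression <- length(screen_hits(scr$overexpression))
    summary$n_down_differentiation <- length(screen_hits(scr$differentiation))
    summary$target_recovery_overexpression <-
      mean(truth %in% screen_hits(scr$overexpression))
    summary$target_recovery_differentiation <-
      mean(truth %in% screen_hits(scr$differentiation))
  }
  if (isTRUE(st$predict)) {
    pred <- predict_targets(seed7, outputs$utrs$utrs,
                            min_sites = cfg$predict$min_sites)
    outputs$predicted <- pred
    summary$n_predicted_targets <- nrow(pred)
    summary$predicted_equals_planted <-
      identical(sort(pred$gene_id), outputs$utrs$truth$true_target_ids)
  }
  if (isTRUE(st$integrate)) {
    tri <- tri_prong_intersect(screen_hits(outputs$screens$overexpression),
                               screen_hits(outputs$screens$differentiation),
                               outputs$predicted$gene_id)
    outputs$tri_prong <- tri
    truth <- outputs$expression$truth$true_target_ids
    summary$n_common <- length(tri$common)
    summary$common_truth_coverage <-
      if (length(truth)) mean(toupper(truth) %in% tri$common) else NA_real_
  }
  if (isTRUE(st$assay)) {
    tabs <- gen_assay_tables(cfg$assay$effect, sc)
    luc <- luciferase_repression(tabs$luciferase)
    outputs$assays <- list(tables = tabs, luciferase = luc)
    summary$luciferase_wt_repression <-
      luc$repression[luc$construct == "wt"]
    summary$luciferase_mut_repression <-
      luc$repression[luc$construct == "mut"]
    folds <- vapply(seq_len(sc$assay_reps), function(i) {
      q <- tabs$qpcr
      row <- function(s) {
        d <- q[q$sample == s & q$replicate == i, ]
        list(gene = d$gene, ct = d$ct,
             reference_cts = c(GAPDH = d$ref_GAPDH, ACTB = d$ref_ACTB))
      }
      ddct_fold(row("treated"), row("calibrator"))
    }, numeric(1))
    summary$qpcr_mean_fold <- mean(folds)
  }

  report <- structure(list(config = cfg, outputs = outputs, summary = summary),
                      class = "run_report")
  if (!is.null(cfg$outdir)) write_report(report)
  report
}

write_report <- function(report) {
  cfg <- report$config
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  o <- report$outputs
  if (!is.null(o$mirna)) {
    write_two_channel_tsv(o$mirna$array,
                          file.path(cfg$outdir, "mirna_arrays.tsv"),
                          file.path(cfg$outdir, "mirna_design.tsv"))
  }
  if (!is.null(o$mirna_de)) {
    write_mirna_de_tsv(o$mirna_de, file.path(cfg$outdir, "mirna_de.tsv"))
  }
  if (!is.null(o$screens)) {
    write_tsv(o$screens$overexpression,
              file.path(cfg$outdir, "screen_overexpression.tsv"))
    write_tsv(o$screens$differentiation,
              file.path(cfg$outdir, "screen_differentiation.tsv"))
  }
  if (!is.null(o$predicted)) {
    write_tsv(o$predicted, file.path(cfg$outdir, "predicted_targets.tsv"))
  }
  if (!is.null(o$tri_prong)) {
    write_gene_list(o$tri_prong$common, file.path(cfg$outdir, "common_genes.txt"))
  }
  yaml::write_yaml(report$summary, file.path(cfg$outdir, "summary.yaml"))
  invisible(report)
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run report\n")
  if (length(x$summary) == 0L) {
    cat("  (no stages enabled)\n")
    return(invisible(x))
  }
  for (k in names(x$summary)) {
    v <- x$summary[[k]]
    cat(sprintf("  %-32s %s\n", k,
                if (is.numeric(v)) format(v, digits = 4) else as.character(v)))
  }
  invisible(x)
}
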