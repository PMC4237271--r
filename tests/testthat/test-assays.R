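# Validation-assay math: insert assembly, mutant-motif inference,
# delta-delta-Ct, dual luciferase, plate quantification.

test_that("overlap-extension assembly reconstructs the template exactly", {
  set.seed(1)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE), collapse = "")
    pp <- primer_pair(substr(s, 1, 60), dna_revcomp(substr(s, 41, 100)))
    expect_equal(assemble_insert(pp), s)
  }
  # insufficient overlap errors and names the best partial overlap
  bad <- primer_pair("ACGTACGTACGTACGTACGT", "TTTTTTTTTTTTTTTTTTTT")
  expect_error(assemble_insert(bad), "best found")
  expect_error(primer_pair("ACGTX", "ACGT"), "outside")
})

test_that("the published reporter primers assemble to a 4-site wt insert", {
  fx <- load_fixtures()
  wt <- assemble_insert(fx$cloning_primers$RUNX2_wt_UTR)
  mut <- assemble_insert(fx$cloning_primers$RUNX2_mut_UTR)
  expect_equal(nchar(wt), 149L)
  expect_equal(nchar(wt), nchar(mut))

  seed <- seed_of(fx$mir320c)
  sites <- scan_utr(wt, seed)
  expect_equal(nrow(sites), 4L)
  expect_equal(sites$site_type, c("7mer-m8", "7mer-m8", "7mer-m8", "8mer"))
  expect_equal(sites$start, c(32L, 62L, 99L, 126L))
  expect_equal(nrow(scan_utr(mut, seed)), 0L)

  # adapter trimming removes the restriction tails but no seed site
  wt_trim <- assemble_insert(fx$cloning_primers$RUNX2_wt_UTR,
                             trim_adapters = TRUE)
  expect_false(grepl("ACTAGT", wt_trim, fixed = TRUE))
  expect_false(grepl("AAGCTT", wt_trim, fixed = TRUE))
  expect_equal(nrow(scan_utr(wt_trim, seed)), 4L)
})

test_that("the mutated motif is inferred from the primer table alone", {
  fx <- load_fixtures()
  motif <- infer_mutated_motif(fx$cloning_primers$RUNX2_wt_UTR,
                               fx$cloning_primers$RUNX2_mut_UTR)
  expect_equal(motif, "CAGCTTT")
  expect_equal(motif, rna_to_dna(dna_revcomp(rna_to_dna(seed_of(fx$mir320c)))))

  # identical constructs: no replaced blocks
  expect_error(infer_mutated_motif(fx$cloning_primers$RUNX2_wt_UTR,
                                   fx$cloning_primers$RUNX2_wt_UTR),
               "no replaced blocks")

  # synthetic construct: motif AACCGGT replaced by TTTTTTT at three loci
  set.seed(2)
  chunks <- replicate(4, paste(sample(c("A", "C", "G"), 25, replace = TRUE),
                               collapse = ""))
  wt_seq <- paste0(chunks[1], "AACCGGT", chunks[2], "AACCGGT", chunks[3],
                   "AACCGGT", chunks[4])
  mut_seq <- gsub("AACCGGT", "TTTTTTT", wt_seq, fixed = TRUE)
  mk <- function(s) primer_pair(substr(s, 1, 70),
                                dna_revcomp(substr(s, 51, nchar(s))))
  expect_equal(infer_mutated_motif(mk(wt_seq), mk(mut_seq)), "AACCGGT")
})

test_that("delta-delta-Ct quantification follows the Livak method", {
  cal <- list(gene = "RUNX2", ct = 26, reference_cts = c(GAPDH = 18, ACTB = 19))
  expect_equal(ddct_fold(cal, cal), 1)
  m <- cal; m$ct <- 25
  expect_equal(ddct_fold(m, cal), 2)                 # ddCt = -1 -> fold 2
  # shifting every Ct by a constant leaves the fold unchanged
  shifted <- lapply(list(m, cal), function(x) {
    x$ct <- x$ct + 3; x$reference_cts <- x$reference_cts + 3; x
  })
  expect_equal(ddct_fold(shifted[[1]], shifted[[2]]), ddct_fold(m, cal))
  # single-reference mode
  expect_equal(ddct_fold(m, cal, reference = "GAPDH"), 2)
  expect_error(ddct_fold(m, cal, reference = "B2M"), "missing")
  m2 <- m; m2$gene <- "PAX6"
  expect_error(ddct_fold(m2, cal), "same gene")

  # simulated plates recover a planted two-fold knockdown
  folds <- vapply(1:20, function(s) {
    tabs <- gen_assay_tables(0.5, small_cfg(rng_seed = 100L + s))
    q <- tabs$qpcr
    mean(vapply(unique(q$replicate), function(i) {
      row <- function(smp) {
        d <- q[q$sample == smp & q$replicate == i, ]
        list(gene = d$gene, ct = d$ct,
             reference_cts = c(GAPDH = d$ref_GAPDH, ACTB = d$ref_ACTB))
      }
      ddct_fold(row("treated"), row("calibrator"))
    }, numeric(1)))
  }, numeric(1))
  expect_equal(mean(folds), 0.5, tolerance = 0.05)
})

test_that("luciferase repression is ratio-based and gain-invariant", {
  wells <- expand.grid(construct = c("wt", "mut"),
                       mir = c("pre-miR-Neg", "pre-miR-320c"),
                       rep = 1:3, stringsAsFactors = FALSE)
  wells$firefly <- 1000
  wells$renilla <- 500
  flat <- luciferase_repression(wells)
  expect_equal(flat$repression, c(0, 0))
  expect_true(all(flat$p > 0.999))

  # scaling all renilla readings by 10 changes nothing
  tabs <- gen_assay_tables(0.5, small_cfg(rng_seed = 42L))
  r1 <- luciferase_repression(tabs$luciferase)
  scaled <- tabs$luciferase
  scaled$renilla <- scaled$renilla * 10
  expect_equal(luciferase_repression(scaled)$repression, r1$repression)

  expect_error(luciferase_repression(wells[wells$mir == "pre-miR-Neg", ]),
               ">= 2 wells")
  bad <- wells; bad$renilla[1] <- 0
  expect_error(luciferase_repression(bad), "renilla")
})

test_that("planted luciferase repression is recovered for wt but not mutant", {
  reps <- t(vapply(1:10, function(s) {
    tabs <- gen_assay_tables(0.5, small_cfg(rng_seed = 200L + s))
    r <- luciferase_repression(tabs$luciferase)
    c(wt = r$repression[r$construct == "wt"],
      mut = r$repression[r$construct == "mut"],
      p_wt = r$p[r$construct == "wt"])
  }, numeric(3)))
  expect_equal(mean(reps[, "wt"]), 0.5, tolerance = 0.05)
  expect_lt(abs(mean(reps[, "mut"])), 0.05)
  expect_true(all(reps[, "p_wt"] < 0.01))
})

test_that("plate quantification subtracts blanks and normalizes to controls", {
  wells <- list(c1 = rep(10, 9), c2 = rep(10, 9), t1 = rep(20, 9))
  expect_warning(res <- plate_quantify(wells, blanks = numeric(0),
                                       control = c("c1", "c2")), "blank")
  expect_equal(res$value[res$well == "t1"], 20)
  expect_equal(res$relative[res$well %in% c("c1", "c2")], c(1, 1))

  res2 <- plate_quantify(wells, blanks = c(2, 2), control = c("c1", "c2"))
  expect_equal(res2$value, c(8, 8, 18))

  # planted 2x signal over control with noise
  set.seed(3)
  noisy <- c(lapply(1:6, function(i) rnorm(9, 100, 5)),
             lapply(1:6, function(i) rnorm(9, 200, 5)))
  names(noisy) <- c(paste0("ctl", 1:6), paste0("trt", 1:6))
  res3 <- plate_quantify(noisy, blanks = rnorm(4, 0, 1),
                         control = paste0("ctl", 1:6))
  expect_equal(mean(res3$relative[grepl("trt", res3$well)]), 2,
               tolerance = 0.1)
  expect_error(plate_quantify(noisy, 0, control = "nope"), "missing")
})
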