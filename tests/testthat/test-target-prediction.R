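# Canonical seed-match prediction: seeds, motifs, scanning, families,
# inverse-correlation ranking.

test_that("seed extraction follows the positions-2-8 definition", {
  fx <- load_fixtures()
  expect_equal(unname(seed_of(fx$mir320c)), "AAAGCUG")
  expect_equal(seed_of("ACGUACGU"), "CGUACGU")           # last 7 of an 8-mer
  expect_equal(seed_of("AACGUACGUAAA"), seed_of("CACGUACGUAAA"))
  expect_error(seed_of("ACGUACG"), ">= 8 nt")
  expect_error(seed_of("ACGTACGTB"), "outside")
})

test_that("site motifs are the canonical reverse-complement constructions", {
  m <- site_motifs("AAAGCUG")
  expect_equal(m$m7m8, "CAGCTTT")
  expect_equal(m$m8site, "CAGCTTTA")
  expect_equal(m$m7A1, "AGCTTTA")
  # construction invariants over random seeds, incl. palindromic-ish ones
  set.seed(1)
  for (i in 1:25) {
    seed <- random_seed_heptamer()
    mm <- site_motifs(seed)
    expect_equal(nchar(mm$m8site), 8L)
    expect_equal(substr(mm$m8site, 8, 8), "A")
    expect_equal(substr(mm$m7A1, 7, 7), "A")
    expect_equal(substr(mm$m8site, 1, 7), mm$m7m8)
    expect_equal(dna_revcomp(mm$m7m8), rna_to_dna(seed))
  }
  expect_equal(site_motifs("ACGUACG")$m7m8, dna_revcomp("ACGTACG"))
})

test_that("the UTR scanner equals a sliding-window oracle", {
  set.seed(2)
  for (i in 1:50) {
    seed <- random_seed_heptamer()
    utr <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
                 collapse = "")
    got <- scan_utr(utr, seed)
    want <- bf_scan(utr, seed)
    expect_identical(got[c("site_type", "start", "end")], want)
  }
})

test_that("site records round-trip to their motifs and are never double-counted", {
  seed <- "AAAGCUG"
  m <- site_motifs(seed)
  utr <- paste0("TTTT", m$m8site, "TT", m$m7m8, "CTT", m$m7A1, "GG")
  sites <- scan_utr(utr, seed, utr_id = "u1")
  expect_equal(sites$site_type, c("8mer", "7mer-m8", "7mer-A1"))
  for (k in seq_len(nrow(sites))) {
    motif <- switch(sites$site_type[k], "8mer" = m$m8site,
                    "7mer-m8" = m$m7m8, "7mer-A1" = m$m7A1)
    expect_equal(substr(utr, sites$start[k], sites$end[k]), motif)
  }
  # an 8mer locus contributes no 7mer record at the same position
  utr8 <- paste0("CC", m$m8site, "CC")
  s8 <- scan_utr(utr8, seed)
  expect_equal(nrow(s8), 1L)
  expect_equal(s8$site_type, "8mer")
  # N never matches
  utrN <- sub("A$", "N", paste0("CC", m$m8site))
  expect_false("8mer" %in% scan_utr(utrN, seed)$site_type)
  # empty UTR is fine
  expect_equal(nrow(scan_utr("", seed)), 0L)
  # overlapping self-similar motifs are all reported
  pal_seed <- "UUUUUUU"   # motif AAAAAAA overlaps itself
  utr_pal <- paste0("G", strrep("A", 10), "G")
  expect_equal(nrow(scan_utr(utr_pal, pal_seed)),
               nrow(bf_scan(utr_pal, pal_seed)))
})

test_that("family grouping partitions by identical seed", {
  fam5 <- setNames(paste0(c("A", "C", "G", "U", "A"), "AAAGCUGGGUU"),
                   paste0("miR-x", 1:5))
  other <- c("miR-y" = "CCCCCCCCCCC")
  fams <- group_families(c(fam5, other))
  expect_length(fams, 2L)
  expect_equal(sort(lengths(lapply(fams, `[[`, "members"))), c(1L, 5L))
  expect_equal(group_families(character(0)), list())
  set.seed(3)
  seqs <- setNames(vapply(1:20, function(i) {
    paste(sample(c("A", "C", "G", "U"), 12, replace = TRUE), collapse = "")
  }, character(1)), paste0("m", 1:20))
  expect_length(group_families(seqs),
                length(unique(vapply(seqs, seed_of, character(1)))))
})

test_that("target prediction recovers exactly the planted target set", {
  cfg <- small_cfg(rng_seed = 5L)
  res <- gen_utrs(cfg, "AAAGCUG")
  pred <- predict_targets("AAAGCUG", res$utrs)
  expect_identical(pred$gene_id, res$truth$true_target_ids)
  expect_true(all(pred$n_sites == cfg$sites_per_target))
  expect_equal(pred$n_sites, pred$n_8mer + pred$n_7mer_m8 + pred$n_7mer_A1)

  # threshold logic: the four-site reporter insert is excluded at min_sites = 5
  fx <- load_fixtures()
  wt <- assemble_insert(fx$cloning_primers$RUNX2_wt_UTR)
  expect_equal(nrow(predict_targets("AAAGCUG", c(RUNX2 = wt), min_sites = 5)), 0L)
  expect_equal(predict_targets("AAAGCUG", c(RUNX2 = wt))$n_sites, 4L)

  # stable under input permutation; duplicate ids rejected
  shuffled <- res$utrs[sample(length(res$utrs))]
  expect_identical(predict_targets("AAAGCUG", shuffled), pred)
  expect_error(predict_targets("AAAGCUG", res$utrs[c(1, 1)]), "duplicate")
})

test_that("inverse-correlation ranking puts anti-correlated targets on top", {
  host <- c(1, 3, 2, 5, 4, 6)
  cands <- rbind(ANTI = -host, FLAT = rep(2, 6), NOISE = c(2, 1, 4, 3, 6, 5))
  rk <- hoctar_rank(host, cands)
  expect_equal(rk$gene[1], "ANTI")
  expect_equal(rk$correlation[1], -1)
  expect_equal(rk$percentile[1], 1 / 3)
  expect_true(rk$flagged[rk$gene == "FLAT"])
  expect_equal(rk$gene[nrow(rk)], "FLAT")   # flagged ranked last

  # planted anti-correlated target among 99 decoys lands in the top 10%
  set.seed(6)
  top10 <- replicate(40, {
    h <- rnorm(8)
    decoys <- matrix(rnorm(99 * 8), 99,
                     dimnames = list(sprintf("D%02d", 1:99), NULL))
    cand <- rbind(TARGET = -h + rnorm(8, 0, 0.2), decoys)
    r <- hoctar_rank(h, cand)
    r$percentile[r$gene == "TARGET"] <= 0.10
  })
  expect_gte(mean(top10), 0.95)

  # independent candidates sit mid-pack on average
  set.seed(7)
  mids <- replicate(50, {
    h <- rnorm(10)
    r <- hoctar_rank(h, matrix(rnorm(50 * 10), 50))
    mean(r$percentile[abs(r$correlation) < 0.2])
  })
  expect_equal(mean(mids), 0.5, tolerance = 0.1)

  expect_error(hoctar_rank(c(1, 2), matrix(1, 2, 2)), "3 paired samples")
})

test_that("FASTA readers return the package's alphabets", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">m1 some description", "AAAAGCUGGGUUGAGAGGGU"), fa)
  mir <- read_mirna_fasta(fa)
  expect_identical(names(mir), "m1")
  expect_match(mir, "^[ACGU]+$")
  fa2 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">utr1", "acgtacgtAACCGGTT"), fa2)
  expect_identical(unname(read_utr_fasta(fa2)), "ACGTACGTAACCGGTT")
})
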