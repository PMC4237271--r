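# Independent brute-force oracles used to cross-check the package
# implementations. These deliberately use different code paths (sliding
# windows, direct definitions, tail sums) from the functions under test.

# every overlapping window of `utr` compared literally against the three
# canonical motifs, then the 8mer-subsumption rule applied
bf_scan <- function(utr, seed) {
  motifs <- site_motifs(seed)
  n <- nchar(utr)
  win <- function(w) {
    if (n < w) return(integer(0))
    starts <- seq_len(n - w + 1L)
    starts[substring(utr, starts, starts + w - 1L) == switch(as.character(w),
      "8" = motifs$m8site, "7" = NA)]
  }
  s8 <- win(8L)
  starts7 <- seq_len(max(n - 6L, 0L))
  words7 <- substring(utr, starts7, starts7 + 6L)
  s7m8 <- setdiff(starts7[words7 == motifs$m7m8], s8)
  s7a1 <- setdiff(starts7[words7 == motifs$m7A1], s8 + 1L)
  out <- rbind(
    data.frame(site_type = rep("8mer", length(s8)), start = s8, end = s8 + 7L),
    data.frame(site_type = rep("7mer-m8", length(s7m8)), start = s7m8,
               end = s7m8 + 6L),
    data.frame(site_type = rep("7mer-A1", length(s7a1)), start = s7a1,
               end = s7a1 + 6L))
  out <- out[order(out$start, out$site_type), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Bonferroni straight from the definition
bf_bonferroni <- function(p) pmin(1, length(p) * p)

# Benjamini-Hochberg step-up straight from the definition:
# adj_(i) = min_{j >= i} min(1, m * p_(j) / j) on the sorted scale
bf_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  adj <- pmin(1, m * sorted / seq_len(m))
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[ord] <- adj
  out
}

# upper-tail hypergeometric P(X >= k) as an explicit sum of terms
bf_hyper_tail <- function(k, term_size, universe_size, query_size) {
  j <- k:min(term_size, query_size)
  sum(choose(term_size, j) * choose(universe_size - term_size, query_size - j)) /
    choose(universe_size, query_size)
}

# tiny config keeping generator-driven tests fast
small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_mirnas = 60L, n_de_mirnas = 6L, n_genes = 80L,
         n_true_targets = 8L, utr_length_range = c(200L, 400L),
         rng_seed = 7L),
    list(...))
  do.call(sim_config, args)
}

random_seed_heptamer <- function() {
  paste(sample(c("A", "C", "G", "U"), 7, replace = TRUE), collapse = "")
}
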