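# Small fixtures shared across test files; everything is generated in code.

tiny_generator <- function(seed = 7, ...) {
  generator_config(n_probes = 400, n_regions = 6,
                   structure_sizes = c(BS = 2, CX = 2, CB = 2),
                   signature_size = 12, stage_subset_size = 20,
                   seed = seed, ...)
}

tiny_match_config <- function(...) match_config(min_genes = 50, ...)

# 3-probe x 4-sample toy atlas with two regions in each of two structures.
toy_atlas <- function() {
  expr <- matrix(c(1, 5, 2,
                   2, 6, 3,
                   8, 1, 4,
                   9, 2, 5), nrow = 3,
                 dimnames = list(c("p1", "p2", "p3"), c("s1", "s2", "s3", "s4")))
  meta <- data.frame(
    sample_id = c("s1", "s2", "s3", "s4"),
    donor_id = c("d1", "d2", "d1", "d2"),
    stage = "adult",
    region_id = c("rA", "rA", "rB", "rB"),
    structure = c("CX", "CX", "CB", "CB"),
    stringsAsFactors = FALSE)
  atlas(expr, meta)
}

toy_counts <- function() {
  counts <- matrix(c(5, 15, 0,
                     10, 30, 0), nrow = 3,
                   dimnames = list(c("g1", "g2", "g3"), c("r1", "r2")))
  query_counts(counts, c(r1 = "grp", r2 = "grp"),
               gene_lengths = c(g1 = 1000, g2 = 2000, g3 = 500))
}

# Brute-force Wilcoxon rank-sum p over all label assignments of the pooled
# sample; independent of the package's enumeration (operates on raw values,
# recomputing ranks per assignment is unnecessary since ranks are fixed by
# the pooled multiset, but sums are recomputed from scratch here).
oracle_wilcoxon_p <- function(x, y, alternative) {
  pooled <- c(x, y)
  r <- rank(pooled)
  nx <- length(x)
  obs <- sum(r[seq_len(nx)])
  idx <- utils::combn(length(pooled), nx)
  sums <- apply(idx, 2L, function(i) sum(r[i]))
  pl <- mean(sums <= obs + 1e-9)
  pg <- mean(sums >= obs - 1e-9)
  switch(alternative,
         less = pl, greater = pg,
         two_sided = min(1, 2 * min(pl, pg)))
}

# Direct min-over-tails Benjamini-Hochberg oracle.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    j <- which(o == i)  # rank position of p[i]
    adj[i] <- min(1, min(m / seq(j, m) * p[o][seq(j, m)]))
  }
  adj
}
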