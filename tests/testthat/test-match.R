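test_that("rank_transform uses ascending average ranks", {
  expect_equal(unname(rank_transform(c(0.1, 5.0, 2.0))), c(1, 3, 2))
  expect_equal(unname(rank_transform(c(1, 1, 2))), c(1.5, 1.5, 3))
  expect_equal(unname(rank_transform(c(4, 4, 4))), c(2, 2, 2))
  expect_error(rank_transform(c(1, NA, 2)), "non-finite")
  # rank sum is G(G+1)/2 regardless of ties
  set.seed(3)
  for (i in 1:20) {
    v <- sample(1:6, 9, replace = TRUE)
    expect_equal(sum(rank_transform(v)), 9 * 10 / 2)
  }
})

test_that("rank differences are absolute, bounded, and zero at identity", {
  expect_equal(rank_difference(c(1, 2, 3), c(3, 2, 1)), c(2, 0, 2))
  expect_equal(rank_difference(c(1, 2, 3), c(1, 2, 3)), c(0, 0, 0))
  for (g in 3:6) {
    d <- rank_difference(seq_len(g), rev(seq_len(g)))
    expect_equal(max(d), g - 1)
    expect_true(all(d <= g - 1))
  }
  expect_equal(rank_difference(c(1, 2), c(2, 1), signed = TRUE), c(-1, 1))
  expect_error(rank_difference(1:3, 1:4), "mismatched")
})

test_that("signed rank differences of tie-free profiles sum to exactly zero", {
  set.seed(17)
  for (i in 1:25) {
    g <- sample(10:200, 1)
    q <- rank_transform(rnorm(g))
    r <- rank_transform(rnorm(g))
    expect_identical(sum(rank_difference(q, r, signed = TRUE)), 0)
  }
})

test_that("score_region matches exact enumeration on toy inputs", {
  sc <- score_region(c(0, 1, 2), c(10, 11, 12, 13))
  expect_equal(sc$p_value, 1 / 35, tolerance = 1e-12)
  expect_equal(sc$neglog10_p, -log10(1 / 35), tolerance = 1e-9)
  expect_equal(sc$median_abs_rank_diff, 1)
  # same distribution on both sides: no evidence of a better-than-typical match
  sc2 <- score_region(c(1, 2, 3), c(1, 2, 3))
  expect_equal(sc2$p_value,
               oracle_wilcoxon_p(c(1, 2, 3), c(1, 2, 3), "less"),
               tolerance = 1e-12)
  expect_gt(sc2$p_value, 0.4)
  expect_error(score_region(c(1, 2), numeric(0)), "empty")
})

test_that("a query equal to a region's mean profile is the unique best match", {
  syn <- generate_atlas(tiny_generator(seed = 3))
  atl <- syn$atlas
  sel <- atl$samples$region_id == "R04" & atl$samples$stage == "adult"
  prof <- rowMeans(atl$expr[, sel, drop = FALSE])
  qe <- setNames(unname(prof), unname(atl$gene_map[names(prof)]))
  res <- suppressMessages(
    score_all_regions(qe, atl, "adult", tiny_match_config()))
  expect_equal(res$region_id[1], "R04")
  top <- res[res$region_id == "R04", ]
  expect_equal(top$median_abs_rank_diff, 0)
  expect_equal(top$p_value, min(res$p_value))
  expect_lt(top$p_value, min(res$p_value[res$region_id != "R04"]))
})

test_that("region scores are invariant under monotone transforms of the query", {
  syn <- generate_atlas(tiny_generator(seed = 5))
  q <- generate_query(syn, "R02", "pcw15_16", seed = 6)
  cpm <- compute_cpm(q)
  qe <- setNames(rowMeans(cpm), rownames(cpm))
  cfg <- tiny_match_config()
  base <- suppressMessages(score_all_regions(qe, syn$atlas, "pcw15_16", cfg))
  mono <- suppressMessages(
    score_all_regions(log1p(qe) * 3 + 2, syn$atlas, "pcw15_16", cfg))
  expect_equal(base, mono, ignore_attr = TRUE)
})

test_that("a query exactly between two swap-symmetric regions ties them", {
  # sigma swaps gene pairs; region B is region A permuted by sigma and the
  # query is sigma-invariant, so the two rank-difference multisets coincide.
  pa <- c(1, 2, 7, 8, 13, 14)
  pb <- c(2, 1, 8, 7, 14, 13)
  q <- c(5, 5, 10, 10, 20, 20)
  genes <- paste0("g", 1:6)
  expr <- cbind(rA = pa, rB = pb)
  rownames(expr) <- genes
  meta <- data.frame(sample_id = c("rA", "rB"), donor_id = "d", stage = "adult",
                     region_id = c("rA", "rB"), structure = c("CX", "CB"),
                     stringsAsFactors = FALSE)
  atl <- atlas(expr, meta)
  res <- suppressMessages(
    score_all_regions(setNames(q, genes), atl, "adult",
                      match_config(min_genes = 2)))
  expect_equal(diff(res$neglog10_p), 0, tolerance = 1e-9)
})

test_that("structure scores follow the pooled rank-difference Wilcoxon", {
  syn <- generate_atlas(tiny_generator(seed = 9))
  q <- generate_query(syn, "R06", "adult", seed = 10)
  cpm <- compute_cpm(q)
  qe <- setNames(rowMeans(cpm), rownames(cpm))
  cfg <- tiny_match_config()
  res <- suppressMessages(score_all_regions(qe, syn$atlas, "adult", cfg))
  st <- score_structures(res, cfg)
  expect_setequal(st$structure, c("BS", "CX", "CB"))
  expect_equal(st$n_regions, rep(2L, 3))
  expect_true(all(st$neglog10_p >= 0))
  # CB holds the true region: it must dominate at the true stage
  expect_equal(st$structure[which.max(st$neglog10_p)], "CB")

  # independent recomputation of one structure score from the diffs matrix
  diffs <- attr(res, "rank_diffs")
  g <- nrow(diffs)
  members <- names(attr(res, "structure_of"))[attr(res, "structure_of") == "CB"]
  inside <- as.vector(diffs[, members])
  outside <- as.vector(diffs[, setdiff(colnames(diffs), members)])
  if (length(inside) > g) inside <- atlasmatch:::with_seed(cfg$seed, sample(inside, g))
  if (length(outside) > g) outside <- atlasmatch:::with_seed(cfg$seed + 1L, sample(outside, g))
  ref <- wilcoxon_rank_sum(inside, outside, alternative = "less",
                           exact_limit = cfg$exact_limit)
  expect_equal(st$neglog10_p[st$structure == "CB"],
               min(cfg$neglog10_cap, -ref$log_p / log(10)),
               tolerance = 1e-9)
})

test_that("swapping the structure labels of a two-region atlas swaps scores", {
  set.seed(42)
  pa <- sort(rnorm(120)); pb <- rnorm(120)
  genes <- paste0("g", seq_along(pa))
  mk <- function(s1, s2) {
    expr <- cbind(rA = pa, rB = pb); rownames(expr) <- genes
    meta <- data.frame(sample_id = c("rA", "rB"), donor_id = "d",
                       stage = "adult", region_id = c("rA", "rB"),
                       structure = c(s1, s2), stringsAsFactors = FALSE)
    atlas(expr, meta)
  }
  qe <- setNames(rnorm(120), genes)
  cfg <- match_config(min_genes = 2)
  r1 <- suppressMessages(score_all_regions(qe, mk("CX", "CB"), "adult", cfg))
  r2 <- suppressMessages(score_all_regions(qe, mk("CB", "CX"), "adult", cfg))
  s1 <- score_structures(r1, cfg)
  s2 <- score_structures(r2, cfg)
  # region rA is CX in the first atlas and CB in the second: the two
  # structure scores trade places exactly
  expect_equal(s1$neglog10_p[s1$structure == "CX"],
               s2$neglog10_p[s2$structure == "CB"])
  expect_equal(s1$neglog10_p[s1$structure == "CB"],
               s2$neglog10_p[s2$structure == "CX"])
  # all regions in one structure is an error
  r3 <- r1; attr(r3, "structure_of")[] <- "CX"; r3$structure <- "CX"
  expect_error(score_structures(r3, cfg), "two structures")
})

test_that("stage_comparison stacks per-stage results and handles edge cases", {
  syn <- generate_atlas(tiny_generator(seed = 13))
  q <- generate_query(syn, "R01", "adult", seed = 14)
  cpm <- compute_cpm(q)
  qe <- setNames(rowMeans(cpm), rownames(cpm))
  cfg <- tiny_match_config()
  single <- suppressMessages(stage_comparison(qe, syn$atlas, "adult", cfg))
  direct <- suppressMessages(score_all_regions(qe, syn$atlas, "adult", cfg))
  expect_equal(single$regions, direct, ignore_attr = TRUE)
  expect_equal(single$structures, score_structures(direct, cfg))
  empty <- stage_comparison(qe, syn$atlas, character(0), cfg)
  expect_equal(nrow(empty$structures), 0)
  expect_error(suppressMessages(
    stage_comparison(qe, syn$atlas, "pcw40", cfg)), "stage absent")
})

test_that("atlas_match returns a classed fit with printable summary", {
  syn <- generate_atlas(tiny_generator(seed = 19))
  q <- generate_query(syn, "R05", "pcw21_22", seed = 20)
  fit <- suppressMessages(atlas_match(q, syn$atlas, config = tiny_match_config()))
  expect_s3_class(fit, "atlas_match")
  expect_setequal(unique(fit$regions$stage), c("adult", "pcw15_16", "pcw21_22"))
  expect_equal(nrow(fit$structures), 9)
  expect_output(print(fit), "best region")
  expect_output(print(summary(fit)), "Structure scores")
})
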