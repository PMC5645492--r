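test_that("load_atlas round-trips a toy atlas and orders samples by header", {
  atl <- toy_atlas()
  td <- withr::local_tempdir()
  expr_p <- file.path(td, "expr.tsv"); meta_p <- file.path(td, "meta.tsv")
  write_atlas(atl, expr_p, meta_p)
  # shuffle metadata rows: loader must reorder to the expression header
  meta <- read.table(meta_p, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  write.table(meta[c(3, 1, 4, 2), ], meta_p, sep = "\t", quote = FALSE,
              row.names = FALSE)
  re <- load_atlas(expr_p, meta_p)
  expect_equal(re$expr, atl$expr)
  expect_equal(re$samples$sample_id, colnames(atl$expr))
  expect_equal(re$samples$region_id, atl$samples$region_id)
})

test_that("write/load/write is byte-stable at full printed precision", {
  syn <- generate_atlas(tiny_generator())
  td <- withr::local_tempdir()
  p1 <- file.path(td, "a.tsv"); m1 <- file.path(td, "am.tsv")
  p2 <- file.path(td, "b.tsv"); m2 <- file.path(td, "bm.tsv")
  write_atlas(syn$atlas, p1, m1)
  re <- load_atlas(p1, m1)
  write_atlas(re, p2, m2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(readLines(m1), readLines(m2))
})

test_that("load_atlas reports missing metadata and non-numeric cells by name", {
  atl <- toy_atlas()
  td <- withr::local_tempdir()
  expr_p <- file.path(td, "expr.tsv"); meta_p <- file.path(td, "meta.tsv")
  write_atlas(atl, expr_p, meta_p)
  meta <- read.table(meta_p, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  write.table(meta[-2, ], meta_p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_atlas(expr_p, meta_p), "s2")

  write_atlas(atl, expr_p, meta_p)
  lines <- readLines(expr_p)
  lines[2] <- sub("\t1\t", "\tNA\t", lines[2])
  writeLines(lines, expr_p)
  expect_error(load_atlas(expr_p, meta_p), "p1")

  # duplicate probe id
  write_atlas(atl, expr_p, meta_p)
  lines <- readLines(expr_p)
  writeLines(c(lines, lines[2]), expr_p)
  expect_error(load_atlas(expr_p, meta_p), "duplicate probe")
})

test_that("atlas constructor enforces stage set, coordinates and shape", {
  atl <- toy_atlas()
  meta <- atl$samples
  meta$stage <- "embryo"
  expect_error(atlas(atl$expr, meta), "declared set")
  expect_error(atlas(atl$expr, atl$samples[1:3, ]), "3 rows")
  meta2 <- atl$samples
  meta2$x <- c(1, 1, 2, 2); meta2$y <- c(1, NA, 2, 2); meta2$z <- c(1, 1, 2, 2)
  expect_error(atlas(atl$expr, meta2), "all of x, y, z")
})

test_that("filter_atlas applies the two-or-more-samples rule to probes and regions", {
  # 6 samples: region rC has a single sample and must be dropped with it;
  # probe q1 expressed in exactly 1 of 6 samples must be dropped.
  expr <- rbind(q1 = c(0, 0, 0, 5, 0, 0),
                q2 = c(1, 2, 3, 4, 5, 6),
                q3 = c(2, 0, 1, 0, 3, 1))
  colnames(expr) <- paste0("s", 1:6)
  meta <- data.frame(sample_id = paste0("s", 1:6), donor_id = "d",
                     stage = "adult",
                     region_id = c("rA", "rA", "rB", "rB", "rB", "rC"),
                     structure = "CX", stringsAsFactors = FALSE)
  atl <- atlas(expr, meta)
  filt <- suppressMessages(filter_atlas(atl, min_samples = 2))
  expect_setequal(rownames(filt$expr), c("q2", "q3"))
  expect_false("rC" %in% filt$samples$region_id)
  expect_equal(ncol(filt$expr), 5)
})

test_that("filter_atlas is idempotent and never grows the atlas", {
  syn <- generate_atlas(tiny_generator(seed = 11, noise_sd = 0.2))
  atl <- syn$atlas
  # induce sparsity so the probe filter has work to do
  atl$expr[atl$expr < stats::quantile(atl$expr, 0.2)] <- 0
  once <- suppressMessages(filter_atlas(atl, min_samples = 3,
                                        detection_threshold = 0))
  twice <- suppressMessages(filter_atlas(once, min_samples = 3,
                                         detection_threshold = 0))
  expect_identical(once$expr, twice$expr)
  expect_identical(once$samples, twice$samples)
  expect_lte(nrow(once$expr), nrow(atl$expr))
  expect_lte(ncol(once$expr), ncol(atl$expr))
})

test_that("filter_atlas with min_samples = 1 only drops never-expressed probes", {
  atl <- toy_atlas()
  atl$expr["p1", ] <- 0
  filt <- suppressMessages(filter_atlas(atl, min_samples = 1))
  expect_setequal(rownames(filt$expr), c("p2", "p3"))
  expect_equal(ncol(filt$expr), ncol(atl$expr))
})

test_that("harmonize_genes collapses multi-probe genes and intersects universes", {
  expr <- rbind(p1 = c(1, 2), p2 = c(3, 6), p3 = c(10, 20))
  colnames(expr) <- c("s1", "s2")
  meta <- data.frame(sample_id = c("s1", "s2"), donor_id = "d", stage = "adult",
                     region_id = c("rA", "rB"), structure = c("CX", "CB"),
                     stringsAsFactors = FALSE)
  atl <- atlas(expr, meta, gene_map = c(p1 = "G1", p2 = "G1", p3 = "G2"))
  h <- suppressMessages(harmonize_genes(atl, c("G1", "G2", "G3")))
  expect_equal(h$genes, c("G1", "G2"))
  expect_equal(unname(h$atlas_expr["G1", ]), c(2, 4))  # mean of p1, p2
  hm <- suppressMessages(harmonize_genes(atl, c("G1", "G2"), collapse = "median"))
  expect_equal(unname(hm$atlas_expr["G1", ]), c(2, 4))

  # identical universes (identity map)
  atl2 <- toy_atlas()
  h2 <- suppressMessages(harmonize_genes(atl2, rownames(atl2$expr)))
  expect_equal(h2$genes, rownames(atl2$expr))
  expect_equal(h2$atlas_expr, atl2$expr)

  expect_error(suppressMessages(harmonize_genes(atl, c("G9"))),
               "empty intersection")
})

test_that("query_counts validates integer counts and complete group map", {
  m <- matrix(c(1.5, 2, 3, 4), 2, dimnames = list(c("g1", "g2"), c("r1", "r2")))
  expect_error(query_counts(m, c(r1 = "a", r2 = "a")), "integer")
  m2 <- matrix(1:4, 2, dimnames = list(c("g1", "g2"), c("r1", "r2")))
  expect_error(query_counts(m2, c(r1 = "a")), "without group")
  q <- query_counts(m2, c(r1 = "a", r2 = "b"))
  expect_s3_class(q, "query_counts")
})
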