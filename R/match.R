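#' Matching configuration
#'
#' Collects the tunable parameters of the atlas-matching pipeline. Defaults
#' reproduce the published thresholds where the study states them
#' (`min_samples = 2`, `alpha = 0.01`, `lfc_threshold = 1.5`).
#'
#' @param min_samples minimum supporting samples for probes and regions in
#'   [filter_atlas()].
#' @param detection_threshold intensity above which a probe counts as
#'   expressed in a sample.
#' @param background_cap the pooled background of rank differences is
#'   subsampled to at most `background_cap` times the shared gene count.
#' @param exact_limit largest pooled sample size using the exact Wilcoxon
#'   branch.
#' @param min_genes minimum shared gene index size for region scoring.
#' @param alpha adjusted-p significance threshold for the DE stage.
#' @param lfc_threshold log2 fold-change threshold for the DE stage.
#' @param pseudocount log2 pseudocount for display transforms.
#' @param collapse probe-to-gene collapsing rule ("mean" or "median").
#' @param signed_diff use signed rather than absolute rank differences in the
#'   region test (non-default variant).
#' @param neglog10_cap cap on -log10 p to avoid infinities.
#' @param seed seed for the background subsampling (results are reproducible
#'   for a fixed configuration).
#' @return a list of class `match_config`.
#' @export
match_config <- function(min_samples = 2, detection_threshold = 0,
                         background_cap = 10, exact_limit = 20,
                         min_genes = 100, alpha = 0.01, lfc_threshold = 1.5,
                         pseudocount = 1, collapse = "mean",
                         signed_diff = FALSE, neglog10_cap = 320, seed = 1) {
  cfg <- list(min_samples = min_samples,
              detection_threshold = detection_threshold,
              background_cap = background_cap, exact_limit = exact_limit,
              min_genes = min_genes, alpha = alpha,
              lfc_threshold = lfc_threshold, pseudocount = pseudocount,
              collapse = collapse, signed_diff = signed_diff,
              neglog10_cap = neglog10_cap, seed = seed)
  class(cfg) <- "match_config"
  cfg
}

#' Rank-transform an expression profile
#'
#' Ascending ranks with average ranks at ties, so the rank sum is always
#' G(G+1)/2 for G genes.
#'
#' @param values finite numeric vector (length >= 2), optionally named by
#'   gene.
#' @return numeric vector of ranks, names preserved.
#' @export
rank_transform <- function(values) {
  if (length(values) < 2L) abort("need at least two values to rank")
  if (!all(is.finite(values))) abort("non-finite expression value")
  rank(values, ties.method = "average")
}

#' Per-gene rank differences between query and region profiles
#'
#' `d(g) = |rank_query(g) - rank_region(g)|` by default; the signed variant is
#' available for diagnostics.
#'
#' @param query_ranks,region_ranks rank vectors over the identical gene index
#'   (names, when present, must match in order).
#' @param signed return signed differences instead of absolute values.
#' @return numeric vector of rank differences.
#' @export
rank_difference <- function(query_ranks, region_ranks, signed = FALSE) {
  if (length(query_ranks) != length(region_ranks)) abort("mismatched gene index")
  if (!is.null(names(query_ranks)) && !is.null(names(region_ranks)) &&
      !identical(names(query_ranks), names(region_ranks))) {
    abort("mismatched gene index")
  }
  d <- query_ranks - region_ranks
  if (signed) d else abs(d)
}

neglog10_from_test <- function(test, cap) {
  nl <- if (!is.null(test$log_p)) -test$log_p / log(10) else -log10(test$p_value)
  min(cap, max(0, nl))
}

#' Score one region's rank differences against a background
#'
#' One-sided Wilcoxon rank-sum of the region's per-gene rank differences
#' against a pooled background of other regions' differences, alternative:
#' the region's differences are smaller (a better match than typical).
#'
#' @param region_diffs numeric vector of the region's rank differences.
#' @param background pooled rank differences of the comparison set.
#' @param exact_limit,neglog10_cap see [match_config()].
#' @return list with `w_statistic`, `p_value`, `neglog10_p`,
#'   `median_abs_rank_diff`.
#' @export
score_region <- function(region_diffs, background, exact_limit = 20,
                         neglog10_cap = 320) {
  if (!length(background)) abort("empty background")
  test <- wilcoxon_rank_sum(region_diffs, background, alternative = "less",
                            exact_limit = exact_limit)
  list(w_statistic = test$w_statistic,
       p_value = test$p_value,
       neglog10_p = neglog10_from_test(test, neglog10_cap),
       median_abs_rank_diff = stats::median(abs(region_diffs)))
}

# Per-region averaged profiles at one stage: genes x regions matrix.
region_profiles <- function(atlas_expr, samples, stage) {
  at_stage <- samples$stage == stage
  if (!any(at_stage)) abort("stage absent from atlas: ", stage)
  regs <- unique(samples$region_id[at_stage])
  prof <- vapply(regs, function(rg) {
    cols <- which(at_stage & samples$region_id == rg)
    rowMeans(atlas_expr[, cols, drop = FALSE])
  }, numeric(nrow(atlas_expr)))
  matrix(prof, nrow = nrow(atlas_expr),
         dimnames = list(rownames(atlas_expr), regs))
}

#' Score every atlas region against a query profile at one stage
#'
#' Builds per-region averaged expression profiles at the requested stage over
#' the gene index shared with the query, rank-transforms region profiles and
#' query, computes per-gene absolute rank differences, and tests each region's
#' differences against the pooled differences of all other regions at that
#' stage (subsampled to `background_cap` times the gene count, reproducibly
#' under the configuration seed). Entirely rank-based: any monotone transform
#' of the query leaves the scores unchanged.
#'
#' @param query_expr named numeric vector of query expression (one averaged
#'   sample; any monotone scale).
#' @param x an [atlas()] object (already filtered).
#' @param stage stage label to score at.
#' @param config a [match_config()].
#' @return data.frame with one row per region (`region_id`, `structure`,
#'   `stage`, `n_genes`, `median_abs_rank_diff`, `w_statistic`, `p_value`,
#'   `neglog10_p`), sorted by `neglog10_p` descending.
#' @export
score_all_regions <- function(query_expr, x, stage, config = match_config()) {
  stopifnot(inherits(x, "atlas"))
  if (is.null(names(query_expr))) abort("query_expr must be named by gene")
  harm <- harmonize_genes(x, names(query_expr), collapse = config$collapse)
  genes <- harm$genes
  if (length(genes) < config$min_genes) {
    abort(sprintf("shared gene index too small: %d < %d",
                  length(genes), config$min_genes))
  }
  prof <- region_profiles(harm$atlas_expr, x$samples, stage)
  g <- length(genes)
  q_ranks <- rank_transform(query_expr[genes])
  r_ranks <- apply(prof, 2L, rank_transform)
  diffs <- abs(q_ranks - r_ranks)
  diffs_test <- if (config$signed_diff) q_ranks - r_ranks else diffs
  regs <- colnames(prof)
  cap <- config$background_cap * g
  struct_of <- x$samples$structure[match(regs, x$samples$region_id)]
  rows <- lapply(seq_along(regs), function(j) {
    bg <- as.vector(diffs_test[, -j, drop = FALSE])
    if (length(bg) > cap) {
      bg <- with_seed(config$seed, sample(bg, cap))
    }
    sc <- score_region(diffs_test[, j], bg, exact_limit = config$exact_limit,
                       neglog10_cap = config$neglog10_cap)
    data.frame(region_id = regs[j], structure = struct_of[j], stage = stage,
               n_genes = g,
               median_abs_rank_diff = stats::median(diffs[, j]),
               w_statistic = sc$w_statistic, p_value = sc$p_value,
               neglog10_p = sc$neglog10_p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$neglog10_p, out$region_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rank_diffs") <- diffs_test
  attr(out, "structure_of") <- stats::setNames(struct_of, regs)
  out
}

#' Aggregate region evidence to anatomical structures
#'
#' Per structure, a one-sided Wilcoxon rank-sum of the member regions' pooled
#' per-gene rank differences against the non-member regions' pooled
#' differences (alternative: member differences smaller), reported as -log10
#' of that p-value. Each side is subsampled to at most the shared gene count
#' (reproducibly under the configuration seed), so the structure score has
#' the same information scale as a single region test and varies smoothly
#' with match strength — a rank-sum on the handful of per-region score values
#' saturates as soon as members and non-members separate completely, which
#' destroys cross-stage contrast.
#'
#' @param results a region score table from [score_all_regions()] (must carry
#'   its `rank_diffs` attribute).
#' @param config a [match_config()].
#' @return data.frame (`structure`, `stage`, `neglog10_p`, `n_regions`).
#' @export
score_structures <- function(results, config = match_config()) {
  diffs <- attr(results, "rank_diffs")
  if (is.null(diffs)) {
    abort("results must come from score_all_regions (rank_diffs attribute missing)")
  }
  struct_of <- attr(results, "structure_of")[colnames(diffs)]
  structs <- unique(results$structure)
  if (length(structs) < 2L) {
    abort("structure scoring needs at least two structures")
  }
  stage <- unique(results$stage)
  g <- nrow(diffs)
  out <- lapply(structs, function(st) {
    members <- colnames(diffs)[struct_of == st]
    if (!length(members)) abort("structure with zero member regions: ", st)
    inside <- as.vector(diffs[, members, drop = FALSE])
    outside <- as.vector(diffs[, setdiff(colnames(diffs), members), drop = FALSE])
    if (length(inside) > g) inside <- with_seed(config$seed, sample(inside, g))
    if (length(outside) > g) outside <- with_seed(config$seed + 1L, sample(outside, g))
    test <- wilcoxon_rank_sum(inside, outside, alternative = "less",
                              exact_limit = config$exact_limit)
    data.frame(structure = st, stage = stage,
               neglog10_p = neglog10_from_test(test, config$neglog10_cap),
               n_regions = length(members), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Compare structure scores across developmental stages
#'
#' Runs [score_all_regions()] and [score_structures()] at each requested
#' stage.
#'
#' @inheritParams score_all_regions
#' @param stages character vector of stage labels, each present in the atlas.
#' @return list with `regions` (row-bound region tables) and `structures`
#'   (one row per structure x stage).
#' @export
stage_comparison <- function(query_expr, x, stages, config = match_config()) {
  if (!length(stages)) {
    return(list(regions = data.frame(), structures = data.frame()))
  }
  per_stage <- lapply(stages, function(s) {
    res <- score_all_regions(query_expr, x, s, config)
    list(regions = res, structures = score_structures(res, config))
  })
  list(regions = do.call(rbind, lapply(per_stage, `[[`, "regions")),
       structures = do.call(rbind, lapply(per_stage, `[[`, "structures")))
}

#' Match a query transcriptome against a region-annotated atlas
#'
#' The main entry point: filters the atlas by detection support, harmonizes
#' gene universes, CPM-normalizes and replicate-averages the query counts,
#' and scores every atlas region and anatomical structure at every requested
#' developmental stage by rank-difference matching. Because scoring is purely
#' rank-based, the choice of query normalization unit does not change the
#' result beyond the replicate averaging step.
#'
#' @param query a [query_counts()] object.
#' @param x an [atlas()] object (unfiltered; filtering is applied here).
#' @param stages stage labels to score at; default all stages in the atlas,
#'   in order of first appearance.
#' @param config a [match_config()].
#' @return an object of class `atlas_match` with elements `regions` (region
#'   score table across queries and stages, with a `query` column), and
#'   `structures` (structure score table), `n_shared_genes`, `config`,
#'   `call`.
#' @seealso [score_all_regions()], [score_structures()], [export_voxel_scores()]
#' @examples
#' truth <- generate_atlas(generator_config(n_probes = 400, n_regions = 6,
#'   structure_sizes = c(BS = 2, CX = 2, CB = 2), signature_size = 12,
#'   stage_subset_size = 20, seed = 7))
#' q <- generate_query(truth$atlas, "R03", "adult", seed = 8)
#' fit <- atlas_match(q, truth$atlas, config = match_config(min_genes = 50))
#' summary(fit)
#' @export
atlas_match <- function(query, x, stages = NULL, config = match_config()) {
  stopifnot(inherits(query, "query_counts"), inherits(x, "atlas"))
  cl <- match.call()
  filt <- filter_atlas(x, config$min_samples, config$detection_threshold)
  if (is.null(stages)) stages <- unique(filt$samples$stage)
  cpm <- compute_cpm(query)
  avg <- average_replicates(cpm, query$group_map)
  all_regions <- list(); all_structs <- list()
  for (grp in colnames(avg)) {
    qe <- stats::setNames(avg[, grp], rownames(avg))
    cmp <- stage_comparison(qe, filt, stages, config)
    cmp$regions$query <- grp
    cmp$structures$query <- grp
    all_regions[[grp]] <- cmp$regions
    all_structs[[grp]] <- cmp$structures
  }
  regions <- do.call(rbind, all_regions)
  rownames(regions) <- NULL
  structures <- do.call(rbind, all_structs)
  rownames(structures) <- NULL
  res <- list(regions = regions, structures = structures,
              n_shared_genes = regions$n_genes[1L],
              stages = stages, atlas = filt, config = config, call = cl)
  class(res) <- "atlas_match"
  res
}

#' @export
print.atlas_match <- function(x, ...) {
  cat("Atlas rank-difference match\n")
  cat(sprintf("  %d shared genes, %d regions, stages: %s\n",
              x$n_shared_genes,
              length(unique(x$regions$region_id)),
              paste(x$stages, collapse = ", ")))
  for (grp in unique(x$regions$query)) {
    sub <- x$regions[x$regions$query == grp, ]
    best <- sub[which.max(sub$neglog10_p), ]
    cat(sprintf("  query '%s': best region %s (%s, %s), -log10 p = %.3f\n",
                grp, best$region_id, best$structure, best$stage,
                best$neglog10_p))
  }
  invisible(x)
}

#' @export
summary.atlas_match <- function(object, n = 5L, ...) {
  structure(list(fit = object, n = n), class = "summary.atlas_match")
}

#' @export
print.summary.atlas_match <- function(x, ...) {
  fit <- x$fit
  print(fit)
  cat("\nStructure scores (-log10 p):\n")
  wide <- stats::reshape(
    fit$structures[, c("structure", "stage", "query", "neglog10_p")],
    idvar = c("query", "structure"), timevar = "stage", direction = "wide")
  names(wide) <- sub("^neglog10_p\\.", "", names(wide))
  print(wide, row.names = FALSE, digits = 3)
  cat(sprintf("\nTop %d regions per query:\n", x$n))
  for (grp in unique(fit$regions$query)) {
    sub <- fit$regions[fit$regions$query == grp, ]
    print(utils::head(sub[, c("region_id", "structure", "stage",
                              "median_abs_rank_diff", "neglog10_p")], x$n),
          row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Plot structure scores of an atlas match
#'
#' Grouped barplot of structure-level -log10 p by developmental stage, one
#' panel per query group.
#'
#' @param x an `atlas_match` object.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.atlas_match <- function(x, ...) {
  queries <- unique(x$structures$query)
  old <- graphics::par(mfrow = c(1, length(queries)))
  on.exit(graphics::par(old))
  for (grp in queries) {
    sub <- x$structures[x$structures$query == grp, ]
    m <- tapply(sub$neglog10_p, list(sub$structure, sub$stage), identity)
    m <- m[, x$stages[x$stages %in% colnames(m)], drop = FALSE]
    graphics::barplot(m, beside = TRUE, legend.text = rownames(m),
                      main = grp, ylab = "-log10 p", xlab = "stage", ...)
  }
  invisible(x)
}
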