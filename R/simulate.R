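#' Synthetic atlas generator configuration
#'
#' Defines a desk-scale surrogate for a region-annotated brain expression
#' atlas: per-probe log2 baselines shared across samples, disjoint probe
#' signatures elevated per region and per structure, a stage-variable probe
#' subset shifted per developmental stage, and Gaussian per-sample noise.
#' Defaults emulate the structure of the real resource at reduced size:
#' 2,000 probes, 30 regions grouped 5/20/5 into brain stem, cortex and
#' cerebellum (echoing the real 59/362/80 imbalance), three stages with two
#' donors each.
#'
#' @param n_probes number of probes.
#' @param n_regions number of micro-dissected regions.
#' @param structure_sizes named integer vector summing to `n_regions`.
#' @param stages named integer vector: stage label -> donor count.
#' @param signature_size probes elevated per region (and per structure).
#' @param region_effect log2-units elevation of a region's signature probes.
#' @param structure_effect log2-units elevation shared by a structure.
#' @param stage_effect log2-units shift of the stage-variable probes.
#' @param stage_subset_size number of stage-variable probes per stage.
#' @param noise_sd per-sample Gaussian noise sd, log2 units.
#' @param region_profile_sd sd (log2 units) of a persistent per-region,
#'   per-probe deviation from the shared baseline — each region's
#'   idiosyncratic transcriptome-wide character, constant across donors and
#'   stages. Keeps structure-level separation partial, as in real
#'   region-annotated atlases, instead of perfectly clean.
#' @param baseline_mean,baseline_sd per-probe baseline log2 intensity is
#'   drawn from Normal(baseline_mean, baseline_sd) (log-normal intensities).
#' @param seed RNG seed; generation is fully deterministic given the config.
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(n_probes = 2000, n_regions = 30,
                             structure_sizes = c(BS = 5, CX = 20, CB = 5),
                             stages = c(adult = 2, pcw15_16 = 2, pcw21_22 = 2),
                             signature_size = 50, region_effect = 2.0,
                             structure_effect = 1.0, stage_effect = 1.0,
                             stage_subset_size = 100, noise_sd = 0.5,
                             region_profile_sd = 0.3,
                             baseline_mean = 7, baseline_sd = 2, seed = 1) {
  if (sum(structure_sizes) != n_regions) {
    abort("structure_sizes must sum to n_regions")
  }
  if (any(c(n_probes, n_regions, structure_sizes, stages,
            signature_size, stage_subset_size) <= 0)) {
    abort("all counts must be positive")
  }
  if (any(c(region_effect, structure_effect, stage_effect, noise_sd,
            region_profile_sd) < 0)) {
    abort("effects and noise_sd must be non-negative")
  }
  need <- length(structure_sizes) * signature_size +
    n_regions * signature_size + length(stages) * stage_subset_size
  if (need > n_probes) {
    abort(sprintf("disjoint signatures need %d probes but n_probes = %d",
                  need, n_probes))
  }
  cfg <- list(n_probes = n_probes, n_regions = n_regions,
              structure_sizes = structure_sizes, stages = stages,
              signature_size = signature_size, region_effect = region_effect,
              structure_effect = structure_effect, stage_effect = stage_effect,
              stage_subset_size = stage_subset_size, noise_sd = noise_sd,
              region_profile_sd = region_profile_sd,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              seed = seed)
  class(cfg) <- "generator_config"
  cfg
}

#' Generate a synthetic region-annotated expression atlas
#'
#' Expression of probe p in a sample of region r (structure c, stage t) is
#' `baseline(p) + dev(p, r) + structure_effect * [p in structure set of c] +
#' region_effect * [p in signature of r] + stage_effect * s(c, t, p) * [p in
#' stage set of t] + Normal(0, noise_sd)`, on the log2 scale (microarray-like
#' intensities), where `s(c, t, p)` is a fixed random sign per structure,
#' stage and stage-variable probe — developmental change is
#' structure-specific, so maturity is identifiable from the data rather than
#' a uniform shift shared by every region. Each region receives one sample
#' per donor per stage. Regions of a structure share a spatial cluster of
#' random 3-D coordinates so voxel exports have realistic geometry.
#'
#' @param config a [generator_config()].
#' @return an object of class `synthetic_atlas`: list with `atlas` (an
#'   [atlas()], probe ids `p0001...` mapped to gene symbols `g0001...`) and
#'   `truth` (config echo plus the signature probe sets).
#' @export
generate_atlas <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  np <- config$n_probes
  probes <- sprintf("p%04d", seq_len(np))
  genes <- sprintf("g%04d", seq_len(np))
  regions <- sprintf("R%02d", seq_len(config$n_regions))
  structure_of <- rep(names(config$structure_sizes), config$structure_sizes)
  baseline <- stats::rnorm(np, config$baseline_mean, config$baseline_sd)

  pool <- sample.int(np)
  take <- function(k) {
    out <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    out
  }
  structure_sets <- lapply(config$structure_sizes, function(...) take(config$signature_size))
  names(structure_sets) <- names(config$structure_sizes)
  region_sets <- lapply(regions, function(...) take(config$signature_size))
  names(region_sets) <- regions
  stage_sets <- lapply(config$stages, function(...) take(config$stage_subset_size))
  names(stage_sets) <- names(config$stages)
  # Developmental signal is structure-specific: each (structure, stage) pair
  # gets its own signed +/- stage_effect pattern over that stage's variable
  # probes, so maturity is identifiable and not a uniform shift that the
  # within-stage background would cancel.
  stage_patterns <- lapply(names(config$structure_sizes), function(...) {
    lapply(names(config$stages), function(...) {
      sample(c(-1, 1), config$stage_subset_size, replace = TRUE)
    })
  })
  names(stage_patterns) <- names(config$structure_sizes)
  for (cx in names(stage_patterns)) names(stage_patterns[[cx]]) <- names(config$stages)
  # Persistent per-region transcriptome-wide character (constant across
  # donors and stages), so structure-level separation stays partial.
  region_dev <- matrix(stats::rnorm(np * config$n_regions, 0,
                                    config$region_profile_sd),
                       nrow = np, ncol = config$n_regions)

  centers <- matrix(c(0, 0, 0, 40, 0, 0, 0, 40, 0), ncol = 3, byrow = TRUE)
  centers <- centers[(seq_along(config$structure_sizes) - 1) %% nrow(centers) + 1, ,
                     drop = FALSE]
  region_xyz <- t(vapply(seq_along(regions), function(i) {
    centers[match(structure_of[i], names(config$structure_sizes)), ] +
      stats::rnorm(3, 0, 4)
  }, numeric(3)))

  rows <- list(); cols <- list()
  for (t in names(config$stages)) {
    for (d in seq_len(config$stages[[t]])) {
      for (i in seq_along(regions)) {
        mu <- baseline + region_dev[, i]
        mu[structure_sets[[structure_of[i]]]] <- mu[structure_sets[[structure_of[i]]]] + config$structure_effect
        mu[region_sets[[i]]] <- mu[region_sets[[i]]] + config$region_effect
        mu[stage_sets[[t]]] <- mu[stage_sets[[t]]] +
          config$stage_effect * stage_patterns[[structure_of[i]]][[t]]
        val <- mu + stats::rnorm(np, 0, config$noise_sd)
        sid <- sprintf("%s_d%d_%s", t, d, regions[i])
        cols[[sid]] <- val
        rows[[sid]] <- data.frame(
          sample_id = sid, donor_id = sprintf("%s_donor%d", t, d), stage = t,
          region_id = regions[i], structure = structure_of[i],
          x = region_xyz[i, 1], y = region_xyz[i, 2], z = region_xyz[i, 3],
          stringsAsFactors = FALSE)
      }
    }
  }
  expr <- do.call(cbind, cols)
  rownames(expr) <- probes
  meta <- do.call(rbind, rows)
  rownames(meta) <- NULL
  truth <- list(config = config,
                structure_probes = lapply(structure_sets, function(i) probes[i]),
                region_signatures = lapply(region_sets, function(i) probes[i]),
                stage_probes = lapply(stage_sets, function(i) probes[i]),
                stage_patterns = stage_patterns)
  out <- list(atlas = atlas(expr, meta,
                            gene_map = stats::setNames(genes, probes),
                            stages = names(config$stages)),
              truth = truth)
  class(out) <- "synthetic_atlas"
  out
}

#' @export
print.synthetic_atlas <- function(x, ...) {
  cat("<synthetic_atlas>\n")
  print(x$atlas)
  invisible(x)
}

#' Simulate an RNA-seq query from a known atlas region and stage
#'
#' The expected expression of each gene is proportional to two to the power
#' of the region's mean log2 atlas profile at the requested stage, scaled so
#' the expected library size equals `mean_libsize`; counts are drawn per gene
#' and replicate from a negative binomial with variance `mu + dispersion *
#' mu^2` (Poisson when `dispersion = 0`). Gene ids are the atlas gene
#' symbols, so the query round-trips through [harmonize_genes()].
#'
#' @param x a `synthetic_atlas` (from [generate_atlas()]) or an [atlas()].
#' @param region,stage the true region and stage the query is drawn from.
#' @param n_reps replicates (default 3, mirroring triplicate well designs).
#' @param mean_libsize expected total counts per replicate.
#' @param dispersion negative-binomial dispersion (phi; default 0.1).
#' @param seed RNG seed.
#' @param group group label assigned to all replicates.
#' @return a [query_counts()] object with attribute `truth` = list(region,
#'   stage).
#' @export
generate_query <- function(x, region, stage, n_reps = 3, mean_libsize = 1e6,
                           dispersion = 0.1, seed = 1, group = "query") {
  atl <- if (inherits(x, "synthetic_atlas")) x$atlas else x
  stopifnot(inherits(atl, "atlas"))
  sel <- atl$samples$region_id == region & atl$samples$stage == stage
  if (!any(sel)) abort(sprintf("unknown region/stage: %s at %s", region, stage))
  prof <- rowMeans(atl$expr[, sel, drop = FALSE])
  w <- 2^prof
  mu <- w / sum(w) * mean_libsize
  set.seed(seed)
  counts <- vapply(seq_len(n_reps), function(r) {
    if (dispersion <= 0) {
      stats::rpois(length(mu), mu)
    } else {
      stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
    }
  }, numeric(length(mu)))
  gene_ids <- if (is.null(atl$gene_map)) rownames(atl$expr) else unname(atl$gene_map[rownames(atl$expr)])
  dimnames(counts) <- list(gene_ids, sprintf("%s_rep%d", group, seq_len(n_reps)))
  q <- query_counts(counts, stats::setNames(rep(group, n_reps), colnames(counts)))
  attr(q, "truth") <- list(region = region, stage = stage)
  q
}

#' Simulate a two-group count matrix with known differential genes
#'
#' Negative-binomial counts for two groups; `n_de` randomly chosen genes are
#' shifted by `lfc` log2 units in group B. Used to calibrate the DE stage.
#'
#' @param n_genes,n_de total and differential gene counts.
#' @param lfc log2 fold change applied to the differential genes in group B.
#' @param n_per_group replicates per group.
#' @param mean_libsize expected total counts per replicate.
#' @param dispersion negative-binomial dispersion.
#' @param seed RNG seed.
#' @return list with `query` (a [query_counts()] with groups "A" and "B") and
#'   `de_genes` (character vector of the truly differential gene ids).
#' @export
generate_de_counts <- function(n_genes = 2000, n_de = 0, lfc = 0,
                               n_per_group = 3, mean_libsize = 1e6,
                               dispersion = 0.1, seed = 1) {
  if (n_de > n_genes) abort("n_de must not exceed n_genes")
  if (n_genes < 1 || n_per_group < 1) abort("invalid sizes")
  set.seed(seed)
  genes <- sprintf("g%05d", seq_len(n_genes))
  base_log2 <- stats::rnorm(n_genes, 7, 2)
  de_idx <- sample.int(n_genes, n_de)
  shift <- numeric(n_genes)
  shift[de_idx] <- lfc
  w_a <- 2^base_log2
  w_b <- 2^(base_log2 + shift)
  mu_a <- w_a / sum(w_a) * mean_libsize
  mu_b <- w_b / sum(w_b) * mean_libsize
  draw <- function(mu) {
    if (dispersion <= 0) stats::rpois(length(mu), mu)
    else stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
  }
  counts <- cbind(
    vapply(seq_len(n_per_group), function(...) draw(mu_a), numeric(n_genes)),
    vapply(seq_len(n_per_group), function(...) draw(mu_b), numeric(n_genes)))
  dimnames(counts) <- list(genes, c(sprintf("A_rep%d", seq_len(n_per_group)),
                                    sprintf("B_rep%d", seq_len(n_per_group))))
  gm <- stats::setNames(rep(c("A", "B"), each = n_per_group), colnames(counts))
  list(query = query_counts(counts, gm), de_genes = genes[sort(de_idx)])
}

#' Write a complete synthetic fixture bundle
#'
#' Emits, in the exact dialects [load_atlas()] and [load_query_counts()]
#' read: `atlas_expr.tsv`, `atlas_meta.tsv`, `gene_map.tsv`,
#' `query_counts.tsv`, `query_groups.tsv`, and `truth.json`. Byte-stable for
#' a fixed configuration.
#'
#' @param out_dir output directory (created if needed).
#' @param config a [generator_config()].
#' @param region,stage true region and stage of the bundled query; defaults
#'   to the first cerebellar region at the last stage.
#' @param query_seed seed for the query counts (atlas uses `config$seed`).
#' @return named character vector of the written paths.
#' @export
write_fixture_bundle <- function(out_dir, config = generator_config(),
                                 region = NULL, stage = NULL,
                                 query_seed = config$seed + 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  syn <- generate_atlas(config)
  regions <- unique(syn$atlas$samples$region_id)
  structure_of <- syn$atlas$samples$structure[match(regions, syn$atlas$samples$region_id)]
  if (is.null(region)) {
    cb <- regions[structure_of == utils::tail(names(config$structure_sizes), 1)]
    region <- cb[1L]
  }
  if (is.null(stage)) stage <- utils::tail(names(config$stages), 1)
  q <- generate_query(syn, region, stage, seed = query_seed)
  paths <- c(expr = file.path(out_dir, "atlas_expr.tsv"),
             meta = file.path(out_dir, "atlas_meta.tsv"),
             gene_map = file.path(out_dir, "gene_map.tsv"),
             counts = file.path(out_dir, "query_counts.tsv"),
             groups = file.path(out_dir, "query_groups.tsv"),
             truth = file.path(out_dir, "truth.json"))
  write_atlas(syn$atlas, paths["expr"], paths["meta"])
  utils::write.table(
    data.frame(probe_id = names(syn$atlas$gene_map),
               gene_symbol = unname(syn$atlas$gene_map)),
    paths["gene_map"], sep = "\t", quote = FALSE, row.names = FALSE)
  write_tsv_matrix(q$counts, paths["counts"], id_col = "gene_id")
  utils::write.table(
    data.frame(sample_id = names(q$group_map), group = unname(q$group_map)),
    paths["groups"], sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- list(true_region = region, true_stage = stage,
                config = unclass(config),
                region_signatures = syn$truth$region_signatures)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}
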