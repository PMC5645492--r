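#' Reference expression atlas
#'
#' An `atlas` bundles a continuous expression matrix (probes x samples) with
#' per-sample anatomical metadata: donor, developmental stage, micro-dissected
#' region label, anatomical structure, and an optional 3-D voxel coordinate.
#' Atlas values are treated as already normalized intensities (microarray-like);
#' no background correction or re-normalization is applied.
#'
#' @param expr numeric matrix, probes in rows (unique rownames), samples in
#'   columns; all values finite.
#' @param samples data.frame with one row per expression column, columns
#'   `sample_id`, `donor_id`, `stage`, `region_id`, `structure` and optional
#'   numeric `x`, `y`, `z`. Row order must match the expression columns.
#' @param gene_map optional named character vector mapping probe id to gene
#'   symbol; required downstream when probe ids are not gene symbols.
#' @param stages character vector of admissible stage labels. Samples with a
#'   stage outside this set are rejected rather than silently grouped.
#' @return an object of class `atlas` with elements `expr`, `samples`,
#'   `gene_map`.
#' @export
atlas <- function(expr, samples, gene_map = NULL,
                  stages = c("adult", "pcw15_16", "pcw21_22")) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    abort("atlas expression must be a numeric matrix")
  }
  if (is.null(rownames(expr))) abort("atlas expression needs probe rownames")
  if (anyDuplicated(rownames(expr))) {
    abort("duplicate probe id: ",
          paste(unique(rownames(expr)[duplicated(rownames(expr))]), collapse = ", "))
  }
  if (!all(is.finite(expr))) {
    bad <- which(!is.finite(expr), arr.ind = TRUE)[1L, ]
    abort(sprintf("non-finite expression value at probe '%s', sample column %d",
                  rownames(expr)[bad[1L]], bad[2L]))
  }
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  req <- c("sample_id", "donor_id", "stage", "region_id", "structure")
  miss <- setdiff(req, names(samples))
  if (length(miss)) abort("metadata lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(samples) != ncol(expr)) {
    abort(sprintf("metadata has %d rows but expression has %d samples",
                  nrow(samples), ncol(expr)))
  }
  for (col in req) samples[[col]] <- trimws(as.character(samples[[col]]))
  if (any(samples$region_id == "")) abort("empty region label in metadata")
  bad_stage <- setdiff(unique(samples$stage), stages)
  if (length(bad_stage)) {
    abort("stage label(s) outside the declared set (",
          paste(stages, collapse = ", "), "): ", paste(bad_stage, collapse = ", "))
  }
  if (!is.null(colnames(expr)) && !identical(colnames(expr), samples$sample_id)) {
    abort("expression column names do not match metadata sample ids in order")
  }
  colnames(expr) <- samples$sample_id
  if (all(c("x", "y", "z") %in% names(samples))) {
    coord <- as.matrix(samples[, c("x", "y", "z")])
    partial <- rowSums(is.na(coord)) %in% c(1L, 2L)
    if (any(partial)) {
      abort("coordinate must be absent or all of x, y, z finite; offending sample: ",
            samples$sample_id[which(partial)[1L]])
    }
  }
  if (!is.null(gene_map)) {
    if (is.null(names(gene_map))) abort("gene_map must be named by probe id")
    gene_map <- gene_map[names(gene_map) %in% rownames(expr)]
  }
  structure(list(expr = expr, samples = samples, gene_map = gene_map),
            class = "atlas")
}

#' @export
print.atlas <- function(x, ...) {
  cat(sprintf("<atlas> %d probes x %d samples\n", nrow(x$expr), ncol(x$expr)))
  cat("  regions:   ", length(unique(x$samples$region_id)), "\n")
  cat("  structures:", paste(sort(unique(x$samples$structure)), collapse = ", "), "\n")
  cat("  stages:    ", paste(sort(unique(x$samples$stage)), collapse = ", "), "\n")
  invisible(x)
}

#' Query RNA-seq counts
#'
#' Gene-level non-negative integer counts (genes x replicate samples) with a
#' replicate-to-group assignment and optional gene lengths for RPKM.
#'
#' @param counts non-negative integer matrix with unique gene rownames and
#'   replicate colnames.
#' @param group_map named character vector: names are replicate ids, values
#'   group labels. Every replicate must be assigned to exactly one group.
#' @param gene_lengths optional named numeric vector of gene lengths in bp.
#' @return an object of class `query_counts`.
#' @export
query_counts <- function(counts, group_map, gene_lengths = NULL) {
  if (!is.matrix(counts) || !is.numeric(counts)) abort("counts must be a numeric matrix")
  if (is.null(rownames(counts))) abort("counts need gene rownames")
  if (anyDuplicated(rownames(counts))) abort("duplicate gene id in counts")
  if (!is_count_matrix(counts)) abort("counts must be non-negative integers")
  if (is.null(colnames(counts))) colnames(counts) <- paste0("rep", seq_len(ncol(counts)))
  group_map <- vapply(group_map, as.character, character(1))
  miss <- setdiff(colnames(counts), names(group_map))
  if (length(miss)) abort("replicate(s) without group assignment: ",
                          paste(miss, collapse = ", "))
  group_map <- group_map[colnames(counts)]
  if (!is.null(gene_lengths)) {
    if (is.null(names(gene_lengths))) abort("gene_lengths must be named")
    gene_lengths <- gene_lengths[rownames(counts)]
  }
  structure(list(counts = counts, group_map = group_map,
                 gene_lengths = gene_lengths),
            class = "query_counts")
}

#' @export
print.query_counts <- function(x, ...) {
  cat(sprintf("<query_counts> %d genes x %d replicates (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s: %d", names(table(x$group_map)),
                            as.integer(table(x$group_map))), collapse = ", ")))
  invisible(x)
}

read_tsv_matrix <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character", quote = "", comment.char = "")
  ids <- tab[[1L]]
  if (anyDuplicated(ids)) {
    abort("duplicate probe id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    abort(sprintf("non-numeric expression cell '%s' at row '%s', column '%s'",
                  vals[bad[1L], bad[2L]], ids[bad[1L]], colnames(vals)[bad[2L]]))
  }
  dimnames(num) <- list(ids, colnames(vals))
  num
}

#' Load an atlas from tab-separated files
#'
#' The expression file is a rectangular TSV whose first column holds probe ids
#' and whose header holds sample ids; the metadata file has one row per sample
#' id with columns `sample_id`, `donor_id`, `stage`, `region_id`, `structure`
#' and optional `x`, `y`, `z`. Gzip-compressed files are accepted
#' transparently. Samples are ordered as in the expression header; a sample id
#' without a metadata row is an error.
#'
#' @param expr_path path to the expression TSV.
#' @param meta_path path to the metadata TSV.
#' @param gene_map_path optional two-column TSV (probe_id, gene_symbol).
#' @inheritParams atlas
#' @return an [atlas()] object.
#' @export
load_atlas <- function(expr_path, meta_path, gene_map_path = NULL,
                       stages = c("adult", "pcw15_16", "pcw21_22")) {
  if (!file.exists(expr_path)) abort("expression file not found: ", expr_path)
  if (!file.exists(meta_path)) abort("metadata file not found: ", meta_path)
  expr <- read_tsv_matrix(expr_path)
  meta <- utils::read.table(meta_path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE,
                            quote = "", comment.char = "")
  miss <- setdiff(colnames(expr), meta$sample_id)
  if (length(miss)) {
    abort("metadata lacks row(s) for sample id(s): ", paste(miss, collapse = ", "))
  }
  meta <- meta[match(colnames(expr), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  gene_map <- NULL
  if (!is.null(gene_map_path)) {
    gm <- utils::read.table(gene_map_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, quote = "")
    gene_map <- stats::setNames(gm[[2L]], gm[[1L]])
  }
  atlas(expr, meta, gene_map = gene_map, stages = stages)
}

#' Write an atlas back to tab-separated files
#'
#' Values are printed at 15 significant digits so that a write/load cycle
#' reproduces the atlas exactly at full printed precision.
#'
#' @param x an [atlas()] object.
#' @param expr_path,meta_path output paths.
#' @export
write_atlas <- function(x, expr_path, meta_path) {
  stopifnot(inherits(x, "atlas"))
  write_tsv_matrix(x$expr, expr_path, id_col = "probe_id")
  utils::write.table(x$samples, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(expr_path, meta_path))
}

write_tsv_matrix <- function(mat, path, id_col = "gene_id") {
  out <- data.frame(id = rownames(mat),
                    apply(mat, 2L, format_full),
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(out)[1L] <- id_col
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load query counts from tab-separated files
#'
#' @param counts_path TSV with gene ids in the first column, replicate ids in
#'   the header, integer counts in the body.
#' @param groups_path two-column TSV (`sample_id`, `group`) assigning each
#'   replicate to a phenotypic group.
#' @param lengths_path optional two-column TSV (`gene_id`, `length_bp`).
#' @return a [query_counts()] object.
#' @export
load_query_counts <- function(counts_path, groups_path, lengths_path = NULL) {
  if (!file.exists(counts_path)) abort("counts file not found: ", counts_path)
  if (!file.exists(groups_path)) abort("group map file not found: ", groups_path)
  counts <- read_tsv_matrix(counts_path)
  grp <- utils::read.table(groups_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "")
  group_map <- stats::setNames(as.character(grp[[2L]]), grp[[1L]])
  lengths <- NULL
  if (!is.null(lengths_path)) {
    lt <- utils::read.table(lengths_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, quote = "")
    lengths <- stats::setNames(as.numeric(lt[[2L]]), lt[[1L]])
  }
  query_counts(counts, group_map, gene_lengths = lengths)
}

#' Filter an atlas by detection support
#'
#' Mirrors the cross-study filtering rule: keep only regions assayed in at
#' least `min_samples` samples and only probes called expressed (value above
#' `detection_threshold`) in at least `min_samples` samples. Regions are
#' filtered first and probes are then assessed on the retained samples, which
#' makes the operation idempotent.
#'
#' @param x an [atlas()] object.
#' @param min_samples minimum number of supporting samples (default 2).
#' @param detection_threshold intensity above which a probe is called
#'   expressed in a sample (default 0).
#' @return the filtered [atlas()].
#' @export
filter_atlas <- function(x, min_samples = 2, detection_threshold = 0) {
  stopifnot(inherits(x, "atlas"))
  if (min_samples < 1) abort("min_samples must be >= 1")
  region_n <- table(x$samples$region_id)
  keep_regions <- names(region_n)[region_n >= min_samples]
  keep_samples <- x$samples$region_id %in% keep_regions
  if (!any(keep_samples)) abort("empty atlas after region filtering")
  expr <- x$expr[, keep_samples, drop = FALSE]
  samples <- x$samples[keep_samples, , drop = FALSE]
  rownames(samples) <- NULL
  expressed_in <- rowSums(expr > detection_threshold)
  expr <- expr[expressed_in >= min_samples, , drop = FALSE]
  if (nrow(expr) == 0L) abort("empty atlas after probe filtering")
  message(sprintf(
    "filter_atlas: %d/%d probes, %d/%d regions, %d/%d samples retained",
    nrow(expr), nrow(x$expr), length(keep_regions), length(region_n),
    ncol(expr), ncol(x$expr)))
  atlas(expr, samples, gene_map = x$gene_map,
        stages = unique(c(samples$stage,
                          c("adult", "pcw15_16", "pcw21_22"))))
}

#' Harmonize atlas probes and query genes onto a shared gene index
#'
#' Maps atlas probes to gene symbols through the atlas `gene_map` (identity
#' when absent), collapses multi-probe genes by the chosen rule, and
#' intersects with the query's gene universe.
#'
#' @param x an [atlas()] object.
#' @param query a [query_counts()] object or a character vector of gene ids.
#' @param collapse how to collapse multiple probes of one gene: "mean"
#'   (default) or "median".
#' @return a list with `genes` (the ordered shared index, following the query
#'   order), and `atlas_expr` (collapsed genes x samples matrix restricted to
#'   the shared index).
#' @export
harmonize_genes <- function(x, query, collapse = c("mean", "median")) {
  stopifnot(inherits(x, "atlas"))
  collapse <- match.arg(collapse)
  qgenes <- if (inherits(query, "query_counts")) rownames(query$counts) else as.character(query)
  probe_gene <- if (is.null(x$gene_map)) {
    stats::setNames(rownames(x$expr), rownames(x$expr))
  } else {
    x$gene_map
  }
  probes <- intersect(rownames(x$expr), names(probe_gene))
  gene_of <- probe_gene[probes]
  shared <- qgenes[qgenes %in% unique(gene_of)]
  if (!length(shared)) abort("empty intersection between atlas genes and query genes")
  fun <- if (collapse == "mean") colMeans else function(m) apply(m, 2L, stats::median)
  idx <- split(probes, gene_of)[shared]
  atlas_expr <- t(vapply(idx, function(p) {
    m <- x$expr[p, , drop = FALSE]
    if (nrow(m) == 1L) m[1L, ] else fun(m)
  }, numeric(ncol(x$expr))))
  dimnames(atlas_expr) <- list(shared, colnames(x$expr))
  message(sprintf("harmonize_genes: %d shared genes (query %d, atlas %d mapped)",
                  length(shared), length(qgenes), length(unique(gene_of))))
  list(genes = shared, atlas_expr = atlas_expr)
}
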