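#' Normalized expression matrix
#'
#' A plain numeric matrix tagged with the unit it carries and, optionally, the
#' TMM scale factors that produced it. All values must be finite; TMM factors,
#' when present, have geometric mean 1.
#'
#' @param values numeric genes x samples matrix.
#' @param unit one of "cpm", "rpkm", "log2cpm", "centered_log2cpm".
#' @param tmm_factors optional per-sample positive scale factors.
#' @return the matrix with class `norm_matrix` and attributes `unit`,
#'   `tmm_factors`.
#' @export
norm_matrix <- function(values,
                        unit = c("cpm", "rpkm", "log2cpm", "centered_log2cpm"),
                        tmm_factors = NULL) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values)) abort("values must be a numeric matrix")
  if (!all(is.finite(values))) abort("normalized matrix contains non-finite values")
  if (!is.null(tmm_factors)) {
    if (any(tmm_factors <= 0)) abort("tmm_factors must be positive")
    if (abs(mean(log(tmm_factors))) > 1e-9) {
      abort("tmm_factors must have geometric mean 1")
    }
  }
  structure(values, unit = unit, tmm_factors = tmm_factors,
            class = c("norm_matrix", "matrix", "array"))
}

#' @export
print.norm_matrix <- function(x, ...) {
  cat(sprintf("<norm_matrix> %d x %d, unit = %s\n", nrow(x), ncol(x), attr(x, "unit")))
  invisible(x)
}

#' Counts per million
#'
#' `cpm(g,s) = count(g,s) / (libsize(s) * factor(s)) * 1e6`, where the library
#' size is the column sum and `factors` are optional per-sample scale factors
#' (for example from [tmm_factors()]).
#'
#' @param x a [query_counts()] object or numeric count matrix.
#' @param factors optional per-sample positive scale factors (recycled by
#'   column order, or named by sample).
#' @return a `cpm`-unit [norm_matrix()].
#' @export
compute_cpm <- function(x, factors = NULL) {
  counts <- count_matrix(x)
  lib <- colSums(counts)
  if (is.null(factors)) factors <- rep(1, ncol(counts))
  if (!is.null(names(factors)) && !is.null(colnames(counts))) {
    factors <- factors[colnames(counts)]
  }
  eff <- lib * factors
  if (any(eff <= 0)) {
    abort("zero effective library size in sample(s): ",
          paste(colnames(counts)[eff <= 0], collapse = ", "))
  }
  norm_matrix(sweep(counts, 2L, eff, "/") * 1e6, unit = "cpm",
              tmm_factors = NULL)
}

#' Reads per kilobase per million mapped reads
#'
#' `rpkm(g,s) = count(g,s) / (length_kb(g) * libsize_millions(s))`.
#'
#' @param x a [query_counts()] object carrying `gene_lengths`, or a count
#'   matrix if `gene_lengths` is supplied directly.
#' @param gene_lengths per-gene lengths in base pairs (named when `x` is a
#'   matrix with rownames).
#' @return an `rpkm`-unit [norm_matrix()].
#' @export
compute_rpkm <- function(x, gene_lengths = NULL) {
  counts <- count_matrix(x)
  if (is.null(gene_lengths) && inherits(x, "query_counts")) {
    gene_lengths <- x$gene_lengths
  }
  if (is.null(gene_lengths)) abort("gene lengths are required for RPKM")
  if (!is.null(names(gene_lengths)) && !is.null(rownames(counts))) {
    gene_lengths <- gene_lengths[rownames(counts)]
  }
  if (anyNA(gene_lengths) || any(gene_lengths <= 0)) {
    abort("missing or non-positive gene length")
  }
  lib <- colSums(counts)
  if (any(lib <= 0)) abort("zero library size")
  vals <- counts / (gene_lengths / 1e3)
  norm_matrix(sweep(vals, 2L, lib / 1e6, "/"), unit = "rpkm")
}

#' Trimmed mean of M-values scale factors
#'
#' Between-sample scale factors following the published TMM procedure: per
#' sample, log2 expression ratios (M) and average log intensities (A) against
#' a reference sample are computed over genes positive in both libraries, the
#' most extreme 30% of M values and 5% of A values are trimmed, and the factor
#' is two to the precision-weighted mean of the remaining M values. Precision
#' weights use the delta-method binomial variance of M evaluated on the
#' proportion scale (a common nominal depth), so the factors depend on
#' relative expression only and are exactly invariant to rescaling any
#' single library; at equal library sizes they coincide with the classical
#' weights. Factors are rescaled to geometric mean 1, so only their ratios
#' matter.
#'
#' @param x a [query_counts()] object or numeric count matrix (>= 2 samples).
#' @param ref_sample reference sample id or column index; by default the
#'   sample whose upper-quartile expression is closest to the mean
#'   upper-quartile.
#' @param logratio_trim,abs_trim trim fractions for M and A (defaults 0.30 and
#'   0.05).
#' @return named per-sample scale factors with geometric mean 1.
#' @export
tmm_factors <- function(x, ref_sample = NULL,
                        logratio_trim = 0.30, abs_trim = 0.05) {
  counts <- count_matrix(x)
  if (ncol(counts) < 2L) abort("TMM needs at least two samples")
  if (is.null(colnames(counts))) colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  lib <- colSums(counts)
  if (any(lib <= 0)) abort("zero library size")
  if (is.null(ref_sample)) {
    uq <- apply(sweep(counts, 2L, lib, "/"), 2L, stats::quantile, probs = 0.75)
    ref <- which.min(abs(uq - mean(uq)))
  } else if (is.character(ref_sample)) {
    ref <- match(ref_sample, colnames(counts))
    if (is.na(ref)) abort("unknown reference sample: ", ref_sample)
  } else {
    ref <- as.integer(ref_sample)
  }
  f <- vapply(seq_len(ncol(counts)), function(k) {
    tmm_pair(counts[, k], counts[, ref], lib[k], lib[ref],
             logratio_trim, abs_trim)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

# One TMM factor: sample obs against reference, both with known library sizes.
tmm_pair <- function(obs, ref, n_obs, n_ref, logratio_trim, abs_trim) {
  pos <- obs > 0 & ref > 0
  if (!any(pos)) abort("a sample shares no doubly-nonzero gene with the reference")
  obs <- obs[pos]; ref <- ref[pos]
  p_obs <- obs / n_obs; p_ref <- ref / n_ref
  m <- log2(p_obs / p_ref)
  a <- 0.5 * log2(p_obs * p_ref)
  # binomial delta-method precision on the proportion scale (common nominal
  # depth): depends on relative expression only, so factors are exactly
  # invariant to rescaling any library; identical to the classical weights
  # whenever library sizes are equal.
  w <- (1 - p_obs) / p_obs + (1 - p_ref) / p_ref
  fin <- is.finite(m) & is.finite(a) & w > 0
  m <- m[fin]; a <- a[fin]; w <- w[fin]
  if (!length(m)) return(1)
  if (max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * logratio_trim) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * abs_trim) + 1
  hi_a <- n + 1 - lo_a
  keep <- rank(m) >= lo_m & rank(m) <= hi_m & rank(a) >= lo_a & rank(a) <= hi_a
  if (!any(keep)) return(1)
  2^(sum(m[keep] / w[keep]) / sum(1 / w[keep]))
}

#' Log2 transform with pseudocount
#'
#' @param mat numeric matrix or [norm_matrix()].
#' @param pseudocount non-negative offset added before taking log2; must be
#'   positive when the matrix contains zeros.
#' @return a `log2cpm`-unit [norm_matrix()] (unit preserved for rpkm input is
#'   not tracked; the log scale is what downstream ranking consumes).
#' @export
log2_transform <- function(mat, pseudocount = 1) {
  if (pseudocount < 0) abort("pseudocount must be non-negative")
  if (pseudocount == 0 && any(mat <= 0)) {
    abort("zero or negative value with zero pseudocount")
  }
  out <- log2(unclass(mat) + pseudocount)
  norm_matrix(out, unit = "log2cpm", tmm_factors = attr(mat, "tmm_factors"))
}

#' Median-center a matrix
#'
#' Subtracts the median along the chosen axis; after centering, medians along
#' that axis are zero. The conventional order in this pipeline is log2 first,
#' then gene-wise centering.
#'
#' @param mat numeric matrix or [norm_matrix()].
#' @param axis "gene" (rows, default) or "sample" (columns).
#' @return a `centered_log2cpm`-unit [norm_matrix()].
#' @export
median_center <- function(mat, axis = c("gene", "sample")) {
  axis <- match.arg(axis)
  if (!length(mat)) abort("empty matrix")
  v <- unclass(mat)
  out <- if (axis == "gene") {
    v - apply(v, 1L, stats::median)
  } else {
    sweep(v, 2L, apply(v, 2L, stats::median))
  }
  norm_matrix(out, unit = "centered_log2cpm",
              tmm_factors = attr(mat, "tmm_factors"))
}

#' Average replicate columns within groups
#'
#' Arithmetic mean of replicate columns per group; output columns follow the
#' first appearance of each group in `group_map`.
#'
#' @param mat numeric matrix or [norm_matrix()] with replicate columns.
#' @param group_map named character vector replicate -> group covering every
#'   column of `mat`.
#' @return matrix with one column per group (attributes of `mat` preserved
#'   where meaningful).
#' @export
average_replicates <- function(mat, group_map) {
  v <- unclass(mat)
  if (is.null(colnames(v))) colnames(v) <- names(group_map)
  miss <- setdiff(colnames(v), names(group_map))
  if (length(miss)) abort("unmapped replicate(s): ", paste(miss, collapse = ", "))
  groups <- unique(unname(group_map[colnames(v)]))
  out <- vapply(groups, function(g) {
    cols <- colnames(v)[group_map[colnames(v)] == g]
    if (!length(cols)) abort("empty group: ", g)
    rowMeans(v[, cols, drop = FALSE])
  }, numeric(nrow(v)))
  out <- matrix(out, nrow = nrow(v), dimnames = list(rownames(v), groups))
  attr(out, "unit") <- attr(mat, "unit")
  out
}
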