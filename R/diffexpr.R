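#' Expression filter for differential testing
#'
#' Keeps a gene when at least one phenotypic group shows one count per
#' million or more in every replicate of that group (CPM on raw library
#' sizes).
#'
#' @param query a [query_counts()] object.
#' @param cpm_threshold CPM threshold (default 1).
#' @return character vector of retained gene ids.
#' @export
filter_expressed <- function(query, cpm_threshold = 1) {
  stopifnot(inherits(query, "query_counts"))
  cpm <- unclass(compute_cpm(query))
  groups <- unique(unname(query$group_map))
  keep <- Reduce(`|`, lapply(groups, function(g) {
    cols <- names(query$group_map)[query$group_map == g]
    rowSums(cpm[, cols, drop = FALSE] >= cpm_threshold) == length(cols)
  }))
  rownames(query$counts)[keep]
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (delegates to
#' [stats::p.adjust()] with `method = "BH"` after validating the input range).
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Two-group differential expression on log2-CPM
#'
#' A deliberately simple DE stage: genes passing [filter_expressed()] are
#' TMM-normalized, transformed to log2-CPM with a 0.5-count offset
#' (`log2((count + 0.5) / (effective libsize + 1) * 1e6)`), and tested with a
#' per-gene pooled-variance two-sample t-test. This approximates a
#' moderated-variance fit without precision weights or empirical-Bayes
#' shrinkage; the output is labelled accordingly. A gene is flagged
#' significant when its BH-adjusted p is below `alpha` and its absolute log2
#' fold change is at least `lfc_threshold`.
#'
#' @param query a [query_counts()] object.
#' @param group1,group2 group labels to contrast; `log_fc` is group2 minus
#'   group1 mean log2-CPM.
#' @param alpha adjusted-p threshold (default 0.01).
#' @param lfc_threshold log2 fold-change threshold (default 1.5; use
#'   `log2(1.5)` for a plain 1.5-fold cutoff).
#' @param var_floor lower bound on the pooled variance for degenerate genes
#'   (flagged in the output).
#' @return data.frame (`gene_id`, `log_fc`, `t_statistic`, `p_value`,
#'   `adj_p`, `significant`, `low_variance`) with attribute
#'   `method = "approximate limma-voom"`.
#' @export
de_test <- function(query, group1, group2, alpha = 0.01, lfc_threshold = 1.5,
                    var_floor = 1e-8) {
  stopifnot(inherits(query, "query_counts"))
  cols1 <- names(query$group_map)[query$group_map == group1]
  cols2 <- names(query$group_map)[query$group_map == group2]
  if (length(cols1) < 2L || length(cols2) < 2L) {
    abort("need at least two replicates per group")
  }
  sub <- query_counts(query$counts[, c(cols1, cols2), drop = FALSE],
                      query$group_map[c(cols1, cols2)],
                      gene_lengths = query$gene_lengths)
  keep <- filter_expressed(sub)
  counts <- sub$counts[keep, , drop = FALSE]
  if (!nrow(counts)) abort("no gene passes the expression filter")
  factors <- tmm_factors(counts)
  eff <- colSums(counts) * factors
  logcpm <- log2(sweep(counts + 0.5, 2L, eff + 1, "/") * 1e6)
  m1 <- rowMeans(logcpm[, cols1, drop = FALSE])
  m2 <- rowMeans(logcpm[, cols2, drop = FALSE])
  n1 <- length(cols1); n2 <- length(cols2)
  v1 <- apply(logcpm[, cols1, drop = FALSE], 1L, stats::var)
  v2 <- apply(logcpm[, cols2, drop = FALSE], 1L, stats::var)
  pooled <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  low_var <- pooled < var_floor
  pooled <- pmax(pooled, var_floor)
  se <- sqrt(pooled * (1 / n1 + 1 / n2))
  lfc <- m2 - m1
  tstat <- lfc / se
  p <- 2 * stats::pt(abs(tstat), df = n1 + n2 - 2, lower.tail = FALSE)
  adj <- bh_adjust(p)
  out <- data.frame(gene_id = keep, log_fc = lfc, t_statistic = tstat,
                    p_value = p, adj_p = adj,
                    significant = adj < alpha & abs(lfc) >= lfc_threshold,
                    low_variance = low_var,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (any(low_var)) {
    warning(sum(low_var), " gene(s) had near-zero within-group variance; ",
            "variance floored", call. = FALSE)
  }
  attr(out, "method") <- "approximate limma-voom"
  out
}
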