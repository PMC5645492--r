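#' Export region scores at voxel coordinates
#'
#' Writes one CSV row per scored region that carries a 3-D coordinate in the
#' atlas metadata (`region_id,structure,x,y,z,neglog10_p`), for 3-D
#' projections of match scores. Regions without coordinates are skipped and
#' counted in a message. Values are printed at full precision so the file
#' round-trips the in-memory scores.
#'
#' @param results region score table from [score_all_regions()] (or the
#'   `regions` element of an [atlas_match()] fit, one stage/query at a time).
#' @param x the [atlas()] the scores were computed against.
#' @param out output CSV path.
#' @return invisibly, the exported data.frame.
#' @export
export_voxel_scores <- function(results, x, out) {
  stopifnot(inherits(x, "atlas"))
  if (!all(c("x", "y", "z") %in% names(x$samples))) {
    abort("no region has coordinates")
  }
  idx <- match(results$region_id, x$samples$region_id)
  coord <- x$samples[idx, c("x", "y", "z")]
  has <- stats::complete.cases(coord) & apply(coord, 1L, function(v) all(is.finite(v)))
  if (!any(has)) abort("no region has coordinates")
  n_skipped <- sum(!has)
  if (n_skipped > 0) {
    message(sprintf("%d region(s) without coordinates", n_skipped))
  }
  df <- data.frame(region_id = results$region_id[has],
                   structure = results$structure[has],
                   x = coord$x[has], y = coord$y[has], z = coord$z[has],
                   neglog10_p = results$neglog10_p[has],
                   stringsAsFactors = FALSE)
  txt <- df
  for (col in c("x", "y", "z", "neglog10_p")) txt[[col]] <- format_full(df[[col]])
  utils::write.table(txt, out, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Export a flattened region-by-stage score heatmap table
#'
#' Wide tab-separated table with one row per region and one column per stage,
#' cells holding -log10 p; pairs not scored are left empty. Rows are ordered
#' by descending maximum score across stages.
#'
#' @param results row-bound region score tables across stages (e.g. the
#'   `regions` element of an [atlas_match()] fit for one query).
#' @param out output TSV path.
#' @return invisibly, the exported wide data.frame.
#' @export
export_heatmap_table <- function(results, out) {
  if (!nrow(results)) abort("empty results")
  stages <- unique(results$stage)
  regions <- unique(results$region_id)
  wide <- matrix(NA_real_, nrow = length(regions), ncol = length(stages),
                 dimnames = list(regions, stages))
  wide[cbind(match(results$region_id, regions),
             match(results$stage, stages))] <- results$neglog10_p
  ord <- order(-apply(wide, 1L, max, na.rm = TRUE))
  wide <- wide[ord, , drop = FALSE]
  txt <- apply(wide, 2L, function(v) ifelse(is.na(v), "", format_full(v)))
  txt <- matrix(txt, nrow = nrow(wide), dimnames = dimnames(wide))
  df <- data.frame(region_id = rownames(wide), txt,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, out, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(as.data.frame(wide))
}

#' Write region and structure score tables with a JSON report
#'
#' Tab-separated `MatchResult` and `StructureScore` tables plus a JSON report
#' echoing the configuration and package version.
#'
#' @param fit an [atlas_match()] object.
#' @param out_dir output directory.
#' @return named vector of written paths.
#' @export
write_match_report <- function(fit, out_dir) {
  stopifnot(inherits(fit, "atlas_match"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(regions = file.path(out_dir, "region_scores.tsv"),
             structures = file.path(out_dir, "structure_scores.tsv"),
             report = file.path(out_dir, "match_report.json"))
  reg <- fit$regions
  for (col in c("median_abs_rank_diff", "w_statistic", "p_value", "neglog10_p")) {
    reg[[col]] <- format_full(reg[[col]])
  }
  utils::write.table(reg, paths["regions"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  st <- fit$structures
  st$neglog10_p <- format_full(st$neglog10_p)
  utils::write.table(st, paths["structures"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(config = unclass(fit$config),
         n_shared_genes = fit$n_shared_genes,
         stages = fit$stages,
         package_version = as.character(utils::packageVersion("atlasmatch"))),
    paths["report"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
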