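#' atlasmatch: rank-difference transcriptome matching against a brain atlas
#'
#' See [atlas_match()] for the main entry point and the package vignette for
#' the statistical model.
#'
#' @keywords internal
#' @importFrom stats rnorm rnbinom rpois setNames median quantile var pt pnorm
#'   p.adjust complete.cases reshape
#' @importFrom utils read.table write.table combn head tail packageVersion
"_PACKAGE"

# Run an expression under a temporary RNG state so library internals that need
# reproducible subsampling do not disturb the caller's random stream.
with_seed <- function(seed, expr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

abort <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Format numeric values at full double precision for text round-trips.
format_full <- function(x) {
  sprintf("%.15g", x)
}

is_count_matrix <- function(x) {
  is.matrix(x) && is.numeric(x) && all(is.finite(x)) &&
    all(x >= 0) && all(abs(x - round(x)) < 1e-8)
}

# Accept either a query_counts object or a bare numeric matrix.
count_matrix <- function(x) {
  if (inherits(x, "query_counts")) return(x$counts)
  if (is.matrix(x) && is.numeric(x)) return(x)
  abort("expected a query_counts object or a numeric matrix")
}
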