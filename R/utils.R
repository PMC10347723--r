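#' @importFrom stats prcomp quantile median rnorm runif rexp sd plogis ecdf
#'   cor p.adjust wilcox.test hclust dist setNames rbinom
#' @importFrom utils head tail write.table read.table combn
#' @import data.table
NULL

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards.  All stochastic stages go through this so
# that a stage is reproducible regardless of what ran before it.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a bounded child seed from a parent seed and a stage label, keeping
# derived seeds inside 32-bit integer range while separating the RNG streams
# of independent stages.
child_seed <- function(seed, label) {
  v <- utf8ToInt(as.character(label))
  h <- sum(v * seq_along(v))
  as.integer((as.numeric(seed) %% 1000003) * 1009 + (h %% 99991))
}

# Gap in bp between two 0-based half-open intervals; 0 if they overlap or
# are adjacent-with-no-gap is FALSE: adjacency ([0,10),[10,20)) has gap 0.
interval_gap <- function(start1, end1, start2, end2) {
  pmax(0L, pmax(start2 - end1, start1 - end2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
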