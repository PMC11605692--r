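# Internal helpers shared across modules.

#' @import data.table
#' @importFrom stats pnorm rbeta rbinom rpois runif rnorm setNames var sd dbinom pbinom
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(ok, ...) {
  if (!isTRUE(ok)) stop(sprintf(...), call. = FALSE)
}

# Convert an interval table (chrom, start, end; 0-based half-open) to GRanges.
# GRanges is 1-based closed, so start+1.
.as_granges <- function(dt) {
  .assert(all(c("chrom", "start", "end") %in% names(dt)),
          "interval table needs columns chrom, start, end")
  .assert(all(dt$end > dt$start), "zero- or negative-length interval rejected")
  GenomicRanges::GRanges(
    seqnames = dt$chrom,
    ranges = IRanges::IRanges(start = dt$start + 1L, end = dt$end)
  )
}

# findOverlaps / distanceToNearest with harmonized seqlevels, so disjoint
# chromosome sets do not warn.
.harmonized <- function(ga, gb) {
  lv <- union(GenomeInfoDb::seqlevels(ga), GenomeInfoDb::seqlevels(gb))
  GenomeInfoDb::seqlevels(ga) <- lv
  GenomeInfoDb::seqlevels(gb) <- lv
  list(ga, gb)
}

.find_overlaps <- function(ga, gb, ...) {
  h <- .harmonized(ga, gb)
  GenomicRanges::findOverlaps(h[[1]], h[[2]], ...)
}

.distance_to_nearest <- function(ga, gb) {
  h <- .harmonized(ga, gb)
  GenomicRanges::distanceToNearest(h[[1]], h[[2]])
}

# Local RNG scope: evaluate expr with a temporary seed, restore global state.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Derive a bounded child seed from a parent seed and a stream label.
.child_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 1103L + h * 12347) %% 2147483587)
}
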