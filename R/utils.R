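#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor cutree dist dnorm dt ecdf fisher.test hclust mad
#'   median optim p.adjust plogis pnorm pt qnorm quantile rbinom rlnorm rnorm
#'   rpois runif sd setNames t.test var wilcox.test complete.cases
#' @importFrom utils head
#' @importFrom data.table fread fwrite data.table as.data.table :=
#' @importFrom methods is
NULL

# Run `expr` with the RNG seeded at `seed`, restoring any pre-existing RNG
# state afterwards.  All generators funnel their randomness through this so
# that a single integer seed fixes every output bit-for-bit without touching
# global state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single finite integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream-specific child seed from a master seed.  Keeps results of
# one generator independent of whether another generator ran first.
child_seed <- function(seed, stream) {
  offsets <- c(gene_effect = 11L, regulatory_locus = 23L,
               reference_expression = 37L, puncta_field = 53L,
               generic = 71L)
  off <- offsets[[match.arg(stream, names(offsets))]]
  (as.integer(seed) * 1103L + off) %% 2147483562L + 1L
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop(sprintf("`%s` must be a positive scalar", name), call. = FALSE)
  invisible(x)
}

# 0-based half-open intervals -> IRanges (1-based closed)
as_granges0 <- function(chrom, start, end) {
  if (any(end <= start)) stop("invalid interval: end must exceed start",
                              call. = FALSE)
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
}

granges_to_bed0 <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}
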