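# Superenhancer landscape: spike-in scaling, the merged/median-normalized
# SE score matrix, recurrence, subtype differentials, dependency
# correlation, and sample clustering.

#' Spike-in (exogenous chromatin) normalization
#'
#' Scales each sample's signal by the ratio of a reference tag count to the
#' sample's exogenous spike-in tag count, so that genome-wide occupancy
#' changes remain quantitative: after scaling, ratios between samples depend
#' only on true occupancy ratios as long as spike-in recovery is
#' proportional to input.
#'
#' @param signal numeric vector or matrix of per-sample signal (samples as
#'   vector elements or matrix columns).
#' @param spike_tags positive spike-in tag count per sample.
#' @param reference_tags positive scalar reference tag count.
#' @return scaled signal with the shape of `signal`.
#' @export
spikein_normalize <- function(signal, spike_tags, reference_tags) {
  if (any(!is.finite(spike_tags)) || any(spike_tags <= 0))
    stop("spike-in tag counts must be positive")
  stopifnot_scalar_pos(reference_tags, "reference_tags")
  scale <- reference_tags / spike_tags
  if (is.matrix(signal)) {
    if (length(spike_tags) != ncol(signal))
      stop("one spike-in count per sample (matrix column) required")
    sweep(signal, 2, scale, `*`)
  } else {
    if (length(spike_tags) != length(signal) && length(spike_tags) != 1L)
      stop("spike_tags must match signal length")
    signal * scale
  }
}

#' Build a superenhancer score matrix from per-sample calls
#'
#' Union-merges overlapping SE calls across samples into a common region
#' set, quantifies every sample on every merged region (sum of the sample's
#' overlapping call scores), and records which samples called each region.
#' Scores are left on the raw scale; apply [median_normalize()] and
#' [collapse_replicates()] to reproduce the standard normalize-then-average
#' workflow (see [se_matrix_pipeline()]).
#'
#' @param per_sample_calls named list of data.frames with columns `chrom`,
#'   `start`, `end` (0-based half-open) and `score`.
#' @return object of class `se_matrix`: `regions` (data.frame chrom, start,
#'   end), `scores` (regions x samples), `called` (logical matrix),
#'   `recurrence` (integer per region).
#' @export
build_se_matrix <- function(per_sample_calls) {
  if (length(per_sample_calls) < 1) stop("need at least one sample")
  if (is.null(names(per_sample_calls)) || anyNA(names(per_sample_calls)))
    stop("per_sample_calls must be a named list")
  grs <- lapply(per_sample_calls, function(df)
    as_granges0(df$chrom, df$start, df$end))
  merged <- GenomicRanges::reduce(unlist(methods::as(grs, "GRangesList")))
  merged <- GenomicRanges::sort(merged)
  n_reg <- length(merged)
  samples <- names(per_sample_calls)
  scores <- matrix(0, n_reg, length(samples),
                   dimnames = list(NULL, samples))
  called <- matrix(FALSE, n_reg, length(samples),
                   dimnames = list(NULL, samples))
  for (s in samples) {
    hit <- GenomicRanges::findOverlaps(merged, grs[[s]])
    if (length(hit)) {
      sc <- tapply(per_sample_calls[[s]]$score[S4Vectors::subjectHits(hit)],
                   S4Vectors::queryHits(hit), sum)
      idx <- as.integer(names(sc))
      scores[idx, s] <- as.numeric(sc)
      called[idx, s] <- TRUE
    }
  }
  new_se_matrix(granges_to_bed0(merged), scores, called)
}

new_se_matrix <- function(regions, scores, called) {
  structure(list(regions = regions, scores = scores, called = called,
                 recurrence = as.integer(rowSums(called))),
            class = "se_matrix")
}

#' @export
print.se_matrix <- function(x, ...) {
  cat(sprintf("se_matrix: %d regions x %d samples\n",
              nrow(x$scores), ncol(x$scores)))
  invisible(x)
}

#' Median-normalize an SE score matrix
#'
#' Divides each sample column by the median of its positive scores, so the
#' per-sample median score over scored regions equals 1.  Idempotent.
#'
#' @param m an `se_matrix`.
#' @return the matrix with normalized scores.
#' @export
median_normalize <- function(m) {
  med <- apply(m$scores, 2, function(x) median(x[x > 0]))
  if (any(!is.finite(med)))
    stop("a sample has no positive scores; cannot median-normalize")
  m$scores <- sweep(m$scores, 2, med, `/`)
  m
}

#' Average replicate columns of an SE matrix
#'
#' Collapses replicate groups to single columns: scores are averaged and a
#' region counts as called in the group when any replicate called it.
#'
#' @param m an `se_matrix`.
#' @param replicate_groups named character vector mapping sample -> group
#'   label; every sample of `m` must appear.
#' @return an `se_matrix` with one column per group; recurrence recomputed.
#' @export
collapse_replicates <- function(m, replicate_groups) {
  samples <- colnames(m$scores)
  unknown <- setdiff(names(replicate_groups), samples)
  if (length(unknown))
    stop("replicate group references unknown sample(s): ",
         paste(unknown, collapse = ", "))
  if (!all(samples %in% names(replicate_groups)))
    stop("every sample needs a replicate group")
  groups <- unique(replicate_groups[samples])
  scores <- sapply(groups, function(g)
    rowMeans(m$scores[, samples[replicate_groups[samples] == g],
                      drop = FALSE]))
  called <- sapply(groups, function(g)
    rowSums(m$called[, samples[replicate_groups[samples] == g],
                     drop = FALSE]) > 0)
  if (nrow(m$regions) == 1) {        # sapply drops to vector
    scores <- matrix(scores, 1, dimnames = list(NULL, groups))
    called <- matrix(called, 1, dimnames = list(NULL, groups))
  }
  new_se_matrix(m$regions, scores, called)
}

#' Standard SE-matrix workflow
#'
#' Merge calls, median-normalize per sample, then average replicates.
#'
#' @inheritParams build_se_matrix
#' @inheritParams collapse_replicates
#' @return an `se_matrix` keyed by replicate group.
#' @export
se_matrix_pipeline <- function(per_sample_calls, replicate_groups = NULL) {
  m <- median_normalize(build_se_matrix(per_sample_calls))
  if (!is.null(replicate_groups)) m <- collapse_replicates(m, replicate_groups)
  m
}

#' Filter SE regions by recurrence
#'
#' Keeps regions called in at least `min_samples` samples.
#'
#' @param m an `se_matrix`.
#' @param min_samples minimum number of calling samples (>= 1).
#' @return the filtered `se_matrix`.
#' @export
recurrence_filter <- function(m, min_samples = 2L) {
  if (min_samples < 1) stop("min_samples must be >= 1")
  keep <- m$recurrence >= min_samples
  new_se_matrix(m$regions[keep, , drop = FALSE],
                m$scores[keep, , drop = FALSE],
                m$called[keep, , drop = FALSE])
}

#' Rank TF genes by SE-score / dependency correlation
#'
#' Pearson correlation between each gene's SE score (the region mapped to
#' it) and its dependency effect score across the cell lines shared by the
#' two matrices, ranked descending.
#'
#' @param m an `se_matrix` whose columns are cell lines.
#' @param dep a `gene_effect_matrix`.
#' @param gene_to_region named integer vector: gene ID -> row index of
#'   `m$regions`.
#' @return data.frame `gene`, `r`, `p` sorted by `r` descending; genes with
#'   constant SE score are skipped with a warning.
#' @export
rank_by_dependency_correlation <- function(m, dep, gene_to_region) {
  shared <- intersect(colnames(m$scores), colnames(dep$effect))
  if (length(shared) < 3) stop("need >= 3 shared samples")
  rows <- lapply(names(gene_to_region), function(g) {
    if (!g %in% rownames(dep$effect)) return(NULL)
    se <- m$scores[gene_to_region[[g]], shared]
    de <- dep$effect[g, shared]
    if (sd(se) == 0 || sd(de) == 0) {
      warning("constant vector for gene ", g, "; skipped")
      return(NULL)
    }
    r <- cor(se, de)
    n <- length(shared)
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    data.frame(gene = g, r = r, p = 2 * pt(-abs(tstat), n - 2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$r, decreasing = TRUE), , drop = FALSE]
}

#' Subtype-differential superenhancers
#'
#' Per-region difference of mean (normalized) SE score between subtype
#' groups, plus a per-sample SE-count comparison between the groups.
#'
#' @param m an `se_matrix`.
#' @param split logical vector over samples (TRUE = in-subtype) or character
#'   IDs.
#' @param count_test `"wilcox"` (default) or `"welch"` for the per-sample
#'   SE-count group comparison.
#' @return list: `regions` (data.frame `delta` = in - out mean, `rank` by
#'   |delta| descending, region coordinates), `counts` (per-sample SE
#'   counts with group), `count_p` (NA when a group has < 2 samples).
#' @export
differential_se <- function(m, split, count_test = c("wilcox", "welch")) {
  count_test <- match.arg(count_test)
  samples <- colnames(m$scores)
  grp <- if (is.logical(split)) split else samples %in% split
  if (!any(grp) || all(grp)) stop("both groups must be non-empty")
  delta <- rowMeans(m$scores[, grp, drop = FALSE]) -
    rowMeans(m$scores[, !grp, drop = FALSE])
  regions <- cbind(m$regions,
                   data.frame(delta = delta,
                              rank = rank(-abs(delta), ties.method = "first")))
  counts <- colSums(m$called)
  count_p <- if (sum(grp) < 2 || sum(!grp) < 2) NA_real_
  else if (count_test == "wilcox")
    suppressWarnings(wilcox.test(counts[grp], counts[!grp])$p.value)
  else t.test(counts[grp], counts[!grp])$p.value
  list(regions = regions,
       counts = data.frame(sample = samples, n_se = as.integer(counts),
                           in_group = grp, stringsAsFactors = FALSE),
       count_p = count_p)
}

#' Cluster samples by SE-score correlation
#'
#' Hierarchical clustering with distance 1 - Pearson correlation between
#' sample score vectors and complete linkage, cut to `k` clusters.
#'
#' @param m an `se_matrix` (or any object with a `scores` matrix) with at
#'   least `k` samples.
#' @param k number of clusters.
#' @return named integer vector of cluster labels with the `hclust` tree in
#'   attribute `tree`.
#' @export
cluster_samples <- function(m, k) {
  scores <- if (is.matrix(m)) m else m$scores
  if (ncol(scores) < k) stop("need at least k samples")
  sds <- apply(scores, 2, sd)
  if (any(sds == 0))
    stop("constant score vector for sample(s): ",
         paste(colnames(scores)[sds == 0], collapse = ", "))
  d <- stats::as.dist(1 - cor(scores))
  tree <- hclust(d, method = "complete")
  cl <- cutree(tree, k = k)
  attr(cl, "tree") <- tree
  cl
}
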