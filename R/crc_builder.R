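# Core regulatory circuitry: intersect selective TF dependencies with
# SE-associated TF genes, and classify samples into subtype-like clusters
# by core-TF expression.

#' TF genes associated with recurrent superenhancers
#'
#' Returns the transcription-factor genes linked (through the supplied
#' associations) to at least one region of a recurrence-filtered SE matrix.
#' Association regions are matched to SE regions by >= 1 bp overlap.
#'
#' @param assocs association data.frame with `gene` and either region
#'   coordinates (`chrom`, `start`, `end`) or a `region_id` matching
#'   `regions$region_id`.
#' @param recurrent_se an `se_matrix` already filtered to recurrent regions
#'   (see [recurrence_filter()]).
#' @param tf_catalog character vector of TF gene IDs (required; supply a
#'   human TF catalog of your choice).
#' @param regions optional data.frame mapping `region_id` to `chrom`,
#'   `start`, `end` when `assocs` carries only IDs.
#' @return character vector of SE-associated TF genes.
#' @export
se_associated_tf_genes <- function(assocs, recurrent_se, tf_catalog,
                                   regions = NULL) {
  if (length(tf_catalog) == 0) stop("TF catalog must be non-empty")
  if (!all(c("chrom", "start", "end") %in% names(assocs))) {
    if (is.null(regions))
      stop("assocs lack coordinates; supply `regions`")
    idx <- match(assocs$region_id, regions$region_id)
    assocs$chrom <- regions$chrom[idx]
    assocs$start <- regions$start[idx]
    assocs$end <- regions$end[idx]
  }
  se_gr <- as_granges0(recurrent_se$regions$chrom,
                       recurrent_se$regions$start,
                       recurrent_se$regions$end)
  as_gr <- as_granges0(assocs$chrom, assocs$start, assocs$end)
  hit <- GenomicRanges::countOverlaps(as_gr, se_gr) > 0
  intersect(unique(assocs$gene[hit]), tf_catalog)
}

#' Intersect selective TF dependencies with SE-associated TFs
#'
#' @param selective_tfs character vector of selectively essential TF genes.
#' @param se_tfs character vector of SE-associated TF genes.
#' @return data.frame of class `core_tf_set`: `tf`, `selective_dependency`,
#'   `se_associated` (all TRUE by construction).  Empty intersection warns.
#' @export
intersect_core <- function(selective_tfs, se_tfs) {
  core <- sort(intersect(unique(selective_tfs), unique(se_tfs)))
  if (length(core) == 0)
    warning("selective and SE-associated TF sets are disjoint")
  structure(data.frame(tf = core,
                       selective_dependency = rep(TRUE, length(core)),
                       se_associated = rep(TRUE, length(core)),
                       stringsAsFactors = FALSE),
            class = c("core_tf_set", "data.frame"))
}

#' Classify samples into subtype-like clusters by core-TF expression
#'
#' Z-scores core-TF expression per gene, hierarchically clusters samples
#' (1 - Pearson distance, complete linkage), cuts at `k`, finds the cluster
#' holding the majority of subtype-positive samples (ties broken by larger
#' subtype count, then by cluster size), and flags its subtype-negative
#' members as subtype-like.
#'
#' @param expr genes x samples expression matrix (log2(TPM+1)).
#' @param core_tfs `core_tf_set` or character vector of core TF genes; all
#'   must be rows of `expr`.
#' @param subtype_labels named logical vector (sample -> carries the
#'   subtype lesion); must cover the expression samples and contain at
#'   least one TRUE.
#' @param k number of clusters.
#' @return data.frame: `sample`, `cluster`, `subtype`, `subtype_like`, with
#'   the focal cluster id in attribute `subtype_cluster`.
#' @export
classify_subtype_like <- function(expr, core_tfs, subtype_labels, k) {
  tfs <- if (inherits(core_tfs, "core_tf_set")) core_tfs$tf else core_tfs
  missing <- setdiff(tfs, rownames(expr))
  if (length(missing))
    stop("core TFs missing from expression matrix: ",
         paste(missing, collapse = ", "))
  samples <- colnames(expr)
  subtype <- subtype_labels[samples]
  if (anyNA(subtype)) stop("subtype labels must cover all samples")
  if (!any(subtype)) stop("no subtype-positive samples")
  z <- t(scale(t(expr[tfs, , drop = FALSE])))
  z <- z[apply(z, 1, function(x) all(is.finite(x))), , drop = FALSE]
  if (k == 1) {
    warning("k = 1: all subtype-negative samples flagged subtype-like")
    cl <- setNames(rep(1L, length(samples)), samples)
  } else {
    cl <- cluster_samples(z, k)
  }
  tab <- table(cluster = cl, subtype = factor(subtype, c(FALSE, TRUE)))
  pos <- tab[, "TRUE"]
  best <- which(pos == max(pos))
  if (length(best) > 1) {                      # tie: larger cluster wins
    size <- rowSums(tab)[best]
    best <- best[order(size, decreasing = TRUE)]
    message("subtype majority tie broken by cluster size")
  }
  focal <- as.integer(rownames(tab)[best[1]])
  out <- data.frame(sample = samples, cluster = as.integer(cl[samples]),
                    subtype = unname(subtype),
                    subtype_like = unname(cl[samples] == focal & !subtype),
                    stringsAsFactors = FALSE)
  attr(out, "subtype_cluster") <- focal
  out
}
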