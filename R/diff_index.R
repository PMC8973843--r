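# Myeloid/lymphoid differentiation index: rank lineage marker genes by a
# pooled-variance separation index between two reference cell types, then
# score samples by summed, sign-adjusted, max-|z|-scaled z-scores over the
# markers.

#' Per-gene separation index between two reference groups
#'
#' For each gene: pooled variance = mean of the two group variances;
#' separation index = (mean_a - mean_b) / sqrt(pooled variance).  Genes
#' with zero pooled variance are skipped with a warning.
#'
#' @param expr genes x samples expression matrix (log2(TPM+1)).
#' @param group_a,group_b character vectors of sample IDs (>= 2 each), e.g.
#'   HSC and monocyte reference samples.
#' @return data.frame: `gene`, `mean_a`, `mean_b`, `var_a`, `var_b`,
#'   `pooled_var`, `sep_index`.
#' @export
separation_index <- function(expr, group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs >= 2 samples")
  a <- expr[, group_a, drop = FALSE]
  b <- expr[, group_b, drop = FALSE]
  out <- data.frame(gene = rownames(expr),
                    mean_a = rowMeans(a), mean_b = rowMeans(b),
                    var_a = apply(a, 1, var), var_b = apply(b, 1, var),
                    row.names = NULL, stringsAsFactors = FALSE)
  out$pooled_var <- (out$var_a + out$var_b) / 2
  zero <- out$pooled_var == 0
  if (any(zero)) {
    warning(sum(zero), " gene(s) with zero pooled variance skipped")
    out <- out[!zero, , drop = FALSE]
  }
  out$sep_index <- (out$mean_a - out$mean_b) / sqrt(out$pooled_var)
  out
}

#' Select lineage marker genes
#'
#' Top `k` genes by signed separation index, descending.  Ties at rank `k`
#' are broken deterministically by gene ID.
#'
#' @param records output of [separation_index()].
#' @param k number of markers.
#' @return character vector of marker gene IDs.
#' @export
select_markers <- function(records, k = 19) {
  if (k > nrow(records)) stop("k exceeds the number of records")
  ord <- order(-records$sep_index, records$gene)
  records$gene[ord][seq_len(k)]
}

#' Reference statistics for lineage-index scoring
#'
#' Per-marker reference mean (over the pooled reference samples of both
#' groups), pooled variance, and direction (-1 when group b has the higher
#' mean, so that group-b-high markers contribute negatively).
#'
#' @inheritParams separation_index
#' @param markers marker gene IDs.
#' @return data.frame: `gene`, `ref_mean`, `pooled_var`, `direction`.
#' @export
reference_stats <- function(expr, group_a, group_b, markers) {
  rec <- separation_index(expr[markers, , drop = FALSE], group_a, group_b)
  data.frame(gene = rec$gene,
             ref_mean = rowMeans(expr[rec$gene, c(group_a, group_b),
                                      drop = FALSE]),
             pooled_var = rec$pooled_var,
             direction = ifelse(rec$mean_b > rec$mean_a, -1, 1),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compute the lineage (myeloid/lymphoid) index per sample
#'
#' Each sample's marker expression is z-scored against the reference mean
#' and pooled variance, scaled to +/-1 by the per-gene maximum |z| over the
#' scored samples, sign-flipped for markers higher in group b (e.g.
#' monocyte-high), and summed across markers.
#'
#' @param expr genes x samples matrix of samples to score.
#' @param ref output of [reference_stats()] (fields `gene`, `ref_mean`,
#'   `pooled_var`, `direction`).
#' @param scale_scope `"per_gene"` (default): each marker scaled by its own
#'   max |z| over the scored samples; `"global"`: one max |z| over all
#'   markers and samples.
#' @return data.frame: `sample`, `index`, with per-sample scaled z-scores in
#'   attribute `scaled_z` (markers x samples).  Scoring a single sample
#'   degenerates (every scaled |z| is 1 or 0) and warns.
#' @export
compute_lineage_index <- function(expr, ref,
                                  scale_scope = c("per_gene", "global")) {
  scale_scope <- match.arg(scale_scope)
  missing <- setdiff(ref$gene, rownames(expr))
  if (length(missing))
    stop("marker gene(s) missing from expression matrix: ",
         paste(missing, collapse = ", "))
  if (ncol(expr) == 1)
    warning("single sample scored: max-|z| scaling is degenerate")
  x <- expr[ref$gene, , drop = FALSE]
  z <- (x - ref$ref_mean) / sqrt(ref$pooled_var)
  zmax <- if (scale_scope == "per_gene")
    apply(abs(z), 1, max) else rep(max(abs(z)), nrow(z))
  zmax[zmax == 0] <- 1                     # all-zero marker contributes 0
  zs <- ref$direction * z / zmax
  data.frame(sample = colnames(expr), index = colSums(zs),
             row.names = NULL, stringsAsFactors = FALSE) |>
    structure(scaled_z = zs)
}
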