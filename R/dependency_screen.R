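# Selective-dependency calling from a gene-effect screen.
#
# A gene is called a selective dependency when it (1) has dependency
# probability > 0.5 in at least three in-group lines, (2) is not a common
# essential gene, and (3) is either an enriched dependency (moderated
# in-group test, q < 0.05 with negative effect size) or a skewed dependency
# (normLRT >= 100 with left-sided skew).

#' Construct a gene-effect matrix container
#'
#' Bundles effect scores, dependency probabilities and sample annotations
#' after validating shapes and ranges.
#'
#' @param effect genes x lines numeric matrix of gene-effect scores
#'   (0 anchors nonessential controls, -1 the common-essential median).
#' @param probability matching matrix of dependency probabilities in [0, 1].
#' @param annotations data.frame with columns `sample`, `lineage` and
#'   logical `subtype`, one row per column of `effect`.
#' @return object of class `gene_effect_matrix`.
#' @export
gene_effect_matrix <- function(effect, probability, annotations) {
  if (!is.matrix(effect) || !is.matrix(probability))
    stop("effect and probability must be matrices")
  if (!identical(dim(effect), dim(probability)))
    stop("effect and probability must share dimensions")
  if (any(probability < 0 | probability > 1, na.rm = TRUE))
    stop("probabilities must lie in [0, 1]")
  if (!all(c("sample", "lineage") %in% names(annotations)))
    stop("annotations need `sample` and `lineage` columns")
  if (nrow(annotations) != ncol(effect))
    stop("one annotation row per sample required")
  if (anyNA(annotations$lineage))
    stop("every sample needs a lineage label")
  structure(list(effect = effect, probability = probability,
                 annotations = annotations, truth = NULL),
            class = "gene_effect_matrix")
}

#' Skew-t likelihood-ratio (normLRT) score for one gene
#'
#' Fits the gene's effect scores across lines with both the skew-t family
#' and a normal distribution, and returns twice the log-likelihood gap.
#' Large scores with mean < median flag left-skewed dependency profiles:
#' a gene that is strongly depleted in a minority of lines against a
#' near-normal background.
#'
#' @param effects numeric vector of effect scores across lines (>= 20 finite
#'   values, non-degenerate variance).
#' @param nu_bounds degrees-of-freedom bounds passed to [fit_skewt()].
#' @return one-row data.frame: `normlrt`, `mean_effect`, `median_effect`,
#'   `left_skewed`, `converged`.
#' @export
fit_normlrt <- function(effects, nu_bounds = c(2.5, 100)) {
  x <- effects[is.finite(effects)]
  if (length(x) < 20L)
    stop("degenerate input: need >= 20 finite effect values")
  if (length(unique(x)) == 1L || sd(x) == 0)
    stop("degenerate input: constant effect vector")
  st <- fit_skewt(x, nu_bounds = nu_bounds)
  nm <- fit_normal_ml(x)
  data.frame(normlrt = 2 * (st$loglik - nm$loglik),
             mean_effect = mean(x), median_effect = median(x),
             left_skewed = mean(x) < median(x),
             converged = st$converged)
}

#' normLRT scores for every gene in a matrix
#'
#' @param m a `gene_effect_matrix`.
#' @param min_finite genes with fewer finite values are skipped (returned
#'   with NA score).
#' @inheritParams fit_normlrt
#' @return data.frame with one row per gene (`gene` column plus the
#'   [fit_normlrt()] fields).
#' @export
normlrt_scores <- function(m, min_finite = 20L, nu_bounds = c(2.5, 100)) {
  res <- lapply(rownames(m$effect), function(g) {
    x <- m$effect[g, ]
    if (sum(is.finite(x)) < min_finite || sd(x, na.rm = TRUE) == 0)
      return(data.frame(normlrt = NA_real_, mean_effect = mean(x, na.rm = TRUE),
                        median_effect = median(x, na.rm = TRUE),
                        left_skewed = NA, converged = FALSE))
    fit_normlrt(x, nu_bounds = nu_bounds)
  })
  out <- do.call(rbind, res)
  cbind(data.frame(gene = rownames(m$effect), stringsAsFactors = FALSE), out)
}

#' Identify common-essential genes by the 90th-percentile rank rule
#'
#' Within each line, genes are ranked by effect score (most negative = rank
#' 1).  Each gene is then summarized by its rank in its 90th-percentile
#' least-dependent line, i.e. the rank it achieves in 90% of lines or
#' better.  The histogram of these summary ranks over genes is bimodal --
#' an essential cluster at low ranks and the bulk at high ranks -- and the
#' cutoff is placed at the central minimum between the two largest modes.
#' Genes at or below the cutoff are common essential.
#'
#' @param m a `gene_effect_matrix` (>= 50 genes, >= 10 lines).
#' @param cutoff optional explicit rank cutoff overriding the histogram rule.
#' @return character vector of common-essential gene IDs, with the chosen
#'   cutoff in attribute `cutoff`.
#' @export
call_common_essential <- function(m, cutoff = NULL) {
  eff <- m$effect
  if (nrow(eff) < 50 || ncol(eff) < 10)
    stop("need >= 50 genes and >= 10 lines")
  if (all(apply(eff, 2, function(col) length(unique(col)) == 1L)))
    stop("degenerate matrix: genes indistinguishable by rank")
  ranks <- apply(eff, 2, rank, ties.method = "average")
  # per gene: rank in its 90th-percentile least-dependent (= highest-rank) line
  r90 <- apply(ranks, 1, quantile, probs = 0.9, type = 1)
  if (is.null(cutoff)) {
    cutoff <- rank_histogram_cutoff(r90)
    if (is.na(cutoff))
      stop(paste("no central minimum found in the rank histogram;",
                 "supply an explicit `cutoff`"))
  }
  out <- rownames(eff)[r90 <= cutoff]
  attr(out, "cutoff") <- cutoff
  out
}

# Central minimum of the (smoothed) histogram of 90th-percentile ranks.
# The distribution is bimodal: an essential mode at low ranks and the
# nonessential bulk at high ranks.  The cutoff is the location of the
# density minimum between the largest mode left of the bulk mode and the
# bulk (global) mode; NA when the density is effectively unimodal.
rank_histogram_cutoff <- function(r90) {
  if (length(unique(r90)) < 3) return(NA_real_)
  d <- stats::density(r90, n = 512)
  y <- d$y
  is_max <- y > c(-Inf, y[-length(y)]) & y >= c(y[-1], -Inf)
  peaks <- which(is_max)
  main <- peaks[which.max(y[peaks])]
  left <- peaks[peaks < main]
  left <- left[y[left] > 1e-3 * y[main]]      # ignore numerical ripples
  if (!length(left)) return(NA_real_)
  second <- left[which.max(y[left])]
  valley <- second + which.min(y[second:main]) - 1L
  d$x[valley]
}

#' @importFrom stats density
NULL

#' Test in-group enrichment of dependency
#'
#' Fits a per-gene linear model with an in-group indicator to the effect
#' scores and moderates the variances with empirical Bayes (limma), yielding
#' moderated t-statistics, log-odds (B) statistics, two-sided and one-sided
#' p-values and Benjamini-Hochberg q-values.  A gene is an enriched
#' dependency when q < 0.05 with a negative effect size (more dependent in
#' the in-group).
#'
#' @param m a `gene_effect_matrix`.
#' @param in_group character vector of in-group sample IDs, or a logical
#'   vector over columns; both groups need >= 2 samples.
#' @param moderated use empirical-Bayes moderation (default); `FALSE` falls
#'   back to per-gene OLS t-tests.
#' @param alpha q-value threshold for the `enriched` call.
#' @return data.frame with one row per gene: `gene`, `effect_size`,
#'   `t_stat`, `log_odds`, `p_two`, `p_left`, `p_right`, `q`, `enriched`.
#' @export
test_group_enrichment <- function(m, in_group, moderated = TRUE,
                                  alpha = 0.05) {
  samples <- colnames(m$effect)
  grp <- if (is.logical(in_group)) in_group else samples %in% in_group
  if (sum(grp) < 2 || sum(!grp) < 2)
    stop("in-group and out-group each need >= 2 samples")
  design <- cbind(Intercept = 1, ingroup = as.numeric(grp))
  fit <- limma::lmFit(m$effect, design)
  if (moderated) {
    fit <- limma::eBayes(fit)
    t_stat <- fit$t[, "ingroup"]
    df <- fit$df.total
    p_two <- fit$p.value[, "ingroup"]
    log_odds <- fit$lods[, "ingroup"]
  } else {
    se <- fit$stdev.unscaled[, "ingroup"] * fit$sigma
    t_stat <- fit$coefficients[, "ingroup"] / se
    df <- fit$df.residual
    p_two <- 2 * pt(-abs(t_stat), df)
    log_odds <- rep(NA_real_, length(t_stat))
  }
  p_left <- pt(t_stat, df)          # more negative in in-group
  p_right <- pt(t_stat, df, lower.tail = FALSE)
  q <- p.adjust(p_two, method = "BH")
  effect_size <- fit$coefficients[, "ingroup"]
  data.frame(gene = rownames(m$effect), effect_size = effect_size,
             t_stat = t_stat, log_odds = log_odds, p_two = p_two,
             p_left = p_left, p_right = p_right, q = q,
             enriched = q < alpha & effect_size < 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Call selective dependencies
#'
#' Applies the three-way selectivity rule: dependency probability > 0.5 in
#' at least `min_dependent` in-group lines, not common essential, and either
#' enriched (q < 0.05, negative effect size) or skewed (normLRT >=
#' `normlrt_threshold` with left-sided skew).
#'
#' @param m a `gene_effect_matrix`.
#' @param in_group in-group sample IDs (or logical over columns).
#' @param enrichment output of [test_group_enrichment()].
#' @param normlrt output of [normlrt_scores()].
#' @param common_essential character vector from [call_common_essential()].
#' @param min_dependent minimum number of dependent in-group lines.
#' @param normlrt_threshold skewed-dependency score threshold.
#' @return data.frame with one row per gene: `gene`,
#'   `n_dependent_ingroup`, `is_common_essential`, `is_enriched`,
#'   `is_skewed`, `selected`.
#' @export
call_selective <- function(m, in_group, enrichment, normlrt,
                           common_essential, min_dependent = 3L,
                           normlrt_threshold = 100) {
  genes <- rownames(m$effect)
  for (nm in list(enrichment = enrichment$gene, normlrt = normlrt$gene)) {
    missing <- setdiff(genes, nm)
    if (length(missing))
      stop("genes missing from an input: ",
           paste(head(missing, 5), collapse = ", "))
  }
  samples <- colnames(m$effect)
  grp <- if (is.logical(in_group)) in_group else samples %in% in_group
  n_dep <- rowSums(m$probability[, grp, drop = FALSE] > 0.5, na.rm = TRUE)
  enr <- enrichment[match(genes, enrichment$gene), ]
  nlr <- normlrt[match(genes, normlrt$gene), ]
  is_skewed <- !is.na(nlr$normlrt) & nlr$normlrt >= normlrt_threshold &
    nlr$left_skewed
  is_ce <- genes %in% common_essential
  sel <- n_dep >= min_dependent & !is_ce & (enr$enriched | is_skewed)
  data.frame(gene = genes, n_dependent_ingroup = as.integer(n_dep),
             is_common_essential = is_ce, is_enriched = enr$enriched,
             is_skewed = is_skewed, selected = sel,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Subtype-differential dependency
#'
#' Per-gene difference of mean effect between two subtype groups with a
#' two-sided Welch t-test, computed on available (finite) values.
#'
#' @param m a `gene_effect_matrix`.
#' @param split logical vector over columns (TRUE = in-subtype) or character
#'   vector of in-subtype sample IDs; defaults to the `subtype` annotation.
#' @return data.frame: `gene`, `delta` (in-subtype mean - out-subtype mean),
#'   `p` (NA with a warning filed in `flag` when a group has < 2 usable
#'   values).
#' @export
differential_dependency <- function(m, split = NULL) {
  samples <- colnames(m$effect)
  if (is.null(split)) split <- m$annotations$subtype
  grp <- if (is.logical(split)) split else samples %in% split
  if (!any(grp) || all(grp)) stop("both subtype groups must be non-empty")
  res <- apply(m$effect, 1, function(x) {
    a <- x[grp]; b <- x[!grp]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    delta <- mean(a) - mean(b)
    if (length(a) < 2 || length(b) < 2)
      return(c(delta = delta, p = NA_real_))
    c(delta = delta, p = t.test(a, b)$p.value)
  })
  data.frame(gene = rownames(m$effect), delta = res["delta", ],
             p = res["p", ], flag = ifelse(is.na(res["p", ]),
                                           "group_too_small", ""),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Run the full selective-dependency screen
#'
#' Convenience wrapper: normLRT scores, common-essential call, in-group
#' enrichment, and the three-criteria selectivity call.
#'
#' @inheritParams call_selective
#' @param ce_cutoff optional explicit common-essential rank cutoff.
#' @return list with `normlrt`, `common_essential`, `enrichment`, `calls`.
#' @export
run_dependency_screen <- function(m, in_group, min_dependent = 3L,
                                  normlrt_threshold = 100, ce_cutoff = NULL) {
  nlr <- normlrt_scores(m)
  ce <- call_common_essential(m, cutoff = ce_cutoff)
  enr <- test_group_enrichment(m, in_group)
  calls <- call_selective(m, in_group, enr, nlr, ce,
                          min_dependent = min_dependent,
                          normlrt_threshold = normlrt_threshold)
  list(normlrt = nlr, common_essential = ce, enrichment = enr, calls = calls)
}
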