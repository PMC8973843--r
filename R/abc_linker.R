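# Modified activity-by-contact (ABC) assignment of enhancer regions to
# genes.  Loops with one anchor near a TSS are scored as
# frequency * sqrt(H3K27ac * ATAC) over the distal anchor, trimmed
# (TSS-TSS loops, blacklist overlap, bottom of the genome-wide score
# distribution), stitched into regions, and retained as gene associations
# when the region's normalized enhancer signal correlates with the gene's
# expression in either of two sample cohorts.

#' Select TSS-anchored loops
#'
#' Keeps loops with at least one anchor midpoint within `window` bp of a
#' gene TSS, assigning that gene; the other anchor becomes the distal
#' candidate enhancer.  A loop near several TSSs yields one candidate per
#' gene.
#'
#' @param loops data.frame with columns `chrom_a`, `start_a`, `end_a`,
#'   `chrom_b`, `start_b`, `end_b`, `frequency` (and optionally `loop_id`);
#'   coordinates 0-based half-open.
#' @param tss data.frame with columns `gene`, `chrom`, `pos`.
#' @param window maximum anchor-midpoint-to-TSS distance, bp.
#' @return data.frame of candidates: `loop_id`, `gene`, `tss`, `chrom`,
#'   `distal_start`, `distal_end`, `frequency`, plus the TSS-side anchor
#'   midpoint (`tss_anchor_mid`) and distal midpoint (`distal_mid`).  The
#'   number of loops matching no TSS is in attribute `n_dropped`.
#' @export
select_tss_loops <- function(loops, tss, window = 5000) {
  if (is.null(loops$loop_id))
    loops$loop_id <- sprintf("L%05d", seq_len(nrow(loops)))
  mid_a <- (loops$start_a + loops$end_a) / 2
  mid_b <- (loops$start_b + loops$end_b) / 2
  cand <- list()
  for (side in c("a", "b")) {
    mid <- if (side == "a") mid_a else mid_b
    chrom <- if (side == "a") loops$chrom_a else loops$chrom_b
    # pair every loop anchor with every TSS on the same chromosome
    for (gi in seq_len(nrow(tss))) {
      hit <- which(chrom == tss$chrom[gi] &
                     abs(mid - tss$pos[gi]) <= window)
      if (!length(hit)) next
      other <- if (side == "a") {
        data.frame(chrom = loops$chrom_b[hit],
                   distal_start = loops$start_b[hit],
                   distal_end = loops$end_b[hit],
                   distal_mid = mid_b[hit])
      } else {
        data.frame(chrom = loops$chrom_a[hit],
                   distal_start = loops$start_a[hit],
                   distal_end = loops$end_a[hit],
                   distal_mid = mid_a[hit])
      }
      cand[[length(cand) + 1L]] <- cbind(
        data.frame(loop_id = loops$loop_id[hit], gene = tss$gene[gi],
                   tss = tss$pos[gi], stringsAsFactors = FALSE),
        other,
        data.frame(frequency = loops$frequency[hit],
                   tss_anchor_mid = mid[hit]))
    }
  }
  out <- if (length(cand)) unique(do.call(rbind, cand))
  else data.frame(loop_id = character(), gene = character(), tss = numeric(),
                  chrom = character(), distal_start = numeric(),
                  distal_end = numeric(), distal_mid = numeric(),
                  frequency = numeric(), tss_anchor_mid = numeric())
  rownames(out) <- NULL
  attr(out, "n_dropped") <-
    length(setdiff(loops$loop_id, out$loop_id))
  out
}

# Sum track signal over [mid - flank, mid + flank); `track` holds per-bp
# densities on 0-based half-open intervals, column `value`.
window_sum <- function(track, chrom, mid, flank) {
  lo <- mid - flank; hi <- mid + flank
  sel <- track$chrom == chrom & track$end > lo & track$start < hi
  if (!any(sel)) return(0)
  w <- pmin(track$end[sel], hi) - pmax(track$start[sel], lo)
  sum(w * track$value[sel])
}

#' Aggregate enhancer activity at distal anchors
#'
#' Sums H3K27ac and ATAC track signal within `flank` bp on either side of
#' each candidate's distal-anchor midpoint and attaches the ABC score
#' (frequency x geometric mean of the two activities).  Track gaps
#' contribute zero.
#'
#' @param cands candidate data.frame from [select_tss_loops()].
#' @param h3k27ac_track,atac_track data.frames `chrom`, `start`, `end`,
#'   `value` with per-bp signal density (0-based half-open).
#' @param flank half-window around the distal midpoint, bp.
#' @return `cands` with `h3k27ac`, `atac` and `abc_score` columns.
#' @export
aggregate_activity <- function(cands, h3k27ac_track, atac_track,
                               flank = 2500) {
  h <- vapply(seq_len(nrow(cands)), function(i)
    window_sum(h3k27ac_track, cands$chrom[i], cands$distal_mid[i], flank),
    numeric(1))
  a <- vapply(seq_len(nrow(cands)), function(i)
    window_sum(atac_track, cands$chrom[i], cands$distal_mid[i], flank),
    numeric(1))
  cands$h3k27ac <- h
  cands$atac <- a
  cands$abc_score <- score_abc(cands$frequency, h, a)
  cands
}

#' ABC strength score
#'
#' Product of loop contact frequency and the geometric mean of H3K27ac and
#' ATAC activity at the distal anchor.
#'
#' @param frequency,h3k27ac,atac non-negative numerics (vectorized).
#' @return numeric vector of scores.
#' @export
score_abc <- function(frequency, h3k27ac, atac) {
  if (any(frequency < 0) || any(h3k27ac < 0) || any(atac < 0))
    stop("ABC score inputs must be non-negative")
  frequency * sqrt(h3k27ac * atac)
}

#' Trim ABC candidates
#'
#' Sequentially removes (1) TSS-TSS loops (both anchor midpoints within
#' `window` bp of any TSS), (2) loops whose either anchor overlaps a
#' blacklist interval by >= 1 bp, and (3) loops with ABC scores strictly
#' below the genome-wide `percentile` of the remaining scores (candidates
#' exactly at the threshold are kept).  Per-stage survivor counts are
#' recorded in attribute `stage_counts`.
#'
#' @param cands scored candidates from [aggregate_activity()].
#' @param tss TSS annotation (`gene`, `chrom`, `pos`).
#' @param blacklist data.frame `chrom`, `start`, `end` (0-based half-open);
#'   may have zero rows.
#' @param percentile genome-wide score percentile in (0, 100).
#' @param window TSS proximity window for rule (1), bp.
#' @param percentile_first compute the score threshold before rules (1)-(2)
#'   instead of after.
#' @return the trimmed candidate data.frame.
#' @export
trim_candidates <- function(cands, tss, blacklist, percentile = 89,
                            window = 5000, percentile_first = FALSE) {
  if (percentile <= 0 || percentile >= 100)
    stop("percentile must lie strictly between 0 and 100")
  counts <- c(input = nrow(cands))
  thr_pool <- if (percentile_first) cands$abc_score else NULL
  # (1) TSS-TSS loops: distal midpoint also within `window` of any TSS
  near_tss <- function(chrom, mid) {
    vapply(seq_along(mid), function(i)
      any(tss$chrom == chrom[i] & abs(tss$pos - mid[i]) <= window),
      logical(1))
  }
  keep <- !near_tss(cands$chrom, cands$distal_mid)
  cands <- cands[keep, , drop = FALSE]
  counts <- c(counts, tss_tss = nrow(cands))
  # (2) blacklist overlap on either anchor
  if (nrow(blacklist) > 0 && nrow(cands) > 0) {
    bl <- as_granges0(blacklist$chrom, blacklist$start, blacklist$end)
    distal <- as_granges0(cands$chrom, cands$distal_start, cands$distal_end)
    tssa <- as_granges0(cands$chrom, cands$tss_anchor_mid - 1,
                        cands$tss_anchor_mid + 1)
    bad <- GenomicRanges::countOverlaps(distal, bl) > 0 |
      GenomicRanges::countOverlaps(tssa, bl) > 0
    cands <- cands[!bad, , drop = FALSE]
  }
  counts <- c(counts, blacklist = nrow(cands))
  # (3) genome-wide score percentile (nearest rank); strictly-below removed
  if (nrow(cands) > 0) {
    pool <- if (percentile_first) thr_pool else cands$abc_score
    n <- length(pool)
    k <- floor(percentile / 100 * n)
    thr <- if (k >= n) Inf else sort(pool)[k + 1L]
    cands <- cands[cands$abc_score >= thr, , drop = FALSE]
  }
  counts <- c(counts, score = nrow(cands))
  attr(cands, "stage_counts") <- counts
  cands
}

#' Stitch trimmed candidates into ABC regions
#'
#' Merges distal anchor intervals that overlap or lie within `gap` bp of
#' each other into regions; each region keeps its member candidates and
#' inherits their gene links.
#'
#' @param cands trimmed candidate data.frame.
#' @param gap maximum gap for stitching, bp (0 = overlapping or bookended).
#' @return list: `regions` (data.frame `region_id`, `chrom`, `start`,
#'   `end`, `n_members`) and `links` (data.frame `region_id`, `gene`,
#'   `loop_id`, `frequency`, `abc_score`).
#' @export
stitch_regions <- function(cands, gap = 0) {
  if (nrow(cands) == 0)
    return(list(regions = data.frame(region_id = character(),
                                     chrom = character(), start = numeric(),
                                     end = numeric(), n_members = integer()),
                links = data.frame(region_id = character(), gene = character(),
                                   loop_id = character(), frequency = numeric(),
                                   abc_score = numeric())))
  gr <- as_granges0(cands$chrom, cands$distal_start, cands$distal_end)
  merged <- GenomicRanges::sort(GenomicRanges::reduce(gr,
                                                      min.gapwidth = gap + 1))
  hit <- GenomicRanges::findOverlaps(gr, merged)
  region_of <- rep(NA_integer_, nrow(cands))
  region_of[S4Vectors::queryHits(hit)] <- S4Vectors::subjectHits(hit)
  bed <- granges_to_bed0(merged)
  bed$region_id <- sprintf("R%05d", seq_len(nrow(bed)))
  bed$n_members <- as.integer(table(factor(region_of,
                                           levels = seq_len(nrow(bed)))))
  links <- unique(data.frame(region_id = bed$region_id[region_of],
                             gene = cands$gene, loop_id = cands$loop_id,
                             frequency = cands$frequency,
                             abc_score = cands$abc_score,
                             stringsAsFactors = FALSE))
  rownames(links) <- NULL
  list(regions = bed[, c("region_id", "chrom", "start", "end", "n_members")],
       links = links)
}

#' Quantify regions per sample and correlate with expression
#'
#' Computes each sample's normalized enhancer signal over the stitched
#' regions (per-sample H3K27ac summed over the region, divided by the
#' sample's total over all regions, so signals sum to 1 per sample), then
#' the Pearson correlation between region signal and target-gene expression
#' separately in each cohort.  Associations with r > `r_min` in either
#' cohort are kept.
#'
#' @param stitched output of [stitch_regions()].
#' @param sample_tracks long data.frame `chrom`, `start`, `end`, `sample`,
#'   `value` of per-bp H3K27ac density per sample.
#' @param expr genes x samples matrix of log2(TPM+1) expression.
#' @param cohorts named character vector sample -> cohort label (two
#'   cohorts expected; a cohort with < 3 samples gets NA correlations).
#' @param r_min correlation threshold (strictly greater retained).
#' @return list: `associations` (data.frame `region_id`, `gene`,
#'   `r_cohort1`, `r_cohort2`, `source` = "abc") and `signal` (regions x
#'   samples normalized signal matrix, rows named by region_id).
#' @export
quantify_and_correlate <- function(stitched, sample_tracks, expr, cohorts,
                                   r_min = 0.3) {
  regions <- stitched$regions
  samples <- unique(sample_tracks$sample)
  sig <- matrix(0, nrow(regions), length(samples),
                dimnames = list(regions$region_id, samples))
  for (s in samples) {
    tr <- sample_tracks[sample_tracks$sample == s, ]
    tr$value <- if ("h3k27ac" %in% names(tr)) tr$h3k27ac else tr$value
    sig[, s] <- vapply(seq_len(nrow(regions)), function(i) {
      sel <- tr$chrom == regions$chrom[i] & tr$end > regions$start[i] &
        tr$start < regions$end[i]
      if (!any(sel)) return(0)
      w <- pmin(tr$end[sel], regions$end[i]) -
        pmax(tr$start[sel], regions$start[i])
      sum(w * tr$value[sel])
    }, numeric(1))
  }
  tot <- colSums(sig)
  if (any(tot == 0)) stop("sample with zero total region signal")
  sig <- sweep(sig, 2, tot, `/`)
  cohort_names <- sort(unique(cohorts))
  cor_in_cohort <- function(region_id, gene, cohort) {
    ss <- intersect(names(cohorts)[cohorts == cohort],
                    intersect(colnames(sig), colnames(expr)))
    if (length(ss) < 3 || !gene %in% rownames(expr)) return(NA_real_)
    x <- sig[region_id, ss]; y <- expr[gene, ss]
    if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
    cor(x, y)
  }
  links <- unique(stitched$links[, c("region_id", "gene")])
  links$r_cohort1 <- mapply(cor_in_cohort, links$region_id, links$gene,
                            MoreArgs = list(cohort = cohort_names[1]))
  links$r_cohort2 <- if (length(cohort_names) > 1)
    mapply(cor_in_cohort, links$region_id, links$gene,
           MoreArgs = list(cohort = cohort_names[2])) else NA_real_
  rmax <- pmax(links$r_cohort1, links$r_cohort2, na.rm = TRUE)
  rmax[is.na(links$r_cohort1) & is.na(links$r_cohort2)] <- -Inf
  keep <- rmax > r_min
  assoc <- links[keep, , drop = FALSE]
  assoc$source <- rep("abc", nrow(assoc))
  rownames(assoc) <- NULL
  list(associations = assoc, signal = sig)
}

#' Merge ABC and proximity gene associations
#'
#' Set union keyed on (region, gene); pairs present in both lists collapse
#' to one row with `source = "both"`.
#'
#' @param abc,proximity data.frames with at least `region_id` and `gene`
#'   (`proximity` rows get `source = "proximity"` if absent).
#' @return merged association data.frame.
#' @export
merge_with_proximity <- function(abc, proximity) {
  if (nrow(proximity) > 0 && is.null(proximity$source))
    proximity$source <- "proximity"
  all_cols <- union(names(abc), names(proximity))
  pad <- function(df) {
    for (cl in setdiff(all_cols, names(df))) df[[cl]] <- NA
    df[, all_cols, drop = FALSE]
  }
  both <- rbind(pad(abc), pad(proximity))
  if (nrow(both) == 0) return(both)
  key <- paste(both$region_id, both$gene, sep = "\r")
  dup <- key[duplicated(key)]
  both$source[key %in% dup] <- "both"
  out <- both[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the modified ABC assignment end to end
#'
#' @param loops,tss,blacklist see [select_tss_loops()] and
#'   [trim_candidates()].
#' @param h3k27ac_track,atac_track pooled activity tracks for scoring.
#' @param sample_tracks per-sample H3K27ac tracks for correlation.
#' @param expr expression matrix; `cohorts` named sample -> cohort.
#' @param window,flank,percentile,gap,r_min stage parameters.
#' @param proximity optional proximity association table to merge.
#' @return list with `candidates`, `trimmed`, `stitched`, `associations`,
#'   `signal` and per-stage `counts`.
#' @export
run_abc <- function(loops, tss, blacklist, h3k27ac_track, atac_track,
                    sample_tracks, expr, cohorts, window = 5000,
                    flank = 2500, percentile = 89, gap = 0, r_min = 0.3,
                    proximity = NULL) {
  cands <- select_tss_loops(loops, tss, window = window)
  cands <- aggregate_activity(cands, h3k27ac_track, atac_track, flank = flank)
  trimmed <- trim_candidates(cands, tss, blacklist, percentile = percentile,
                             window = window)
  stitched <- stitch_regions(trimmed, gap = gap)
  qc <- quantify_and_correlate(stitched, sample_tracks, expr, cohorts,
                               r_min = r_min)
  assoc <- qc$associations
  if (!is.null(proximity)) assoc <- merge_with_proximity(assoc, proximity)
  counts <- c(candidates = nrow(cands),
              attr(trimmed, "stage_counts")[-1],
              regions = nrow(stitched$regions),
              associations = nrow(assoc))
  list(candidates = cands, trimmed = trimmed, stitched = stitched,
       associations = assoc, signal = qc$signal, counts = counts)
}
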