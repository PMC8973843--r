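# 3D puncta aggregation and colocalization testing.  Per-z-slice 2D
# (discoid) detections are linked across consecutive slices into spheroids;
# red (RNA FISH) foci are capped per nucleus; colocalization of red with
# green (protein IF) puncta is tested by Fisher's exact test against the
# expectation from the nuclear volume fraction occupied by green puncta.

#' Aggregate per-slice discoids into 3D spheroids
#'
#' Within each cell and channel, discoids on consecutive z-slices are linked
#' when the xy distance between their centers is strictly less than the mean
#' discoid diameter of that cell/channel; connected components become
#' spheroids.  Spheroids represented on a single z-slice are discarded.
#'
#' @param puncta data.frame with columns `cell`, `channel`, `z_index`, `x`,
#'   `y`, `radius`, `fluorescence` (lengths in nm).
#' @param z_spacing z-stack spacing, nm (> 0).
#' @return data.frame of spheroids: `spheroid_id`, `cell`, `channel`, `x`,
#'   `y`, `z` (fluorescence-weighted center, nm), `n_slices`, `radius`
#'   (max member discoid radius), `volume` (sphere of that radius, nm^3),
#'   `total_fluorescence`.
#' @export
aggregate_spheroids <- function(puncta, z_spacing) {
  stopifnot_scalar_pos(z_spacing, "z_spacing")
  need <- c("cell", "channel", "z_index", "x", "y", "radius", "fluorescence")
  if (!all(need %in% names(puncta)))
    stop("puncta table needs columns: ", paste(need, collapse = ", "))
  out <- list()
  for (key in split(seq_len(nrow(puncta)),
                    paste(puncta$cell, puncta$channel, sep = "\r"))) {
    p <- puncta[key, , drop = FALSE]
    link_dist <- 2 * mean(p$radius)         # mean discoid diameter
    n <- nrow(p)
    # collect links between discoids on consecutive z-slices (strict <)
    ord <- order(p$z_index)
    by_z <- split(ord, p$z_index[ord])
    zs <- as.integer(names(by_z))
    edges <- list()
    for (zi in seq_along(zs)) {
      nxt <- match(zs[zi] + 1L, zs)
      if (is.na(nxt)) next
      i <- by_z[[zi]]; j <- by_z[[nxt]]
      d2 <- outer(p$x[i], p$x[j], `-`)^2 + outer(p$y[i], p$y[j], `-`)^2
      hit <- which(d2 < link_dist^2, arr.ind = TRUE)
      if (nrow(hit))
        edges[[length(edges) + 1L]] <- cbind(i[hit[, 1]], j[hit[, 2]])
    }
    # union-find over the collected edges
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    if (length(edges)) {
      for (e in seq_len(nrow(em <- do.call(rbind, edges)))) {
        ri <- find(em[e, 1]); rj <- find(em[e, 2])
        if (ri != rj) parent[rj] <- ri
      }
    }
    comp <- vapply(seq_len(n), find, integer(1))
    f <- factor(comp)
    n_slices <- vapply(split(p$z_index, f),
                       function(z) length(unique(z)), integer(1))
    w <- pmax(p$fluorescence, .Machine$double.eps)  # all-zero guard
    wsum <- as.numeric(tapply(w, f, sum))
    df <- data.frame(
      cell = p$cell[1], channel = p$channel[1],
      x = as.numeric(tapply(p$x * w, f, sum)) / wsum,
      y = as.numeric(tapply(p$y * w, f, sum)) / wsum,
      z = as.numeric(tapply(p$z_index * z_spacing * w, f, sum)) / wsum,
      n_slices = n_slices,
      radius = as.numeric(tapply(p$radius, f, max)),
      total_fluorescence = as.numeric(tapply(p$fluorescence, f, sum)),
      stringsAsFactors = FALSE)
    df <- df[df$n_slices >= 2, , drop = FALSE]   # single-slice: discard
    if (nrow(df)) out[[length(out) + 1L]] <- df
  }
  if (!length(out))
    return(data.frame(spheroid_id = character(), cell = character(),
                      channel = character(), x = numeric(), y = numeric(),
                      z = numeric(), n_slices = integer(), radius = numeric(),
                      volume = numeric(), total_fluorescence = numeric()))
  res <- do.call(rbind, out)
  res$volume <- 4 / 3 * pi * res$radius^3
  res <- res[order(res$cell, res$channel, res$x), , drop = FALSE]
  res$spheroid_id <- sprintf("SPH%05d", seq_len(nrow(res)))
  rownames(res) <- NULL
  res[, c("spheroid_id", "cell", "channel", "x", "y", "z", "n_slices",
          "radius", "volume", "total_fluorescence")]
}

#' Cap RNA-FISH foci per nucleus
#'
#' Keeps at most `max_foci` red spheroids per cell, ranked by total
#' fluorescence (ties broken deterministically by spheroid id), reflecting
#' a known transcribed-allele copy number; extra detections are background.
#'
#' @param spheroids spheroid data.frame from [aggregate_spheroids()].
#' @param max_foci maximum red foci per nucleus.
#' @param channel channel to cap (default "red").
#' @return the capped spheroid data.frame.
#' @export
cap_rna_foci <- function(spheroids, max_foci = 3L, channel = "red") {
  is_ch <- spheroids$channel == channel
  keep <- rep(TRUE, nrow(spheroids))
  for (cell in unique(spheroids$cell[is_ch])) {
    idx <- which(is_ch & spheroids$cell == cell)
    if (length(idx) <= max_foci) next
    ord <- idx[order(-spheroids$total_fluorescence[idx],
                     spheroids$spheroid_id[idx])]
    keep[setdiff(idx, ord[seq_len(max_foci)])] <- FALSE
  }
  spheroids[keep, , drop = FALSE]
}

#' Fisher exact colocalization test
#'
#' Counts red spheroids whose center lies inside any green spheroid of the
#' same cell, compares this with the expectation under uniform placement
#' (n_red x green volume fraction of the nucleus, rounded half-up), and
#' tests the 2x2 table observed/expected by a two-sided Fisher exact test.
#' Cells are pooled: counts and expectations are summed over cells before
#' the test.
#'
#' @param red,green spheroid data.frames (one channel each) from
#'   [aggregate_spheroids()]; `red` should already be capped.
#' @param geom data.frame `cell`, `nucleus_volume`, `green_occupied_volume`.
#' @param predicate `"center_inside"` (default; red center within a green
#'   spheroid's radius) or `"center_distance"` with `max_distance` nm.
#' @param max_distance center-distance threshold for the alternative
#'   predicate.
#' @return list of class `coloc_result`: `n_red`, `observed_coloc`,
#'   `expected_coloc`, `fisher_p`, `odds_ratio`, `table`.
#' @export
colocalization_test <- function(red, green, geom,
                                predicate = c("center_inside",
                                              "center_distance"),
                                max_distance = NULL) {
  predicate <- match.arg(predicate)
  if (nrow(red) == 0) stop("no red spheroids to test")
  if (any(geom$nucleus_volume <= 0)) stop("nucleus volume must be positive")
  observed <- 0L
  expected <- 0
  for (cell in unique(red$cell)) {
    r <- red[red$cell == cell, , drop = FALSE]
    g <- green[green$cell == cell, , drop = FALSE]
    ge <- geom[geom$cell == cell, , drop = FALSE]
    if (nrow(ge) != 1) stop("geometry missing for cell ", cell)
    frac <- ge$green_occupied_volume / ge$nucleus_volume
    obs_cell <- 0L
    if (nrow(g) > 0) {
      for (i in seq_len(nrow(r))) {
        d <- sqrt((r$x[i] - g$x)^2 + (r$y[i] - g$y)^2 + (r$z[i] - g$z)^2)
        inside <- if (predicate == "center_inside") any(d < g$radius)
        else any(d < max_distance)
        if (inside) obs_cell <- obs_cell + 1L
      }
    }
    if (frac == 0 && obs_cell > 0)
      stop("green volume fraction 0 with observed colocalization: ",
           "inconsistent geometry")
    observed <- observed + obs_cell
    expected <- expected + nrow(r) * frac
  }
  n_red <- nrow(red)
  exp_int <- floor(expected + 0.5)           # round half-up
  tab <- matrix(c(observed, n_red - observed,
                  exp_int, n_red - exp_int), 2, 2, byrow = TRUE,
                dimnames = list(c("observed", "expected"),
                                c("coloc", "not_coloc")))
  ft <- fisher.test(t(tab))
  structure(list(n_red = n_red, observed_coloc = observed,
                 expected_coloc = expected, fisher_p = ft$p.value,
                 odds_ratio = unname(ft$estimate), table = tab),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf(
    "coloc_result: %d/%d red puncta colocalized (expected %.2f), p = %.3g\n",
    x$observed_coloc, x$n_red, x$expected_coloc, x$fisher_p))
  invisible(x)
}

#' Compare puncta count and intensity between conditions
#'
#' Per-nucleus spheroid counts and mean fluorescence, compared between two
#' conditions with two-sided Mann-Whitney U tests.
#'
#' @param spheroids spheroid data.frame (one channel).
#' @param conditions named character vector cell -> condition (exactly two
#'   conditions, both non-empty).
#' @return list: `per_nucleus` (cell, condition, count, mean_fluorescence),
#'   `count_p`, `intensity_p` (NA and flagged when a condition has a single
#'   nucleus).
#' @export
summarize_puncta <- function(spheroids, conditions) {
  conds <- unique(conditions)
  if (length(conds) != 2) stop("exactly two conditions required")
  cells <- names(conditions)
  per <- do.call(rbind, lapply(cells, function(cl) {
    s <- spheroids[spheroids$cell == cl, , drop = FALSE]
    data.frame(cell = cl, condition = conditions[[cl]],
               count = nrow(s),
               mean_fluorescence = if (nrow(s)) mean(s$total_fluorescence)
               else NA_real_,
               stringsAsFactors = FALSE)
  }))
  n1 <- sum(per$condition == conds[1]); n2 <- sum(per$condition == conds[2])
  if (n1 == 0 || n2 == 0) stop("a condition has no nuclei")
  if (n1 < 2 || n2 < 2) {
    return(list(per_nucleus = per, count_p = NA_real_,
                intensity_p = NA_real_, flag = "single_nucleus_condition"))
  }
  a <- per[per$condition == conds[1], ]
  b <- per[per$condition == conds[2], ]
  rank_p <- function(x, y) {
    if (length(unique(c(x, y))) == 1L) return(1)   # no variation: no signal
    suppressWarnings(wilcox.test(x, y)$p.value)
  }
  list(per_nucleus = per,
       count_p = rank_p(a$count, b$count),
       intensity_p = rank_p(a$mean_fluorescence, b$mean_fluorescence),
       flag = "")
}
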