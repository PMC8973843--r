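# Synthetic-data generators.
#
# Every pipeline input can be generated here with planted ground truth: a
# gene-effect screen with selective/common-essential/null genes, a toy
# regulatory locus with true and decoy enhancer-gene loops, reference
# expression profiles with planted marker separation, and microscopy puncta
# fields with a controlled colocalization fraction.  Each generator is
# deterministic given its seed and returns a `truth` table listing every
# generated entity exactly once.

#' Simulate a CRISPR gene-effect screen
#'
#' Generates a genes x cell-lines gene-effect matrix on the control-anchored
#' scale (0 = nonessential controls, -1 = median of common essentials),
#' with three planted gene classes: null genes centered at 0 in every line,
#' common-essential genes centered at -1 in every line, and selective genes
#' shifted negative only in an annotated in-group of lines.  Dependency
#' probabilities are a monotone logistic transform of the effect, centered at
#' -0.5 with scale 0.1, so an effect of -1 maps to ~0.99 and 0 to ~0.01.
#' Per-gene noise is Gaussian with heteroscedastic standard deviations drawn
#' log-normally around `noise_sd`.
#'
#' @param n_genes total number of genes (>= 10).
#' @param n_lines total number of cell lines (>= 6).
#' @param n_selective number of planted in-group-selective genes.
#' @param n_common number of planted common-essential genes.
#' @param n_ingroup size of the annotated in-group ("AML"-like lineage).
#' @param n_subtype number of in-group lines flagged as the focal subtype
#'   (e.g. carrying a KMT2A rearrangement); must be <= `n_ingroup`.
#' @param shift planted in-group mean effect for selective genes.
#' @param noise_sd baseline per-observation noise standard deviation.
#' @param het_sdlog log-sd of the per-gene lognormal noise multiplier.
#' @param seed integer master seed.
#' @return list of class `gene_effect_matrix` with elements `effect` and
#'   `probability` (gene x line matrices), `annotations` (data.frame with
#'   `sample`, `lineage`, `subtype`), and `truth` (data.frame with one row
#'   per gene: `gene`, `planted_class`, `shift`, `noise_sd`).
#' @export
sim_gene_effect <- function(n_genes = 200, n_lines = 30, n_selective = 5,
                            n_common = 5, n_ingroup = 10, n_subtype = 4,
                            shift = -1, noise_sd = 0.15, het_sdlog = 0.2,
                            seed = 1) {
  if (n_genes < 10 || n_lines < 6) stop("need n_genes >= 10 and n_lines >= 6")
  if (n_selective + n_common > n_genes) stop("planted genes exceed n_genes")
  if (n_ingroup < 3 && n_selective > 0)
    stop("in-group must have >= 3 lines for planted selective genes")
  if (n_subtype > n_ingroup) stop("n_subtype cannot exceed n_ingroup")
  with_seed(child_seed(seed, "gene_effect"), {
    genes <- sprintf("G%04d", seq_len(n_genes))
    lines <- sprintf("LINE%03d", seq_len(n_lines))
    cls <- rep("null_gene", n_genes)
    cls[seq_len(n_selective)] <- "selective_dependency"
    cls[n_selective + seq_len(n_common)] <- "common_essential"
    in_group <- c(rep(TRUE, n_ingroup), rep(FALSE, n_lines - n_ingroup))
    gene_sd <- noise_sd * rlnorm(n_genes, 0, het_sdlog)
    mu <- matrix(0, n_genes, n_lines, dimnames = list(genes, lines))
    mu[cls == "common_essential", ] <- -1
    mu[cls == "selective_dependency", in_group] <- shift
    eff <- mu + matrix(rnorm(n_genes * n_lines), n_genes, n_lines) * gene_sd
    dimnames(eff) <- list(genes, lines)
    prob <- plogis((-0.5 - eff) / 0.1)
    ann <- data.frame(sample = lines,
                      lineage = ifelse(in_group, "AML", "other"),
                      subtype = in_group & seq_len(n_lines) <= n_subtype,
                      stringsAsFactors = FALSE)
    truth <- data.frame(gene = genes, planted_class = cls,
                        shift = ifelse(cls == "selective_dependency", shift,
                                       ifelse(cls == "common_essential", -1, 0)),
                        noise_sd = gene_sd, stringsAsFactors = FALSE)
    structure(list(effect = eff, probability = prob, annotations = ann,
                   truth = truth),
              class = "gene_effect_matrix")
  })
}

#' @export
print.gene_effect_matrix <- function(x, ...) {
  tab <- table(x$annotations$lineage)
  cat(sprintf("gene_effect_matrix: %d genes x %d lines (%s)\n",
              nrow(x$effect), ncol(x$effect),
              paste(names(tab), tab, sep = ": ", collapse = ", ")))
  invisible(x)
}

#' Simulate a toy regulatory locus with planted enhancer-gene loops
#'
#' Builds a single toy chromosome carrying gene TSSs and distal anchors,
#' HiChIP-style loops connecting TSSs to anchors, per-sample H3K27ac and ATAC
#' activity over the anchors, and a matching expression matrix.  True links
#' connect a TSS to a high-activity anchor whose H3K27ac covaries with the
#' gene's expression (Pearson coupling `coupling` across samples) and carry
#' high contact frequency; decoy links point at low-activity, uncorrelated
#' anchors.  Samples split into two equally sized cohorts.
#'
#' @param n_genes number of genes (>= 1).
#' @param n_true number of planted true enhancer-gene links.
#' @param n_decoy number of decoy links.
#' @param n_samples_per_cohort samples per cohort (two cohorts generated).
#' @param coupling planted activity-expression Pearson coupling in [0, 1].
#' @param anchor_width width of every anchor footprint, bp.
#' @param true_freq,decoy_freq Poisson means of loop contact frequencies.
#' @param true_act,decoy_act mean per-bp activity of true/decoy anchors.
#' @param seed integer master seed.
#' @return list of class `regulatory_locus` with `loops` (BEDPE-style
#'   data.frame with `frequency`), `tss` (gene, chrom, pos), `tracks` (long
#'   data.frame: chrom, start, end, sample, h3k27ac, atac -- per-bp
#'   densities), `pooled_track` (same intervals, sample-averaged), `expr`
#'   (genes x samples log2(TPM+1)), `cohorts` (named character of sample ->
#'   cohort), `blacklist` (empty BED data.frame), and `truth` (one row per
#'   loop: `loop_id`, `gene`, `planted_class` true_link/false_link,
#'   `coupling`).
#' @export
sim_regulatory_locus <- function(n_genes = 10, n_true = 20, n_decoy = 200,
                                 n_samples_per_cohort = 12, coupling = 0.9,
                                 anchor_width = 1000, true_freq = 30,
                                 decoy_freq = 5, true_act = 50,
                                 decoy_act = 5, seed = 1) {
  if (n_genes < 1) stop("need at least one gene")
  if (n_samples_per_cohort < 1) stop("need at least one sample per cohort")
  if (coupling < 0 || coupling > 1) stop("coupling must lie in [0, 1]")
  with_seed(child_seed(seed, "regulatory_locus"), {
    n_anchors <- n_true + n_decoy
    n_samples <- 2L * n_samples_per_cohort
    samples <- sprintf("S%03d", seq_len(n_samples))
    cohorts <- setNames(rep(c("cohort1", "cohort2"),
                            each = n_samples_per_cohort), samples)
    genes <- sprintf("GENE%03d", seq_len(n_genes))
    # layout: TSSs first, then anchors, all spaced 50 kb apart on one chrom
    spacing <- 50000L
    tss_pos <- spacing * seq_len(n_genes)
    anchor_start <- spacing * (n_genes + seq_len(n_anchors))
    tss <- data.frame(gene = genes, chrom = "chrS", pos = tss_pos,
                      stringsAsFactors = FALSE)
    # expression: per-gene baseline + standard-normal sample variation
    z_expr <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
                     dimnames = list(genes, samples))
    expr <- sweep(z_expr, 1, runif(n_genes, 4, 8), `+`)
    # anchors: first n_true are true anchors paired 1:1 with a gene
    link_gene <- c(genes[(seq_len(n_true) - 1L) %% n_genes + 1L],
                   genes[(seq_len(n_decoy) - 1L) %% n_genes + 1L])
    is_true <- c(rep(TRUE, n_true), rep(FALSE, n_decoy))
    act <- matrix(NA_real_, n_anchors, n_samples,
                  dimnames = list(NULL, samples))
    for (i in seq_len(n_anchors)) {
      if (is_true[i]) {
        zg <- z_expr[link_gene[i], ]
        zi <- coupling * zg + sqrt(1 - coupling^2) * rnorm(n_samples)
        act[i, ] <- pmax(true_act + 0.2 * true_act * zi, 0.5)
      } else {
        act[i, ] <- pmax(decoy_act + 0.4 * decoy_act * rnorm(n_samples), 0.1)
      }
    }
    atac <- pmax(0.8 * act + 0.1 * mean(act) * rnorm(length(act)), 0.05)
    dim(atac) <- dim(act); dimnames(atac) <- dimnames(act)
    tracks <- data.frame(
      chrom = "chrS",
      start = rep(anchor_start, n_samples),
      end = rep(anchor_start + anchor_width, n_samples),
      sample = rep(samples, each = n_anchors),
      h3k27ac = as.vector(act) / anchor_width,
      atac = as.vector(atac) / anchor_width,
      stringsAsFactors = FALSE)
    pooled <- data.frame(chrom = "chrS", start = anchor_start,
                         end = anchor_start + anchor_width,
                         h3k27ac = rowMeans(act) / anchor_width,
                         atac = rowMeans(atac) / anchor_width,
                         stringsAsFactors = FALSE)
    freq <- rpois(n_anchors, ifelse(is_true, true_freq, decoy_freq))
    tss_of <- setNames(tss_pos, genes)
    loops <- data.frame(
      loop_id = sprintf("L%04d", seq_len(n_anchors)),
      chrom_a = "chrS",
      start_a = tss_of[link_gene] - 250L,
      end_a = tss_of[link_gene] + 250L,
      chrom_b = "chrS",
      start_b = anchor_start,
      end_b = anchor_start + anchor_width,
      frequency = freq,
      stringsAsFactors = FALSE)
    truth <- data.frame(loop_id = loops$loop_id, gene = link_gene,
                        planted_class = ifelse(is_true, "true_link",
                                               "false_link"),
                        coupling = ifelse(is_true, coupling, 0),
                        stringsAsFactors = FALSE)
    structure(list(loops = loops, tss = tss, tracks = tracks,
                   pooled_track = pooled, expr = expr, cohorts = cohorts,
                   blacklist = data.frame(chrom = character(),
                                          start = integer(), end = integer()),
                   truth = truth),
              class = "regulatory_locus")
  })
}

#' Simulate reference expression profiles with planted marker separation
#'
#' Generates log2(TPM+1)-scale expression for labeled reference cell types
#' (HSC, monocyte, and optionally T and B cells) plus optional unlabeled
#' query samples drawn from the HSC-like or monocyte-like profile.  Planted
#' marker genes receive the configured mean separation between HSC and
#' monocyte; null genes share one mean.  By default markers are HSC-high
#' (positive separation index, so signed top-k ranking recovers them
#' exactly); `marker_direction = "alternate"` plants both HSC-high and
#' monocyte-high markers, exercising the sign-flip step of the lineage
#' index.
#'
#' @param n_markers planted marker genes.
#' @param n_null null genes.
#' @param n_per_type reference samples per cell type (>= 2).
#' @param mean_a,mean_b HSC / monocyte marker means (first marker; direction
#'   alternates across markers around the midpoint).
#' @param var_a,var_b HSC / monocyte variances (> 0).
#' @param n_query_a,n_query_b unlabeled query samples drawn HSC-like /
#'   monocyte-like.
#' @param marker_direction `"hsc_high"` (default) or `"alternate"`.
#' @param types reference cell types to emit.
#' @param seed integer master seed.
#' @return list of class `reference_expression`: `expr` (genes x samples),
#'   `labels` (named character; query samples labeled "query"),
#'   `truth` (gene, planted_class marker/null_gene, direction, separation),
#'   `query_truth` (named character of query sample -> profile).
#' @export
sim_reference_expression <- function(n_markers = 19, n_null = 500,
                                     n_per_type = 4, mean_a = 10, mean_b = 4,
                                     var_a = 4, var_b = 4,
                                     n_query_a = 0, n_query_b = 0,
                                     marker_direction = c("hsc_high",
                                                          "alternate"),
                                     types = c("HSC", "monocyte", "T", "B"),
                                     seed = 1) {
  marker_direction <- match.arg(marker_direction)
  if (n_per_type < 2) stop("need >= 2 samples per reference cell type")
  if (var_a <= 0 || var_b <= 0) stop("variances must be positive")
  with_seed(child_seed(seed, "reference_expression"), {
    genes <- c(sprintf("MRK%03d", seq_len(n_markers)),
               sprintf("NUL%03d", seq_len(n_null)))
    direction <- if (marker_direction == "hsc_high") rep(1, n_markers)
    else rep(c(1, -1), length.out = n_markers)          # 1 = HSC-high
    mid <- (mean_a + mean_b) / 2
    half <- (mean_a - mean_b) / 2
    mu_hsc <- c(mid + direction * half, rep(mid, n_null))
    mu_mono <- c(mid - direction * half, rep(mid, n_null))
    labels <- rep(types, each = n_per_type)
    samples <- paste0(labels, "_", sequence(rep(n_per_type, length(types))))
    mu_of <- function(lab) switch(lab, HSC = mu_hsc, monocyte = mu_mono,
                                  rep(mid, length(genes)))  # T/B: flat
    sd_of <- function(lab) switch(lab, HSC = sqrt(var_a),
                                  monocyte = sqrt(var_b),
                                  sqrt((var_a + var_b) / 2))
    cols <- lapply(seq_along(samples), function(j)
      mu_of(labels[j]) + rnorm(length(genes), 0, sd_of(labels[j])))
    if (n_query_a + n_query_b > 0) {
      qlab <- c(rep("HSC", n_query_a), rep("monocyte", n_query_b))
      qnames <- sprintf("QRY_%02d", seq_along(qlab))
      qcols <- lapply(qlab, function(lab)
        mu_of(lab) + rnorm(length(genes), 0, sd_of(lab)))
      cols <- c(cols, qcols)
      samples <- c(samples, qnames)
      labels <- c(labels, rep("query", length(qlab)))
      query_truth <- setNames(qlab, qnames)
    } else query_truth <- setNames(character(), character())
    expr <- do.call(cbind, cols)
    dimnames(expr) <- list(genes, samples)
    truth <- data.frame(
      gene = genes,
      planted_class = c(rep("marker", n_markers), rep("null_gene", n_null)),
      direction = c(direction, rep(0, n_null)),
      separation = c(direction * (mean_a - mean_b) / sqrt((var_a + var_b) / 2),
                     rep(0, n_null)),
      stringsAsFactors = FALSE)
    structure(list(expr = expr, labels = setNames(labels, samples),
                   truth = truth, query_truth = query_truth),
              class = "reference_expression")
  })
}

#' Simulate a 3D puncta field
#'
#' Places green (protein IF) and red (RNA FISH) spheroids inside spherical
#' nuclei and emits them as per-z-slice 2D discoids, the form produced by
#' SIM image segmentation.  A configured fraction of red puncta is planted
#' inside green puncta; the remainder (and all green puncta) are uniform in
#' the nucleus volume.  Spheroid radii smaller than the z spacing would give
#' single-slice detections, which downstream aggregation discards; such
#' puncta are flagged `discard_candidate` in the truth table.
#'
#' @param n_cells number of nuclei.
#' @param nucleus_radius nucleus radius, nm.
#' @param n_green,n_red green / red spheroids per nucleus.
#' @param green_radius,red_radius spheroid radii, nm.
#' @param coloc_fraction fraction of red puncta planted inside green ones.
#' @param z_spacing z-stack spacing, nm.
#' @param fluor_scale fluorescence per nm^2 of discoid area.
#' @param seed integer master seed.
#' @return list of class `puncta_field`: `puncta` (data.frame: cell, channel,
#'   punctum_id, z_index, x, y, radius, fluorescence), `geometry` (cell,
#'   nucleus_volume, green_occupied_volume), `truth` (punctum_id, cell,
#'   channel, planted_class colocalized/random, discard_candidate), and
#'   `params`.
#' @export
sim_puncta_field <- function(n_cells = 10, nucleus_radius = 4000,
                             n_green = 120, n_red = 3, green_radius = 300,
                             red_radius = 300, coloc_fraction = 0,
                             z_spacing = 125, fluor_scale = 1e-3, seed = 1) {
  stopifnot_scalar_pos(nucleus_radius, "nucleus_radius")
  stopifnot_scalar_pos(z_spacing, "z_spacing")
  if (green_radius <= 0 || red_radius <= 0) stop("puncta radii must be > 0")
  if (coloc_fraction < 0 || coloc_fraction > 1)
    stop("coloc_fraction must lie in [0, 1]")
  vol_frac <- n_green * (green_radius / nucleus_radius)^3
  if (vol_frac >= 1)
    stop("requested green puncta volume exceeds the nucleus volume")
  with_seed(child_seed(seed, "puncta_field"), {
    unif_in_sphere <- function(n, R) {
      # rejection-free: direction x radius with cube-root law
      u <- matrix(rnorm(3 * n), n, 3)
      u <- u / sqrt(rowSums(u^2))
      u * R * runif(n)^(1 / 3)
    }
    puncta <- list(); truth <- list(); geom <- list()
    for (ci in seq_len(n_cells)) {
      cell <- sprintf("cell%03d", ci)
      gc <- unif_in_sphere(n_green, nucleus_radius - green_radius)
      n_col <- round(coloc_fraction * n_red)
      rc <- matrix(NA_real_, n_red, 3)
      if (n_col > 0) {
        host <- sample.int(n_green, n_col, replace = TRUE)
        rc[seq_len(n_col), ] <- gc[host, , drop = FALSE] +
          unif_in_sphere(n_col, green_radius * 0.99)
      }
      if (n_red > n_col)
        rc[(n_col + 1):n_red, ] <-
          unif_in_sphere(n_red - n_col, nucleus_radius - red_radius)
      emit <- function(centers, radius, channel) {
        empty <- data.frame(cell = character(), channel = character(),
                            punctum_id = character(), z_index = integer(),
                            x = numeric(), y = numeric(), radius = numeric(),
                            fluorescence = numeric(), stringsAsFactors = FALSE)
        if (nrow(centers) == 0) return(empty)
        n <- nrow(centers)
        z0 <- centers[, 3]
        z_lo <- floor((z0 - radius) / z_spacing) + 1
        z_hi <- ceiling((z0 + radius) / z_spacing) - 1
        cnt <- pmax(z_hi - z_lo + 1, 0)
        if (sum(cnt) == 0) return(empty)
        idx <- rep.int(seq_len(n), cnt)
        zk <- unlist(lapply(seq_len(n), function(i)
          if (cnt[i] > 0) z_lo[i]:z_hi[i] else integer()))
        keep <- abs(zk * z_spacing - z0[idx]) < radius
        idx <- idx[keep]; zk <- zk[keep]
        if (!length(idx)) return(empty)
        rdisc <- sqrt(radius^2 - (zk * z_spacing - z0[idx])^2)
        data.frame(
          cell = cell, channel = channel,
          punctum_id = sprintf("%s_%s_%03d", cell, channel, idx),
          z_index = as.integer(zk), x = centers[idx, 1], y = centers[idx, 2],
          radius = rdisc, fluorescence = fluor_scale * pi * rdisc^2,
          stringsAsFactors = FALSE)
      }
      pg <- emit(gc, green_radius, "green")
      pr <- emit(rc, red_radius, "red")
      puncta[[ci]] <- rbind(pg, pr)
      slice_counts <- c(table(pg$punctum_id), table(pr$punctum_id))
      ids_g <- sprintf("%s_green_%03d", cell, seq_len(n_green))
      ids_r <- sprintf("%s_red_%03d", cell, seq_len(n_red))
      truth[[ci]] <- data.frame(
        punctum_id = c(ids_g, ids_r),
        cell = cell,
        channel = c(rep("green", n_green), rep("red", n_red)),
        planted_class = c(rep("random", n_green),
                          c(rep("colocalized", n_col),
                            rep("random", n_red - n_col))),
        discard_candidate = unname(
          slice_counts[c(ids_g, ids_r)] < 2 |
            is.na(slice_counts[c(ids_g, ids_r)])),
        stringsAsFactors = FALSE)
      geom[[ci]] <- data.frame(
        cell = cell,
        nucleus_volume = 4 / 3 * pi * nucleus_radius^3,
        green_occupied_volume = sphere_union_volume(gc, rep(green_radius,
                                                            n_green)),
        stringsAsFactors = FALSE)
    }
    structure(list(puncta = as.data.frame(data.table::rbindlist(puncta)),
                   geometry = do.call(rbind, geom),
                   truth = do.call(rbind, truth),
                   params = list(n_cells = n_cells, n_red = n_red,
                                 coloc_fraction = coloc_fraction,
                                 z_spacing = z_spacing)),
              class = "puncta_field")
  })
}

# Union volume of spheres with pairwise-overlap correction (higher-order
# intersections ignored; adequate at the low volume fractions simulated).
sphere_union_volume <- function(centers, radii) {
  n <- nrow(centers)
  vol <- sum(4 / 3 * pi * radii^3)
  if (n < 2) return(vol)
  d <- as.matrix(dist(centers))
  iu <- which(upper.tri(d), arr.ind = TRUE)
  vol - sum(sphere_overlap_volume(d[iu], radii[iu[, 1]], radii[iu[, 2]]))
}

# Lens volume of two intersecting spheres at center distance d (vectorized).
sphere_overlap_volume <- function(d, r1, r2) {
  lens <- pi * (r1 + r2 - d)^2 *
    (d^2 + 2 * d * (r1 + r2) - 3 * (r1 - r2)^2) / (12 * d)
  out <- ifelse(d >= r1 + r2, 0,
                ifelse(d <= abs(r1 - r2), 4 / 3 * pi * pmin(r1, r2)^3, lens))
  out[d == 0] <- (4 / 3 * pi * pmin(r1, r2)^3)[d == 0]
  out
}
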