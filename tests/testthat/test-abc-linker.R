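toy_tss <- data.frame(gene = c("G1", "G2"), chrom = "chr1",
                      pos = c(10000, 80000))

test_that("TSS-loop selection honors the 5 kb midpoint window", {
  mk_loop <- function(mid_a, mid_b, freq = 1)
    data.frame(chrom_a = "chr1", start_a = mid_a - 100, end_a = mid_a + 100,
               chrom_b = "chr1", start_b = mid_b - 100, end_b = mid_b + 100,
               frequency = freq)
  loops <- rbind(mk_loop(10000 + 4999, 40000),   # inside window
                 mk_loop(10000 + 5001, 42000),   # outside
                 mk_loop(10000, 80000))          # near both genes' TSSs
  out <- select_tss_loops(loops, toy_tss, window = 5000)
  expect_true("L00001" %in% out$loop_id)
  expect_false("L00002" %in% out$loop_id)
  expect_equal(attr(out, "n_dropped"), 1)
  # loop near two TSSs yields one candidate per gene
  both <- out[out$loop_id == "L00003", ]
  expect_setequal(both$gene, c("G1", "G2"))
})

test_that("activity aggregation equals a brute-force window sum", {
  # uniform 1/bp track: flank 2500 -> activity 5000
  uni <- data.frame(chrom = "chr1", start = 0, end = 1e6, value = 1)
  cand <- data.frame(loop_id = "L1", gene = "G1", tss = 10000,
                     chrom = "chr1", distal_start = 39000, distal_end = 41000,
                     distal_mid = 40000, frequency = 2,
                     tss_anchor_mid = 10000)
  got <- aggregate_activity(cand, uni, uni, flank = 2500)
  expect_equal(got$h3k27ac, 5000)
  expect_equal(got$abc_score, 2 * 5000)
  # empty track -> 0
  empty <- uni[0, ]
  expect_equal(aggregate_activity(cand, empty, empty)$h3k27ac, 0)
  # ragged synthetic track matches independent per-bp re-summation
  set.seed(7)
  st <- sort(sample(35000:45000, 20))
  trk <- data.frame(chrom = "chr1", start = st,
                    end = st + sample(100:800, 20, replace = TRUE),
                    value = runif(20, 0, 3))
  got2 <- aggregate_activity(cand, trk, uni, flank = 2500)
  expect_equal(got2$h3k27ac, oracle_window_sum(trk, 40000, 2500),
               tolerance = 1e-9)
})

test_that("ABC score arithmetic and input validation", {
  expect_identical(score_abc(4, 9, 4), 24)
  expect_equal(score_abc(3, 0, 7), 0)
  a <- c(0.3, 2, 17)
  expect_equal(score_abc(1, a, a), a)        # geometric-mean identity
  expect_error(score_abc(-1, 1, 1), "non-negative")
})

test_that("trimming applies TSS-TSS, blacklist and strict-percentile rules", {
  set.seed(8)
  n <- 100
  cands <- data.frame(
    loop_id = sprintf("L%03d", 1:n), gene = "G1", tss = 10000,
    chrom = "chr1",
    distal_start = seq(30000, by = 2000, length.out = n),
    distal_end = seq(31000, by = 2000, length.out = n),
    frequency = 1, tss_anchor_mid = 10000)
  cands$distal_mid <- (cands$distal_start + cands$distal_end) / 2
  cands$h3k27ac <- 1; cands$atac <- 1
  cands$abc_score <- sample(1:n)              # distinct scores
  no_bl <- data.frame(chrom = character(), start = integer(),
                      end = integer())
  tss_far <- toy_tss[1, , drop = FALSE]       # no distal anchor near a TSS
  out <- trim_candidates(cands, tss_far, no_bl, percentile = 89)
  expect_equal(nrow(out), 11)
  expect_setequal(out$abc_score,
                  oracle_percentile_survivors(cands$abc_score, 89))
  # candidate exactly at the threshold is kept ("below" is strict)
  expect_setequal(out$abc_score, 90:100)
  expect_true(90 %in% out$abc_score)
  # TSS-TSS rule: distal midpoint 3 kb from a TSS is removed
  tt <- cands[1, ]; tt$distal_start <- 12000; tt$distal_end <- 14000
  tt$distal_mid <- 13000
  out2 <- trim_candidates(rbind(tt, cands[2:10, ]), toy_tss, no_bl,
                          percentile = 10)
  expect_false(tt$loop_id %in% out2$loop_id ||
                 13000 %in% out2$distal_mid)
  # blacklist overlap removes the candidate
  bl <- data.frame(chrom = "chr1", start = 30000, end = 30500)
  out3 <- trim_candidates(cands, tss_far, bl, percentile = 1)
  expect_false(any(out3$distal_start == 30000))
  expect_error(trim_candidates(cands, toy_tss, no_bl, percentile = 0),
               "percentile")
})

test_that("stitching merges adjacent regions and is permutation-invariant", {
  cands <- data.frame(
    loop_id = c("a", "b", "c"), gene = c("G1", "G1", "G2"), tss = 1,
    chrom = "chr1", distal_start = c(100, 500, 5000),
    distal_end = c(600, 1000, 6000), distal_mid = c(350, 750, 5500),
    frequency = 1, abc_score = 1, tss_anchor_mid = 1)
  st <- stitch_regions(cands)
  expect_equal(nrow(st$regions), 2)
  expect_equal(st$regions$start[1], 100)
  expect_equal(st$regions$end[1], 1000)
  expect_equal(st$regions$n_members[1], 2L)
  # disjoint by more than gap stays separate; bookended merges at gap 0
  book <- cands; book$distal_start <- c(0, 500, 5000)
  book$distal_end <- c(500, 900, 6000)
  expect_equal(nrow(stitch_regions(book)$regions), 2)
  # permutation invariance
  for (perm in list(c(2, 1, 3), c(3, 2, 1))) {
    stp <- stitch_regions(cands[perm, ])
    expect_equal(stp$regions, st$regions)
    expect_setequal(paste(stp$links$region_id, stp$links$gene),
                    paste(st$links$region_id, st$links$gene))
  }
})

test_that("quantification normalizes to sum 1 and the r > 0.3 rule is strict", {
  loc <- sim_regulatory_locus(n_genes = 4, n_true = 4, n_decoy = 10,
                              seed = 11)
  cands <- select_tss_loops(loc$loops, loc$tss)
  ph <- data.frame(chrom = loc$pooled_track$chrom,
                   start = loc$pooled_track$start,
                   end = loc$pooled_track$end,
                   value = loc$pooled_track$h3k27ac)
  pa <- ph; pa$value <- loc$pooled_track$atac
  cands <- aggregate_activity(cands, ph, pa)
  st <- stitch_regions(cands)
  qc <- quantify_and_correlate(st, loc$tracks, loc$expr, loc$cohorts)
  expect_equal(unname(colSums(qc$signal)), rep(1, ncol(qc$signal)),
               tolerance = 1e-9)
  expect_true(all(c("r_cohort1", "r_cohort2") %in% names(qc$associations)))
  rmax <- pmax(qc$associations$r_cohort1, qc$associations$r_cohort2,
               na.rm = TRUE)
  expect_true(all(rmax > 0.3))
  # normalized signal identical to expression -> r = 1, kept; a second
  # region absorbs the complement so each sample total is constant
  sig_regions <- list(regions = data.frame(region_id = c("R1", "R2"),
                                           chrom = "chrX",
                                           start = c(0, 1000),
                                           end = c(100, 1100),
                                           n_members = 1L),
                      links = data.frame(region_id = c("R1", "R2"),
                                         gene = c("g", "h"),
                                         loop_id = c("l1", "l2"),
                                         frequency = 1, abc_score = 1))
  samples <- paste0("s", 1:6)
  expr <- rbind(g = 1:6, h = c(3, 1, 4, 1, 5, 9))
  colnames(expr) <- samples
  trks <- rbind(
    data.frame(chrom = "chrX", start = 0, end = 100, sample = samples,
               value = 1:6),
    data.frame(chrom = "chrX", start = 1000, end = 1100, sample = samples,
               value = 10 - (1:6)))
  qc2 <- quantify_and_correlate(sig_regions, trks, expr,
                                setNames(rep("c1", 6), samples))
  expect_equal(qc2$associations$r_cohort1[qc2$associations$gene == "g"], 1)
  # r exactly equal to the threshold is dropped (strict >)
  set.seed(30)
  x <- (1:6) / 10                              # normalized R1 signal
  zx <- (x - mean(x)) / sd(x)
  e <- residuals(lm(rnorm(6) ~ zx))
  y <- 0.3 * zx + sqrt(1 - 0.09) * e / sd(e)   # cor(x, y) = 0.3 by design
  expr2 <- rbind(g = y)
  colnames(expr2) <- samples
  r_exact <- cor(x, y)
  expect_equal(r_exact, 0.3, tolerance = 1e-12)
  qc3 <- quantify_and_correlate(
    list(regions = sig_regions$regions,
         links = sig_regions$links[1, , drop = FALSE]),
    trks, expr2, setNames(rep("c1", 6), samples), r_min = r_exact)
  expect_equal(nrow(qc3$associations), 0)
})

test_that("proximity merge is a keyed set union", {
  abc <- data.frame(region_id = c("R1", "R2", "R3"),
                    gene = c("A", "B", "C"), source = "abc")
  prox <- data.frame(region_id = c("R3", "R4", "R5", "R6"),
                     gene = c("C", "D", "E", "F"))
  out <- merge_with_proximity(abc, prox)
  expect_equal(nrow(out), 6)
  expect_equal(out$source[out$region_id == "R3"], "both")
  # disjoint lists of sizes 3 and 4 -> 7
  prox4 <- data.frame(region_id = c("R4", "R5", "R6", "R7"),
                      gene = c("D", "E", "F", "G"))
  out2 <- merge_with_proximity(abc, prox4)
  expect_equal(nrow(out2), 7)
  # empty abc -> proximity passthrough
  out3 <- merge_with_proximity(abc[0, ], prox)
  expect_equal(nrow(out3), 4)
  expect_true(all(out3$source == "proximity"))
})

test_that("end-to-end ABC pipeline only removes candidates stage by stage", {
  loc <- sim_regulatory_locus(seed = 13)
  ph <- data.frame(chrom = loc$pooled_track$chrom,
                   start = loc$pooled_track$start,
                   end = loc$pooled_track$end,
                   value = loc$pooled_track$h3k27ac)
  pa <- ph; pa$value <- loc$pooled_track$atac
  res <- run_abc(loc$loops, loc$tss, loc$blacklist, ph, pa, loc$tracks,
                 loc$expr, loc$cohorts)
  cnt <- res$counts
  expect_true(all(diff(cnt[c("candidates", "tss_tss", "blacklist",
                             "score")]) <= 0))
  expect_lte(cnt[["associations"]], cnt[["score"]] + 0)
})
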