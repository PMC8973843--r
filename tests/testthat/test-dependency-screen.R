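test_that("fit_normlrt rejects degenerate input and matches the independent oracle", {
  expect_error(fit_normlrt(rep(0.3, 100)), "constant")
  expect_error(fit_normlrt(rnorm(10)), ">= 20")
  set.seed(1)
  x <- rnorm(769, 0, 0.15)
  rec <- fit_normlrt(x)
  expect_lt(rec$normlrt, 10)
  expect_equal(rec$normlrt, oracle_normlrt(x), tolerance = 1)
  # left-skew mixture: strong signal, left_skewed flag set
  set.seed(2)
  k <- rbinom(1, 769, 0.04)
  y <- c(rnorm(769 - k, 0, 0.15), rnorm(k, -1.2, 0.1))
  recm <- fit_normlrt(y)
  expect_gte(recm$normlrt, 100)
  expect_true(recm$left_skewed)
  expect_true(recm$mean_effect < recm$median_effect)
  expect_equal(recm$normlrt, oracle_normlrt(y), tolerance = 0.02 * recm$normlrt)
})

test_that("common-essential caller follows the 90th-percentile rank-histogram rule", {
  ge <- sim_gene_effect(seed = 5)
  ce <- call_common_essential(ge)
  planted <- ge$truth$gene[ge$truth$planted_class == "common_essential"]
  expect_setequal(ce, planted)
  # uniformly mid-ranked genes are not in the set
  nulls <- ge$truth$gene[ge$truth$planted_class == "null_gene"]
  expect_length(intersect(ce, nulls), 0)
  # degenerate matrix errors
  flat <- ge
  flat$effect[] <- 0.5
  expect_error(call_common_essential(flat))
  # explicit cutoff override
  ce2 <- call_common_essential(ge, cutoff = attr(ce, "cutoff"))
  expect_setequal(ce2, ce)
})

test_that("group enrichment agrees with closed-form t-tests and controls nulls", {
  set.seed(7)
  n_in <- 20; n_out <- 700
  eff <- rbind(
    planted = c(rnorm(n_in, -1, 0.1), rnorm(n_out, 0, 0.1)),
    matrix(rnorm(999 * (n_in + n_out), 0, 0.1), nrow = 999,
           dimnames = list(paste0("null", 1:999), NULL)))
  colnames(eff) <- paste0("c", seq_len(n_in + n_out))
  m <- gene_effect_matrix(eff, matrix(0.5, nrow(eff), ncol(eff),
                                      dimnames = dimnames(eff)),
                          data.frame(sample = colnames(eff),
                                     lineage = "x", subtype = FALSE))
  res <- test_group_enrichment(m, colnames(eff)[seq_len(n_in)])
  planted <- res[res$gene == "planted", ]
  expect_lt(planted$q, 0.05)
  expect_lt(planted$effect_size, 0)
  expect_true(planted$enriched)
  # moderated call agrees with the closed-form two-sample t oracle
  tt <- t.test(eff["planted", seq_len(n_in)], eff["planted", -seq_len(n_in)],
               var.equal = TRUE)
  expect_equal(planted$effect_size, unname(diff(rev(tt$estimate))),
               tolerance = 1e-10)
  expect_lt(tt$p.value, 0.05)
  # null genes: essentially no q < 0.05 and effect sizes centered at 0
  nulls <- res[res$gene != "planted", ]
  expect_lt(mean(nulls$q < 0.05), 0.005)
  expect_lt(abs(mean(nulls$effect_size)), 0.01)
  # BH monotonicity: q non-decreasing in p rank
  ord <- order(res$p_two)
  expect_true(all(diff(res$q[ord]) >= -1e-12))
  # one-sided p consistency for the symmetric moderated t
  expect_equal(res$p_left + res$p_right, rep(1, nrow(res)), tolerance = 1e-9)
  expect_error(test_group_enrichment(m, character(0)), ">= 2")
})

test_that("single-gene BH gives q equal to the two-sided p", {
  set.seed(8)
  eff <- matrix(rnorm(24), 1, dimnames = list("g1", paste0("s", 1:24)))
  m <- gene_effect_matrix(eff, (eff < -0.5) * 1,
                          data.frame(sample = colnames(eff), lineage = "x",
                                     subtype = FALSE))
  res <- test_group_enrichment(m, paste0("s", 1:6))
  expect_equal(res$q, res$p_two)
})

test_that("call_selective applies the three printed criteria exactly", {
  genes <- c("gA", "gB", "gC", "gD")
  prob <- matrix(0.01, 4, 10, dimnames = list(genes, paste0("s", 1:10)))
  prob["gA", 1:3] <- 0.9   # 3 dependent in-group lines
  prob["gB", 1:2] <- 0.9   # only 2
  prob["gC", 1:5] <- 0.9   # common essential, otherwise qualifying
  prob["gD", 1:4] <- 0.9   # skewed but not enriched
  eff <- -prob
  m <- gene_effect_matrix(eff, prob,
                          data.frame(sample = colnames(prob), lineage = "x",
                                     subtype = FALSE))
  in_group <- paste0("s", 1:5)
  enr <- data.frame(gene = genes, enriched = c(TRUE, TRUE, TRUE, FALSE))
  nlr <- data.frame(gene = genes, normlrt = c(5, 5, 500, 500),
                    left_skewed = c(FALSE, FALSE, TRUE, TRUE))
  calls <- call_selective(m, in_group, enr, nlr, common_essential = "gC")
  expect_equal(calls$selected, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(calls$n_dependent_ingroup, c(3L, 2L, 5L, 4L))
  expect_true(calls$is_skewed[4])
  # selected matches the brute-force rule application
  expect_equal(calls$selected,
               unname(oracle_selective(prob, in_group, enr$enriched,
                                       nlr$normlrt >= 100 & nlr$left_skewed,
                                       "gC")))
  expect_error(call_selective(m, in_group, enr[-1, ], nlr, "gC"), "missing")
})

test_that("differential dependency matches the closed-form Welch test", {
  set.seed(10)
  n1 <- 6; n2 <- 14
  eff <- rbind(hit = c(rnorm(n1, -1, 0.15), rnorm(n2, 0, 0.15)),
               null = rnorm(n1 + n2, 0, 0.15))
  colnames(eff) <- paste0("s", seq_len(n1 + n2))
  m <- gene_effect_matrix(eff, plogis((-0.5 - eff) / 0.1),
                          data.frame(sample = colnames(eff), lineage = "x",
                                     subtype = rep(c(TRUE, FALSE),
                                                   c(n1, n2))))
  dd <- differential_dependency(m)
  hit <- dd[dd$gene == "hit", ]
  expect_equal(hit$delta, -1, tolerance = 0.25)
  expect_lt(hit$p, 0.05)
  wt <- t.test(eff["hit", 1:n1], eff["hit", -(1:n1)])
  expect_equal(hit$p, wt$p.value, tolerance = 1e-12)
  # identical groups -> delta 0
  same <- matrix(rep(eff["null", ], 2), 2, byrow = TRUE,
                 dimnames = list(c("a", "b"), colnames(eff)))
  m2 <- gene_effect_matrix(same, plogis((-0.5 - same) / 0.1),
                           m$annotations)
  expect_equal(differential_dependency(m2, rep(c(TRUE, FALSE),
                                               c(10, 10)))$delta[1],
               mean(same[1, 1:10]) - mean(same[1, 11:20]))
  # missing values are dropped, computation on available values
  eff_na <- eff; eff_na["hit", 1] <- NA
  m3 <- gene_effect_matrix(eff_na, plogis((-0.5 - eff_na) / 0.1),
                           m$annotations)
  dd3 <- differential_dependency(m3)
  expect_equal(dd3$delta[dd3$gene == "hit"],
               mean(eff["hit", 2:n1]) - mean(eff["hit", -(1:n1)]))
  # one-member group -> p flagged unavailable
  dd4 <- differential_dependency(m, c(TRUE, rep(FALSE, n1 + n2 - 1)))
  expect_true(all(is.na(dd4$p)))
  expect_true(all(dd4$flag == "group_too_small"))
})
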