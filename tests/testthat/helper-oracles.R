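# Independent oracles used to freeze expected values.  These deliberately
# avoid the package's own code paths: a different optimizer and
# parameterization for the skew-t fit, plain arithmetic for percentiles and
# window sums, and literal rule application for the selectivity call.

# Skew-t log-density written out independently of crcminer::dskewt.
oracle_skewt_logd <- function(x, xi, omega, alpha, nu) {
  z <- (x - xi) / omega
  log(2) - log(omega) + stats::dt(z, nu, log = TRUE) +
    stats::pt(alpha * z * sqrt((nu + 1) / (nu + z^2)), nu + 1, log.p = TRUE)
}

# Independent ML fit: nlminb over (xi, omega, alpha, log nu) from a grid of
# starting points.  Returns the maximized log-likelihood.
oracle_skewt_loglik <- function(x) {
  nll <- function(p) {
    if (p[2] <= 0) return(1e10)
    nu <- exp(p[4])
    if (nu < 2.5 || nu > 100) return(1e10)
    v <- -sum(oracle_skewt_logd(x, p[1], p[2], p[3], nu))
    if (!is.finite(v)) 1e10 else v
  }
  s <- sd(x)
  grid <- expand.grid(alpha = c(-8, -2, 0, 2, 8), lnu = log(c(3, 10, 60)))
  best <- Inf
  for (i in seq_len(nrow(grid))) {
    fit <- tryCatch(
      stats::nlminb(c(median(x), s, grid$alpha[i], grid$lnu[i]), nll),
      error = function(e) NULL)
    if (!is.null(fit) && fit$objective < best) best <- fit$objective
  }
  -best
}

oracle_normal_loglik <- function(x) {
  m <- mean(x); s <- sqrt(mean((x - m)^2))
  sum(stats::dnorm(x, m, s, log = TRUE))
}

oracle_normlrt <- function(x) 2 * (oracle_skewt_loglik(x) -
                                     oracle_normal_loglik(x))

# Literal application of the three selectivity criteria.
oracle_selective <- function(prob, in_group, enriched, skewed,
                             common_essential) {
  n_dep <- rowSums(prob[, in_group, drop = FALSE] > 0.5)
  n_dep >= 3 & !(rownames(prob) %in% common_essential) & (enriched | skewed)
}

# Survivors of trimming scores strictly below the p-th percentile, where the
# threshold is the smallest score with at least floor(p*n/100) scores below
# it (nearest-rank, "below" strict).
oracle_percentile_survivors <- function(scores, p) {
  k <- floor(p * length(scores) / 100)
  thr <- sort(scores)[k + 1]
  scores[scores >= thr]
}

# Brute-force per-bp window sum of a piecewise-constant density track.
oracle_window_sum <- function(track, mid, flank) {
  bp <- seq(floor(mid - flank), ceiling(mid + flank) - 1)
  val <- numeric(length(bp))
  for (i in seq_len(nrow(track))) {
    sel <- bp >= track$start[i] & bp < track$end[i]
    val[sel] <- val[sel] + track$value[i]
  }
  sum(val[bp >= mid - flank & bp < mid + flank])
}

# Hypergeometric (Fisher) p for the pooled colocalization table.
oracle_fisher_p <- function(observed, n_red, expected_int) {
  stats::fisher.test(matrix(c(observed, expected_int,
                              n_red - observed, n_red - expected_int),
                            2, 2))$p.value
}

# Adjusted Rand index between two labelings.
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  (sij - si * sj / n2) / ((si + sj) / 2 - si * sj / n2)
}
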