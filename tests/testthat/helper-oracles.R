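# Independent brute-force oracles, deliberately written from first principles
# (no calls into the code paths they check).

# Fine-grained scan of the forward TEP model: returns the volume interval
# whose |TEP| <= half_width, at `step` resolution.
oracle_band_scan <- function(cath, eso, p_box, half_width = 1,
                             step = 0.01, v_max = 10) {
  v <- seq(0, v_max, by = step)
  tep <- tep_model(v, p_box, cath, eso)
  ok <- abs(tep) <= half_width + 1e-12
  if (!any(ok)) return(c(NA_real_, NA_real_))
  c(min(v[ok]), max(v[ok]))
}

# Exhaustive hinge-model breakpoint search on a 0.01-mL grid: flat level m up
# to b, line m + s * (v - b) after, m and s by least squares.
oracle_hinge_breakpoint <- function(v, p, grid_step = 0.01) {
  candidates <- seq(0, v[length(v) - 2L], by = grid_step)
  best_b <- NA_real_
  best_rss <- Inf
  for (b in candidates) {
    X <- cbind(1, pmax(0, v - b))
    beta <- qr.solve(X, p)
    rss <- sum((p - X %*% beta)^2)
    if (rss < best_rss - 1e-12) { best_rss <- rss; best_b <- b }
  }
  best_b
}

# Kruskal-Wallis H from the definition (tie-free case), independent of
# stats::kruskal.test: average-rank form with no correction factor.
oracle_kw_H <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  r <- rank(x)
  N <- length(x)
  rbar <- tapply(r, g, mean)
  n <- as.vector(table(g))
  (12 / (N * (N + 1))) * sum(n * (rbar - (N + 1) / 2)^2)
}

# Two-sided Fisher exact p for a 2x2 table by full hypergeometric
# enumeration over all tables with the observed margins.
oracle_fisher_2x2 <- function(tab) {
  m <- sum(tab[1, ])   # row-1 total
  n <- sum(tab[2, ])   # row-2 total
  k <- sum(tab[, 1])   # column-1 total
  a_obs <- tab[1, 1]
  a_all <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(a_all, m, n, k)
  p_obs <- stats::dhyper(a_obs, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
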