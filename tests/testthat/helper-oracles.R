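# Independent oracles used across the suite.

# Quadrature of the implementation's density (oracle for CDF/mean checks).
quad_cdf <- function(dist, tau, rel.tol = 1e-10) {
  stats::integrate(function(t) wt_pdf(dist, t), 0, tau,
                   rel.tol = rel.tol)$value
}

quad_mean <- function(dist, rel.tol = 1e-10) {
  stats::integrate(function(t) t * wt_pdf(dist, t), 0, Inf,
                   rel.tol = rel.tol)$value
}

# Grid-scan root isolation: tabulate F and return the first sign change of
# F - r. Independent of the bisection code path. A coarse scan locates the
# bracketing cell; the fine scan at 'step' runs only inside that cell, so
# the tabulation stays memory-bounded.
grid_scan_inverse <- function(dist, r, tau_max, step) {
  coarse <- seq(0, tau_max, length.out = 10001L)
  Fc <- wt_cdf(dist, coarse)
  j <- which(Fc[-1] >= r & Fc[-length(Fc)] < r)[1]
  stopifnot(!is.na(j))
  grid <- seq(coarse[j], coarse[j + 1], by = step)
  F <- wt_cdf(dist, grid)
  i <- which(F[-1] >= r & F[-length(F)] < r)[1]
  stopifnot(!is.na(i))
  (grid[i] + grid[i + 1]) / 2
}

# One-sample Kolmogorov-Smirnov statistic against an analytic CDF.
ks_stat <- function(samples, dist) {
  n <- length(samples)
  F <- wt_cdf(dist, sort(samples))
  max(pmax(abs(F - (seq_len(n) - 1) / n), abs(F - seq_len(n) / n)))
}

# Asymptotic KS critical value at significance alpha.
ks_crit <- function(n, alpha = 0.01) {
  sqrt(-log(alpha / 2) / (2 * n))
}

# The six printed kinetic fixture sets, with a substrate concentration for
# the B sets (micromolar units).
all_fixture_sets <- function(S_B = 10) {
  list(A1 = mm_fixture("A1"), A2 = mm_fixture("A2"), A3 = mm_fixture("A3"),
       B1 = mm_fixture("B1", S = S_B), B2 = mm_fixture("B2", S = S_B),
       B3 = mm_fixture("B3", S = S_B))
}
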