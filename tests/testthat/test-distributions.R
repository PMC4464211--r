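test_that("single-molecule MM parameter derivation matches hand arithmetic", {
  d <- dist_mm(k1 = 1e7, k2 = 250, k_minus1 = 0, S = 5e-6)
  # B = -(k1 S + k-1 + k2)/2 = -150; A = sqrt(B^2 - k1 k2 S) = sqrt(10000)
  expect_equal(d$A, 100)
  expect_equal(d$B, -150)
  expect_equal(d$alpha, 62.5)   # k1 k2 S / (2A)
  expect_equal(d$beta, -50)     # A + B
  expect_equal(d$gamma, -250)   # B - A

  # set A3: high dissociation; derived invariants must still hold
  d3 <- dist_mm(1e7, 250, 2000, 5e-6)
  expect_gt(d3$A, 0)
  expect_lt(d3$A, abs(d3$B))
  expect_lt(d3$B, 0)
  expect_lt(d3$beta, 0)
  expect_lt(d3$gamma, 0)
  expect_gt(d3$beta, d3$gamma)
})

test_that("degenerate and invalid MM parameters are rejected distinctly", {
  # k_minus1 = 0, k1 S = k2: A = 0 double root
  expect_error(dist_mm(1, 1, 0, 1), "degenerate")
  # a nearby set with k1 S != k2 is valid (B^2 - k1 k2 S = 2.25 > 0)
  expect_silent(dist_mm(1, 1, 0, 4))
  # plain positivity violations are a different error
  expect_error(dist_mm(-1, 1, 0, 4), "k1")
  expect_error(dist_mm(1, 0, 0, 4), "k2")
  expect_error(dist_mm(1, 1, -0.5, 4), "k_minus1")
  expect_error(dist_mm(1, 1, 0, 0), "'S'")
})

test_that("densities evaluate to the closed forms", {
  a1 <- mm_fixture("A1")
  expect_equal(wt_pdf(a1, 0), 0)  # the two exponentials cancel at tau = 0
  expect_equal(wt_pdf(a1, 0.01), 62.5 * (exp(-0.5) - exp(-2.5)),
               tolerance = 1e-12)
  expect_equal(wt_pdf(dist_exponential(0.0078), 0), 0.0078)
  er <- dist_erlang(2, 0.0078)
  expect_equal(wt_pdf(er, 100), 0.0078^2 * 100 * exp(-0.78),
               tolerance = 1e-12)
  hy <- dist_hyperexp(c(0.3, 0.7), c(1, 5))
  expect_equal(wt_pdf(hy, 0.2), 0.3 * exp(-0.2) + 0.7 * 5 * exp(-1),
               tolerance = 1e-12)
})

test_that("negative tau errors by default and is 0 in lenient mode", {
  a1 <- mm_fixture("A1")
  expect_error(wt_pdf(a1, -0.1), "negative")
  expect_error(wt_cdf(a1, -0.1), "negative")
  expect_equal(wt_pdf(a1, c(-1, 0.01), lenient = TRUE)[1], 0)
  expect_equal(wt_cdf(a1, -1, lenient = TRUE), 0)
})

test_that("CDFs start at 0, reach 1, and match the quadrature oracle", {
  fams <- list(mm_fixture("A1"), dist_exponential(0.0078),
               dist_erlang(2, 0.0078), dist_hyperexp(c(0.3, 0.7), c(1, 5)))
  for (d in fams) {
    expect_equal(wt_cdf(d, 0), 0)
    expect_equal(wt_cdf(d, 40 * wt_mean(d)), 1, tolerance = 1e-6)
  }
  a1 <- mm_fixture("A1")
  # closed form vs adaptive quadrature of the density, frozen oracle value
  expect_equal(wt_cdf(a1, 0.024), 0.624126923154, tolerance = 1e-9)
  expect_equal(wt_cdf(a1, 0.024), quad_cdf(a1, 0.024), tolerance = 1e-9)
  # tail normalisation: deviation ~ alpha e^{beta tau}/|beta|
  expect_equal(wt_cdf(a1, 10 / abs(a1$beta)), 1, tolerance = 1e-4)
  expect_equal(wt_cdf(a1, 20 / abs(a1$beta)), 1, tolerance = 1e-6)
})

test_that("CDF is strictly increasing and consistent with the density", {
  for (d in list(mm_fixture("A2"), dist_hyperexp(c(0.5, 0.5), c(0.5, 3)))) {
    taus <- seq(0.05, 4, length.out = 20) * wt_mean(d)
    expect_true(all(diff(wt_cdf(d, taus)) > 0))
    h <- 1e-6 * wt_mean(d)
    deriv <- (wt_cdf(d, taus + h) - wt_cdf(d, taus - h)) / (2 * h)
    expect_equal(deriv, wt_pdf(d, taus), tolerance = 1e-4)
  }
})

test_that("densities integrate to one for fixtures and random sets", {
  for (d in all_fixture_sets())
    expect_equal(stats::integrate(function(t) wt_pdf(d, t), 0, Inf,
                                  rel.tol = 1e-9)$value, 1,
                 tolerance = 1e-6)
  set.seed(7)
  for (i in 1:20) {
    d <- random_mm_params()
    expect_equal(stats::integrate(function(t) wt_pdf(d, t), 0, Inf,
                                  rel.tol = 1e-9)$value, 1,
                 tolerance = 1e-6)
  }
})

test_that("the mean turnover rate obeys the single-molecule MM equation", {
  a1 <- mm_fixture("A1")
  # K_M = 250/1e7 = 2.5e-5 M; rate = 250 * 5e-6 / 3e-5
  expect_equal(mm_mean_rate(a1), 250 * 5e-6 / 3e-5, tolerance = 1e-12)
  expect_equal(1 / quad_mean(a1), mm_mean_rate(a1), tolerance = 1e-6)
  # B1 at S = 0.001 uM
  b1 <- mm_fixture("B1", S = 0.001)
  expect_equal(mm_mean_rate(b1), 1920 * 0.001 / (0.001 + (2320 + 1920) / 41),
               tolerance = 1e-12)
  # saturation: rate approaches k2 as S grows
  expect_equal(mm_mean_rate(dist_mm(1e7, 250, 50, 1)), 250,
               tolerance = 1e-4)
})

test_that("analytic means match closed forms and quadrature", {
  expect_equal(wt_mean(dist_exponential(0.0078)), 1 / 0.0078)
  expect_equal(wt_mean(dist_erlang(2, 0.0078)), 2 / 0.0078)
  expect_equal(wt_mean(dist_hyperexp(1, 2)), 0.5)  # degenerate mixture
  for (d in list(mm_fixture("A3"), dist_erlang(3, 0.4),
                 dist_hyperexp(c(0.2, 0.8), c(0.3, 2))))
    expect_equal(wt_mean(d), quad_mean(d), tolerance = 1e-6)
})

test_that("MM family approaches an exponential of rate k2 at saturation", {
  # k_minus1 = 0, k1 S / k2 = 1e4: binding is instantaneous on the
  # catalytic time scale, so the waiting time is ~ Exp(k2)
  d <- dist_mm(k1 = 1e7, k2 = 250, k_minus1 = 0, S = 0.25)
  ref <- dist_exponential(250)
  taus <- seq(0, 6, length.out = 50) * wt_mean(ref)
  expect_lt(max(abs(wt_cdf(d, taus) - wt_cdf(ref, taus))), 1e-3)
})

test_that("hyperexponential parameter validation", {
  expect_error(dist_hyperexp(c(0.5, 0.4), c(1, 2)), "sum to 1")
  expect_error(dist_hyperexp(c(0.5, 0.5), c(1, -2)), "rates")
  expect_error(dist_hyperexp(c(1, -0.5, 0.5), c(1, 2, 3)), "weights")
  expect_error(dist_erlang(1.5, 1), "integer")
  expect_error(dist_exponential(0), "lam")
})
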