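test_that("analytic MLmS is half alpha2 times stiffness, with exact conservation", {
  expect_equal(siteValues(mlmsAnalytic(2, EnsembleParams(alpha2 = 1))), 1)

  ki <- siteStiffness(buildPfANM(collinearTrace()))
  mlms <- mlmsAnalytic(ki, EnsembleParams(alpha2 = 0.1))
  expect_equal(siteValues(mlms)[1], 0.05 * (1 / 3.8^2 + 1 / 7.6^2),
               tolerance = 1e-12)

  # z-normalized MLmS is invariant to the mutation-size parameter
  kiG <- siteStiffness(pfanmFixture(1))
  z1 <- znorm(siteValues(mlmsAnalytic(kiG, EnsembleParams(alpha2 = 0.01))))
  z2 <- znorm(siteValues(mlmsAnalytic(kiG, EnsembleParams(alpha2 = 100))))
  expect_equal(z1, z2, tolerance = 1e-12)
  # ... and to uniform rescaling of all force constants
  expect_equal(znorm(siteValues(kiG) * 7.3), znorm(siteValues(kiG)),
               tolerance = 1e-10)

  # conservation: total stress counts each spring's variance once per end
  k <- forceConstants(pfanmFixture(1))
  a2 <- 0.37
  tot <- sum(siteValues(mlmsAnalytic(siteStiffness(pfanmFixture(1)),
                                     EnsembleParams(alpha2 = a2))))
  expect_equal(tot, a2 * sum(k[upper.tri(k)]) * 2 / 2, tolerance = 1e-10)
})

test_that("sampled mutations agree between direct and potential-energy routes", {
  net <- pfanmFixture(1)
  mut <- sampleMutation(net, site = 7, seed = 42)
  expect_equal(mut$site, 7L)
  expect_equal(length(mut$deltas), length(mut$partners))
  expect_gte(mut$deltaV, 0)
  # the dual-route consistency check is internal to sampleMutation (1e-10
  # relative); drawing many mutations exercises it across sites
  for (s in c(1, 30, 60, 120)) {
    m <- sampleMutation(net, site = s, seed = s)
    expect_gte(m$deltaV, 0)
  }
  # determinism
  expect_identical(sampleMutation(net, 7, seed = 42)$deltas, mut$deltas)
  expect_error(sampleMutation(net, 0), "out of range")
})

test_that("Monte-Carlo MLmS reproduces the analytic identity within 4 SE", {
  params <- EnsembleParams(alpha2 = 1)
  for (s in 1:2) {
    net <- pfanmFixture(s)
    ki <- siteValues(siteStiffness(net))
    sites <- round(seq(1, 120, length.out = 5))
    for (site in sites) {
      mc <- mlmsMonteCarlo(net, site, params, nSamples = 10000, seed = 100 + site)
      expect_lt(abs(mc$estimate - 0.5 * ki[site]), 4 * mc$se)
    }
  }
})

test_that("Monte-Carlo MLmS scales with the perturbation variance and is seeded", {
  net <- pfanmFixture(1)
  m1 <- mlmsMonteCarlo(net, 10, EnsembleParams(alpha2 = 1), 5000, seed = 7)
  m4 <- mlmsMonteCarlo(net, 10, EnsembleParams(alpha2 = 4), 5000, seed = 7)
  expect_lt(abs(m4$estimate - 4 * m1$estimate), 4 * (m4$se + 4 * m1$se))
  expect_identical(mlmsMonteCarlo(net, 10, nSamples = 1000, seed = 3),
                   mlmsMonteCarlo(net, 10, nSamples = 1000, seed = 3))
  expect_error(mlmsMonteCarlo(net, 10, nSamples = 50), ">= 100")
})

test_that("MLmS depends only on the perturbation variance, not its shape", {
  net <- pfanmFixture(1)
  g <- mlmsMonteCarlo(net, 25, nSamples = 20000, seed = 5, dist = "gaussian")
  u <- mlmsMonteCarlo(net, 25, nSamples = 20000, seed = 5, dist = "uniform")
  expect_lt(abs(g$estimate - u$estimate), 4 * (g$se + u$se))
  ki <- siteValues(siteStiffness(net))[25]
  expect_lt(abs(u$estimate - 0.5 * ki), 4 * u$se)
})

test_that("linearized acceptance rate is an affine map of MLmS", {
  expect_equal(siteValues(acceptanceRateLinearized(0)), 1)
  mlms <- mlmsAnalytic(siteStiffness(pfanmFixture(1)))
  wBeta0 <- acceptanceRateLinearized(mlms, EnsembleParams(beta = 1e-12))
  expect_equal(siteValues(wBeta0), rep(1, 120), tolerance = 1e-9)
  w <- acceptanceRateLinearized(mlms, EnsembleParams(beta = 1))
  expect_equal(cor(znorm(siteValues(w)), znorm(siteValues(mlms))), -1,
               tolerance = 1e-12)
})

test_that("closed-form acceptance rate matches quadrature, MC, and Jensen bounds", {
  # one spring, k = 1, beta * alpha2 = 1: exact value 2^(-1/2), checked
  # against direct numerical integration of the Gaussian expectation
  net1 <- buildANM(twoSiteTrace(d = 3.8), rcut = 13)
  cf <- acceptanceRateClosedForm(net1, 1, EnsembleParams(beta = 1, alpha2 = 1))
  expect_equal(cf, 2^(-0.5), tolerance = 1e-12)
  quad <- integrate(function(d) exp(-0.5 * d^2) * dnorm(d), -Inf, Inf)$value
  expect_equal(cf, quad, tolerance = 1e-8)
  mc <- acceptanceRateMC(net1, 1, EnsembleParams(), nSamples = 100000, seed = 9)
  expect_lt(abs(mc$estimate - cf), 4 * mc$se)

  # globule: closed form vs MC for several sites, plus Jensen ordering
  net <- pfanmFixture(1)
  params <- EnsembleParams(beta = 1, alpha2 = 1)
  mlms <- siteValues(mlmsAnalytic(siteStiffness(net), params))
  sites <- round(seq(3, 117, length.out = 6))
  for (site in sites) {
    cfs <- acceptanceRateClosedForm(net, site, params)
    mcs <- acceptanceRateMC(net, site, params, nSamples = 10000, seed = 200 + site)
    expect_lt(abs(mcs$estimate - cfs), 4 * mcs$se)
    expect_gte(cfs, exp(-mlms[site]) - 1e-12)
    expect_gte(cfs, 1 - mlms[site] - 1e-12)
  }

  # beta -> 0 limit: (1 - closed form) / (beta MLmS) -> 1
  small <- EnsembleParams(beta = 1e-3 / max(forceConstants(net)), alpha2 = 1)
  site <- 50
  cfs <- acceptanceRateClosedForm(net, site, small)
  mlmsS <- siteValues(mlmsAnalytic(siteStiffness(net), small))[site] * small@beta
  expect_equal((1 - cfs) / mlmsS, 1, tolerance = 0.01)
})

test_that("beta = 0 limit of the exponential acceptance rate is exactly 1", {
  net <- pfanmFixture(1)
  mc <- acceptanceRateMC(net, 5, EnsembleParams(beta = 1e-300), 1000, seed = 1)
  expect_equal(mc$estimate, 1)
  expect_equal(mc$se, 0)
})
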