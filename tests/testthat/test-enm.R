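test_that("pfANM force constants follow the inverse-square rule", {
  net <- buildPfANM(twoSiteTrace(d = 2))
  expect_equal(forceConstants(net)[1, 2], 0.25)

  tri <- buildPfANM(triangleTrace(side = 1))
  k <- forceConstants(tri)
  expect_equal(k[upper.tri(k)], rep(1, 3))

  col <- buildPfANM(collinearTrace())
  k <- forceConstants(col)
  expect_equal(k[1, 2], 1 / 3.8^2)
  expect_equal(k[2, 3], 1 / 3.8^2)
  expect_equal(k[1, 3] / k[1, 2], 0.25)
})

test_that("ANM springs are unit within the inclusive cutoff and absent beyond", {
  tri <- buildANM(triangleTrace(side = 5), rcut = 13)
  expect_equal(forceConstants(tri)[upper.tri(diag(3))], rep(1, 3))
  atBoundary <- buildANM(twoSiteTrace(d = 13), rcut = 13)
  expect_equal(forceConstants(atBoundary)[1, 2], 1)
  beyond <- buildANM(twoSiteTrace(d = 14), rcut = 13)
  expect_equal(forceConstants(beyond)[1, 2], 0)
  expect_error(buildANM(twoSiteTrace(), rcut = -1), "positive")
})

test_that("site stiffness sums incident force constants", {
  ki <- siteValues(siteStiffness(buildPfANM(collinearTrace())))
  expect_equal(ki[1], 1 / 3.8^2 + 1 / 7.6^2, tolerance = 1e-12)
  expect_equal(ki[2], 2 / 3.8^2, tolerance = 1e-12)

  kTri <- siteValues(siteStiffness(buildANM(triangleTrace(side = 5), 13)))
  expect_equal(kTri, rep(2, 3))

  # double-counting identity on a nontrivial fixture
  net <- pfanmFixture(1)
  k <- forceConstants(net)
  expect_equal(sum(siteValues(siteStiffness(net))),
               2 * sum(k[upper.tri(k)]), tolerance = 1e-10)
})

test_that("potential energy is zero at equilibrium and matches single-spring algebra", {
  net <- pfanmFixture(2)
  expect_equal(potentialEnergy(net), 0)

  two <- buildANM(twoSiteTrace(d = 3.8), rcut = 13)
  two@kij[1, 2] <- two@kij[2, 1] <- 2
  stretched <- rbind(c(0, 0, 0), c(4.3, 0, 0))
  expect_equal(potentialEnergy(two, stretched), 0.5 * 2 * 0.25)
  expect_error(potentialEnergy(net, stretched), "matrix")
})

test_that("potential energy agrees with the Hessian quadratic form for small displacements", {
  net <- buildPfANM(helixFixture(30))
  H <- buildHessian(net)
  set.seed(11)
  for (rep in 1:5) {
    u <- rnorm(3 * 30)
    u <- 1e-3 * u / sqrt(sum(u^2))
    vQuad <- 0.5 * sum(u * (H %*% u))
    disp <- coords(net) + matrix(u, 30, 3, byrow = TRUE)
    expect_equal(potentialEnergy(net, disp), vQuad, tolerance = 1e-3)
  }
})

test_that("Hessian is symmetric and annihilates rigid-body motions", {
  for (net in list(pfanmFixture(1), buildANM(globuleFixture(1), 13))) {
    H <- buildHessian(net)
    expect_lt(max(abs(H - t(H))), 1e-12)
    modes <- rigidBodyModes(coords(net))
    expect_lt(max(abs(H %*% modes[, 1:3])), 1e-10)   # translations
    expect_lt(max(abs(H %*% modes[, 4:6])), 1e-8)    # rotations
  }
})

test_that("Hessian matches the central-difference second derivatives of the potential", {
  net <- buildPfANM(helixFixture(20))
  H <- buildHessian(net)
  Hnum <- numericalHessian(net, h = 1e-4)
  expect_lt(norm(H - Hnum, "F") / norm(H, "F"), 1e-5)
})

test_that("pseudo-inverse covariance has 6 zero modes and satisfies H C H = H", {
  H <- buildHessian(pfanmFixture(1))
  cv <- covarianceFromHessian(H)
  expect_equal(nZeroModes(cv), 6L)
  C <- covarianceMatrix(cv)
  expect_equal(C, t(C), tolerance = 1e-10)
  expect_gte(min(diag(C)), 0)
  expect_lt(norm(H %*% C %*% H - H, "F") / norm(H, "F"), 1e-6)
})

test_that("disconnected ANM networks are rejected with a zero-mode count", {
  sparse <- buildANM(globuleFixture(1), rcut = 4)
  expect_error(covarianceFromHessian(buildHessian(sparse)),
               "disconnected or degenerate")
})

test_that("two-site system matches the analytic eigen-decomposition", {
  k <- 1
  net <- buildANM(twoSiteTrace(d = 3.8), rcut = 13)
  H <- buildHessian(net)
  lam <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(lam > 1e-10), 1L)
  expect_equal(max(lam), 2 * k, tolerance = 1e-12)
  # collinear geometry: only 5 rigid modes exist
  cv <- covarianceFromHessian(H, expectedZeroModes = 5L)
  msf <- siteValues(msfFromCovariance(cv))
  expect_equal(msf, rep(1 / (4 * k), 2), tolerance = 1e-12)
})

test_that("MSF is positive, scales as 1/beta, and peaks at chain termini", {
  msf <- siteValues(msfFixture(1))
  expect_gt(min(msf), 0)

  net <- buildPfANM(helixFixture(50))
  cv <- covarianceFromHessian(buildHessian(net))
  m1 <- siteValues(msfFromCovariance(cv, EnsembleParams(beta = 1)))
  m2 <- siteValues(msfFromCovariance(cv, EnsembleParams(beta = 2)))
  expect_equal(m2, m1 / 2, tolerance = 1e-12)
  expect_equal(znorm(m1), znorm(m2), tolerance = 1e-10)
  expect_gt(m1[1], m1[25])
  expect_gt(m1[50], m1[25])
})

test_that("stiffness approximation tracks the exact MSF on compact globules", {
  for (s in 1:5) {
    net <- pfanmFixture(s)
    ki <- siteStiffness(net)
    approx <- msfApprox(ki)
    expect_equal(siteValues(approx), 3 / (2 * siteValues(ki)), tolerance = 1e-12)
    # z-scored approximation is exactly z(1/ki)
    expect_equal(znorm(siteValues(approx)), znorm(1 / siteValues(ki)),
                 tolerance = 1e-10)
    r <- cor(znorm(siteValues(msfFixture(s))), znorm(siteValues(approx)))
    expect_gt(r, 0.6)
  }
  expect_equal(siteValues(msfApprox(1.5)), 1.0)
  expect_error(msfApprox(c(1, 0)), "positive")
})
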