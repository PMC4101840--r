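test_that("OLS on z-scored variables recovers the correlation as slope, with the k=3 AIC", {
  set.seed(7)
  x <- znorm(rnorm(100))
  y <- znorm(0.5 * x + rnorm(100, 0, 0.2))
  fit <- fitLinear(y, x)
  expect_equal(fit$b, cor(x, y), tolerance = 1e-12)
  expect_equal(fit$a, 0, tolerance = 1e-10)
  expect_equal(fit$r, cor(x, y), tolerance = 1e-12)
  # Gaussian ML log-likelihood and AIC from first principles
  llRef <- -(fit$n / 2) * (log(2 * pi * fit$rss / fit$n) + 1)
  expect_equal(fit$loglik, llRef, tolerance = 1e-6)
  expect_equal(fit$aic, 2 * 3 - 2 * llRef, tolerance = 1e-6)
  # slope recovery: theoretical slope of re-z-scored y on x
  slopeTheory <- 0.5 / sqrt(0.5^2 + 0.2^2)
  se <- sqrt((1 - slopeTheory^2) / (fit$n - 2))
  expect_lt(abs(fit$b - slopeTheory), 3 * se)

  expect_error(fitLinear(x, x), "degenerate perfect fit")
  expect_error(fitLinear(y, x[1:50]), "length")
})

test_that("Akaike weights are normalized, tie-symmetric and monotone in AIC", {
  expect_equal(aicWeights(c(100, 100)), c(0.5, 0.5))
  w <- aicWeights(c(100, 102))
  expect_equal(w, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-10)
  expect_equal(round(w, 4), c(0.7311, 0.2689))
  expect_equal(aicWeights(c(0, 1000)), c(1, 0), tolerance = 1e-12)
  expect_error(aicWeights(c(1, Inf)), "finite")
  set.seed(8)
  aics <- rnorm(5, 100, 10)
  ww <- aicWeights(aics)
  expect_equal(sum(ww), 1, tolerance = 1e-12)
  expect_equal(order(aics), order(-ww))
})

test_that("Pearson and partial correlations match hand-evaluated cases", {
  expect_equal(pearsonCor(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearsonCor(c(1, 2, 3), c(3, 2, 1)), -1)
  set.seed(3)
  x <- rnorm(1000)
  expect_lt(abs(pearsonCor(x, sample(x))), 0.1)
  expect_error(pearsonCor(rep(1, 5), rnorm(5)), "zero variance")

  # first-order formula on synthetic correlations r_yx=.8, r_yz=.5, r_xz=.5
  expect_equal((0.8 - 0.5 * 0.5) / sqrt((1 - 0.25) * (1 - 0.25)),
               0.7333333, tolerance = 1e-6)
  set.seed(4)
  z <- rnorm(500); y <- rnorm(500); x <- rnorm(500)
  prFormula <- partialCorrelation(y, x, z)
  # independent oracle: correlation of the two regression residual vectors
  ry <- residuals(lm(y ~ z)); rx <- residuals(lm(x ~ z))
  expect_equal(prFormula, cor(ry, rx), tolerance = 1e-10)
  expect_error(partialCorrelation(y, x, x), "collinear")
  # z uncorrelated with both: partial reduces to the plain correlation
  zc <- rnorm(500)
  expect_lt(abs(partialCorrelation(y, x, zc) - cor(y, x)), 0.02)
})

test_that("equal-count binning follows the remainder and tie rules", {
  x <- seq_len(40); y <- -x
  prof <- binnedProfile(znorm(x), znorm(y), nBins = 20)
  expect_equal(prof$n, rep(2L, 20))
  expect_equal(prof$mean_y, -prof$mean_x, tolerance = 1e-12)
  expect_true(all(diff(prof$mean_x) > 0))

  prof41 <- binnedProfile(znorm(seq_len(41)), znorm(rnorm(41)), nBins = 20)
  expect_equal(prof41$n, c(3L, rep(2L, 19)))
  expect_error(binnedProfile(rnorm(10), rnorm(10), nBins = 20), "at least 20")
})

test_that("per-protein comparison finds the generating model", {
  study <- stressStudyFixture(1)
  res <- comparePerProtein(study$table, potential = "pfANM")
  s <- comparisonSummary(res)
  expect_equal(sum(s$n_best), 20L)
  nBestStress <- s$n_best[s$model == "stress"]
  expect_gte(nBestStress, 18L)
  per <- perProteinStats(res)
  expect_equal(per$waic_stress + per$waic_flex, rep(1, nrow(per)),
               tolerance = 1e-12)
  # stress correlations are negative (stressed sites evolve slowly)
  expect_lt(s$mean_r[s$model == "stress"], 0)
  expect_gt(s$mean_r[s$model == "flexibility"], 0)

  # symmetric simulation: rates generated from MSF favour the flexibility model
  flexStudy <- makeStressStudy(nProteins = 6, nSites = 120, noiseSD = 0.8,
                               seed = 101, generativeModel = "flexibility")
  resF <- comparePerProtein(flexStudy$table, potential = "pfANM")
  sF <- comparisonSummary(resF)
  expect_gt(sF$n_best[sF$model == "flexibility"],
            sF$n_best[sF$model == "stress"])
})

test_that("pooling a single protein reproduces its per-protein fit", {
  study <- stressStudyFixture(1)
  one <- study$table[study$table$pdb == study$table$pdb[1], ]
  per <- perProteinStats(comparePerProtein(one, "pfANM"))
  pool <- perProteinStats(comparePooled(one, "pfANM"))
  for (cc in c("aic_stress", "aic_flex", "r_stress", "r_flex",
               "pr_stress", "pr_flex"))
    expect_equal(pool[[cc]], per[[cc]], tolerance = 1e-10)
})

test_that("comparison validates its input schema", {
  study <- stressStudyFixture(1)
  broken <- study$table[, setdiff(names(study$table), "zmlms_anm")]
  expect_error(comparePerProtein(broken, "ANM"), "zmlms_anm")
  expect_error(comparePooled(broken, "ANM"), "zmlms_anm")
})

test_that("profile curvature test flags the reciprocal but not the linear relation", {
  study <- stressStudyFixture(1)
  tab <- study$table
  pMSF <- profileCurvatureTest(binnedProfile(tab$zmsf_pfanm, tab$zwr4s))
  pMLmS <- profileCurvatureTest(binnedProfile(tab$zmlms_pfanm, tab$zwr4s))
  expect_lt(pMSF, 0.01)
  expect_gt(pMLmS, 0.01)
})
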