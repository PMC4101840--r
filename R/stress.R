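#' Mean local mutational stress, analytic
#'
#' A mutation at a site is modelled as independent random perturbations of
#' the rest lengths of that site's springs, each with mean zero and
#' variance `alpha2`. Holding the mutant at the wild-type equilibrium
#' conformation, the expected stored elastic energy is exactly
#' `MLmS_i = 1/2 alpha2 ki` regardless of the perturbation distribution:
#' mutational stress is proportional to site stiffness and hence to local
#' packing density.
#'
#' @param ki a [SiteVector-class] (or numeric vector) of site stiffnesses.
#' @param params an [EnsembleParams-class]; only `alpha2` is used.
#' @return a raw [SiteVector-class] tagged `"MLmS"` (units of kT).
#' @examples
#' net <- buildPfANM(makeHelixTrace(20))
#' mlms <- mlmsAnalytic(siteStiffness(net))
#' @export
mlmsAnalytic <- function(ki, params = EnsembleParams()) {
  v <- .vals(ki)
  pid <- if (is(ki, "SiteVector")) ki@proteinId else "protein"
  SiteVector(0.5 * params@alpha2 * v, proteinId = pid, quantity = "MLmS",
             normalized = FALSE)
}

# draw the rest-length perturbations for one mutation: one delta per spring
# incident to the site, mean 0, variance alpha2
.drawDeltas <- function(nSprings, alpha2, dist = c("gaussian", "uniform")) {
  dist <- match.arg(dist)
  if (dist == "gaussian") stats::rnorm(nSprings, 0, sqrt(alpha2))
  else stats::runif(nSprings, -sqrt(3 * alpha2), sqrt(3 * alpha2))
}

#' Sample one random mutation at a site
#'
#' Draws a rest-length perturbation for every spring incident to `site`
#' and returns the energy penalty `deltaV` of holding the mutant at the
#' wild-type equilibrium conformation. `deltaV` is computed two ways that
#' must agree: directly as `1/2 sum_j kij deltaij^2` (the wild-type springs
#' are relaxed there, so each perturbed spring stores exactly its
#' rest-length offset), and by re-evaluating [potentialEnergy()] on a copy
#' of the network with the perturbed rest lengths. A discrepancy beyond
#' 1e-10 relative aborts, as a self-check of the energy bookkeeping.
#'
#' @param network a [SpringNetwork-class].
#' @param site site index (1..N).
#' @param params an [EnsembleParams-class].
#' @param seed optional integer seed (caller's RNG untouched when given).
#' @param dist perturbation distribution, `"gaussian"` (default) or
#'   `"uniform"`; both have mean 0 and variance `alpha2`.
#' @return a list with elements `site`, `partners` (indices of the
#'   perturbed springs' far ends), `deltas`, and `deltaV` (>= 0, kT).
#' @export
sampleMutation <- function(network, site, params = EnsembleParams(),
                           seed = NULL, dist = c("gaussian", "uniform")) {
  stopifnot(is(network, "SpringNetwork"))
  n <- nSites(network)
  site <- as.integer(site)
  if (is.na(site) || site < 1L || site > n) stop("site index out of range")
  dist <- match.arg(dist)
  partners <- which(network@kij[site, ] > 0)
  deltas <- .withSeed(seed, .drawDeltas(length(partners), params@alpha2, dist))
  kInc <- network@kij[site, partners]
  dvDirect <- 0.5 * sum(kInc * deltas^2)

  # independent route: perturb the rest lengths and re-evaluate the potential
  mutant <- network
  mutant@d0[site, partners] <- mutant@d0[site, partners] + deltas
  mutant@d0[partners, site] <- mutant@d0[site, partners]
  dvPotential <- potentialEnergy(mutant, coords(network))
  if (dvDirect > 0 && abs(dvDirect - dvPotential) / dvDirect > 1e-10)
    stop("internal inconsistency: direct and potential-energy mutation energies disagree")

  list(site = site, partners = partners, deltas = deltas, deltaV = dvDirect)
}

# vectorized deltaV for nSamples mutations at one site (direct route)
.sampleDeltaV <- function(network, site, params, nSamples, dist = "gaussian") {
  partners <- which(network@kij[site, ] > 0)
  m <- length(partners)
  if (m == 0L) return(rep(0, nSamples))
  kInc <- network@kij[site, partners]
  D <- matrix(.drawDeltas(m * nSamples, params@alpha2, dist), nrow = m)
  0.5 * colSums(kInc * D^2)
}

#' Monte-Carlo estimate of the mean local mutational stress
#'
#' Averages the mutation energy penalty over `nSamples` independent random
#' mutations at one site. Serves as the stochastic check of the analytic
#' identity `MLmS_i = 1/2 alpha2 ki` computed by [mlmsAnalytic()].
#'
#' @inheritParams sampleMutation
#' @param nSamples number of mutations (>= 100).
#' @param seed integer seed (required for reproducibility).
#' @return a list with `estimate` and `se` (standard error of the mean).
#' @examples
#' net <- buildPfANM(makeHelixTrace(20))
#' mlmsMonteCarlo(net, site = 5, nSamples = 1000, seed = 1)
#' @export
mlmsMonteCarlo <- function(network, site, params = EnsembleParams(),
                           nSamples = 10000, seed = 1,
                           dist = c("gaussian", "uniform")) {
  stopifnot(is(network, "SpringNetwork"))
  if (nSamples < 100) stop("nSamples must be >= 100 for a meaningful standard error")
  dist <- match.arg(dist)
  dv <- .withSeed(seed, .sampleDeltaV(network, site, params, nSamples, dist))
  list(estimate = mean(dv), se = stats::sd(dv) / sqrt(nSamples))
}

#' Linearized mutant acceptance rate
#'
#' Under weak selection the expected Boltzmann acceptance probability of a
#' random mutant linearizes to `omega_i = 1 - beta * MLmS_i`. No clipping
#' is applied: for strongly stressed sites the linearization can go
#' negative, which is its known breakdown; downstream analyses work on
#' z-scores where the affine map is immaterial.
#'
#' @param mlms a raw [SiteVector-class] (or numeric vector) of MLmS values.
#' @param params an [EnsembleParams-class]; only `beta` is used.
#' @return a raw [SiteVector-class] tagged `"acceptance"`.
#' @export
acceptanceRateLinearized <- function(mlms, params = EnsembleParams()) {
  v <- .vals(mlms)
  pid <- if (is(mlms, "SiteVector")) mlms@proteinId else "protein"
  SiteVector(1 - params@beta * v, proteinId = pid, quantity = "acceptance",
             normalized = FALSE)
}

#' Monte-Carlo mutant acceptance rate (no linearization)
#'
#' Estimates the exact expected acceptance probability
#' `omega_i = < exp(-beta deltaV) >` over random mutations at one site,
#' i.e. the quantity whose first-order expansion gives
#' [acceptanceRateLinearized()].
#'
#' @inheritParams mlmsMonteCarlo
#' @return a list with `estimate` and `se`.
#' @export
acceptanceRateMC <- function(network, site, params = EnsembleParams(),
                             nSamples = 10000, seed = 1,
                             dist = c("gaussian", "uniform")) {
  stopifnot(is(network, "SpringNetwork"))
  if (nSamples < 100) stop("nSamples must be >= 100 for a meaningful standard error")
  dist <- match.arg(dist)
  dv <- .withSeed(seed, .sampleDeltaV(network, site, params, nSamples, dist))
  w <- exp(-params@beta * dv)
  list(estimate = mean(w), se = stats::sd(w) / sqrt(nSamples))
}

#' Closed-form mutant acceptance rate for Gaussian perturbations
#'
#' For Gaussian rest-length perturbations the expectation
#' `< exp(-beta deltaV) >` factorizes over the site's springs into a
#' product of one-dimensional Gaussian integrals:
#' `prod_j (1 + beta alpha2 kij)^(-1/2)`. Exact companion (and test
#' oracle) for [acceptanceRateMC()].
#'
#' @inheritParams sampleMutation
#' @return a single number in (0, 1].
#' @export
acceptanceRateClosedForm <- function(network, site, params = EnsembleParams()) {
  stopifnot(is(network, "SpringNetwork"))
  kInc <- network@kij[site, ]
  kInc <- kInc[kInc > 0]
  prod((1 + params@beta * params@alpha2 * kInc)^(-0.5))
}
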