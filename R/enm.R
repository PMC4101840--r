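#' Build a parameter-free anisotropic network model (pfANM)
#'
#' Connects every pair of sites with a spring of force constant
#' `kij = 1/d0ij^2`, where `d0ij` is the equilibrium CA-CA distance, so
#' nearby pairs are stiffly coupled and distant pairs weakly. All springs
#' are relaxed at the input conformation.
#'
#' @param trace a [CaTrace-class].
#' @return a [SpringNetwork-class] with `modelType` `"pfANM"`.
#' @examples
#' net <- buildPfANM(makeHelixTrace(10))
#' net
#' @export
buildPfANM <- function(trace) {
  stopifnot(is(trace, "CaTrace"))
  d0 <- .distMatrix(trace@coords)
  if (min(d0[upper.tri(d0)]) <= 0)
    stop("zero pairwise distance: pfANM force constant would be infinite")
  kij <- 1 / d0^2
  diag(kij) <- 0
  new("SpringNetwork", trace = trace, model = "pfANM", kij = kij, d0 = d0,
      rcut = NA_real_)
}

#' Build a cutoff anisotropic network model (ANM)
#'
#' Connects pairs of sites within `rcut` of each other with unit springs
#' (`kij = 1` for `d0ij <= rcut`, boundary inclusive, else 0). The default
#' cutoff is 13 Angstrom.
#'
#' @param trace a [CaTrace-class].
#' @param rcut cutoff distance in Angstrom (> 0).
#' @return a [SpringNetwork-class] with `modelType` `"ANM"`.
#' @examples
#' net <- buildANM(makeHelixTrace(10), rcut = 13)
#' @export
buildANM <- function(trace, rcut = 13) {
  stopifnot(is(trace, "CaTrace"))
  if (!is.numeric(rcut) || length(rcut) != 1L || rcut <= 0)
    stop("rcut must be a single positive number")
  d0 <- .distMatrix(trace@coords)
  kij <- (d0 <= rcut) * 1
  diag(kij) <- 0
  new("SpringNetwork", trace = trace, model = "ANM", kij = kij, d0 = d0,
      rcut = rcut)
}

#' Site stiffness: total force constant incident to each site
#'
#' `ki = sum_{j != i} kij`. For the pfANM this equals the weighted contact
#' number (WCN) of the site, and for the ANM its contact number (CN);
#' stiffness is the bridge between the elastic network and local packing
#' density.
#'
#' @param network a [SpringNetwork-class].
#' @return a raw [SiteVector-class] tagged `"ki"`.
#' @examples
#' siteValues(siteStiffness(buildPfANM(makeHelixTrace(10))))
#' @export
siteStiffness <- function(network) {
  stopifnot(is(network, "SpringNetwork"))
  SiteVector(rowSums(network@kij), proteinId = network@trace@proteinId,
             quantity = "ki", normalized = FALSE)
}

#' Elastic potential energy of a conformation
#'
#' `V = 1/2 sum_{i<j} kij (dij - d0ij)^2`, in units of kT. Zero at the
#' network's equilibrium conformation (all springs relaxed) and
#' non-negative everywhere.
#'
#' @param network a [SpringNetwork-class].
#' @param conformation N x 3 coordinate matrix (defaults to the network's
#'   equilibrium coordinates).
#' @return a single non-negative number.
#' @examples
#' net <- buildPfANM(makeHelixTrace(10))
#' potentialEnergy(net)  # 0 at equilibrium
#' @export
potentialEnergy <- function(network, conformation = coords(network)) {
  stopifnot(is(network, "SpringNetwork"))
  conformation <- as.matrix(conformation)
  n <- nSites(network)
  if (!all(dim(conformation) == c(n, 3)))
    stop(sprintf("conformation must be a %d x 3 matrix", n))
  dm <- .distMatrix(conformation)
  ut <- upper.tri(dm)
  0.5 * sum(network@kij[ut] * (dm[ut] - network@d0[ut])^2)
}

#' Assemble the 3N x 3N Hessian of an elastic network
#'
#' Analytic second-derivative matrix of the network potential at the
#' equilibrium conformation: off-diagonal 3x3 block
#' `Hij = -(kij/d0ij^2) dij dij^T` (outer product of the inter-site
#' vector), diagonal block `Hii = -sum_{j != i} Hij`. Symmetric, positive
#' semi-definite, with translations and rotations in its null space.
#'
#' @param network a [SpringNetwork-class].
#' @return a numeric 3N x 3N matrix.
#' @export
buildHessian <- function(network) {
  stopifnot(is(network, "SpringNetwork"))
  xyz <- coords(network)
  n <- nrow(xyz)
  k <- network@kij
  d0 <- network@d0
  H <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n - 1L)) {
    ii <- (3 * (i - 1L) + 1L):(3 * i)
    for (j in (i + 1L):n) {
      if (k[i, j] == 0) next
      jj <- (3 * (j - 1L) + 1L):(3 * j)
      dv <- xyz[j, ] - xyz[i, ]
      B <- -(k[i, j] / d0[i, j]^2) * tcrossprod(dv)
      H[ii, jj] <- B
      H[jj, ii] <- B
      H[ii, ii] <- H[ii, ii] - B
      H[jj, jj] <- H[jj, jj] - B
    }
  }
  H
}

#' Pseudo-inverse covariance matrix of an ENM Hessian
#'
#' Eigendecomposes the Hessian, discards eigenvalues at or below
#' `zeroModeRtol * max(eigenvalue)` as rigid-body zero modes, and returns
#' the Moore-Penrose pseudo-inverse `C = sum_{lambda > 0} v v^T / lambda`.
#' A connected non-collinear network must yield exactly six zero modes
#' (three translations, three rotations); any other count raises an error
#' rather than silently inverting a disconnected or degenerate network.
#' Deliberately degenerate geometries (e.g. a two-site system, where the
#' rotation about the axis is trivial and only five rigid modes exist) can
#' be analysed by setting `expectedZeroModes` accordingly.
#'
#' @param hessian symmetric positive semi-definite matrix from
#'   [buildHessian()].
#' @param zeroModeRtol relative eigenvalue threshold for the null space.
#' @param expectedZeroModes number of rigid-body modes that must be found
#'   (default 6).
#' @return a [CovarianceResult-class].
#' @export
covarianceFromHessian <- function(hessian, zeroModeRtol = 1e-8,
                                  expectedZeroModes = 6L) {
  if (!isTRUE(all.equal(hessian, t(hessian), tolerance = 1e-10)))
    stop("hessian must be symmetric")
  eig <- eigen(hessian, symmetric = TRUE)
  lam <- eig$values
  lmax <- max(lam)
  if (lmax <= 0) stop("hessian has no positive eigenvalues")
  zero <- lam <= zeroModeRtol * lmax
  nz <- sum(zero)
  if (nz > expectedZeroModes)
    stop(sprintf("network is disconnected or degenerate (found %d zero modes)", nz))
  if (nz < expectedZeroModes)
    stop(sprintf("rigid-body invariance numerically broken (found %d zero modes, expected %d)",
                 nz, expectedZeroModes))
  keep <- which(!zero)
  V <- eig$vectors[, keep, drop = FALSE]
  C <- V %*% (t(V) / lam[keep])
  C <- (C + t(C)) / 2
  new("CovarianceResult", covariance = C, nZeroModes = as.integer(nz),
      eigenvalues = sort(lam))
}

#' Site mean square fluctuations from a covariance matrix
#'
#' `MSF_i = Tr(C_ii) / beta`: the trace of the i-th 3x3 diagonal block of
#' the pseudo-inverse covariance, scaled by inverse temperature. This is
#' the dynamical-flexibility measure of the package.
#'
#' @param covResult a [CovarianceResult-class].
#' @param params an [EnsembleParams-class]; only `beta` is used.
#' @param proteinId identifier stored in the result.
#' @return a raw [SiteVector-class] tagged `"MSF"`, all entries positive.
#' @export
msfFromCovariance <- function(covResult, params = EnsembleParams(),
                              proteinId = "protein") {
  stopifnot(is(covResult, "CovarianceResult"), is(params, "EnsembleParams"))
  C <- covResult@covariance
  n <- nrow(C) / 3L
  d <- diag(C)
  msf <- (d[3 * seq_len(n) - 2L] + d[3 * seq_len(n) - 1L] + d[3 * seq_len(n)]) /
    params@beta
  SiteVector(msf, proteinId = proteinId, quantity = "MSF", normalized = FALSE)
}

#' Exact MSF of every site of a network
#'
#' Convenience wrapper: Hessian, pseudo-inverse covariance, per-site trace.
#'
#' @param network a [SpringNetwork-class].
#' @param params an [EnsembleParams-class].
#' @return a raw [SiteVector-class] tagged `"MSF"`.
#' @examples
#' msf <- computeMSF(buildPfANM(makeHelixTrace(30)))
#' which.max(siteValues(msf))  # chain ends are the most mobile
#' @export
computeMSF <- function(network, params = EnsembleParams()) {
  covRes <- covarianceFromHessian(buildHessian(network))
  msfFromCovariance(covRes, params, proteinId = network@trace@proteinId)
}

#' Stiffness approximation to the MSF
#'
#' `MSF_i ~ 3 / (2 beta ki)`: the single-site (diagonal) approximation that
#' links flexibility to the inverse of local packing density. It is an
#' approximation — the exact MSF couples all sites through the covariance —
#' but on compact globular structures the two are strongly correlated.
#'
#' @param ki a [SiteVector-class] (or numeric vector) of site stiffnesses,
#'   all positive.
#' @param params an [EnsembleParams-class]; only `beta` is used.
#' @return a raw [SiteVector-class] tagged `"MSF_approx"`.
#' @export
msfApprox <- function(ki, params = EnsembleParams()) {
  v <- .vals(ki)
  if (any(v <= 0)) stop("all site stiffnesses must be positive (isolated site?)")
  pid <- if (is(ki, "SiteVector")) ki@proteinId else "protein"
  SiteVector(3 / (2 * params@beta * v), proteinId = pid,
             quantity = "MSF_approx", normalized = FALSE)
}
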