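#' @import methods
NULL

#' CaTrace: an ordered C-alpha trace of one protein chain
#'
#' Holds one chain's C-alpha sites in residue order: 3D coordinates in
#' Angstrom, residue labels (author numbering plus insertion code) and,
#' optionally, the B-factor of each CA atom. This is the geometric input to
#' every elastic-network computation in the package.
#'
#' @slot proteinId single string identifying the protein (e.g. a PDB code).
#' @slot chainId single string, the chain identifier.
#' @slot siteLabels character vector of residue labels, one per site.
#' @slot coords numeric N x 3 matrix of CA coordinates (Angstrom).
#' @slot bfactors numeric vector of per-site B-factors, or length 0 when the
#'   source provides none.
#'
#' @examples
#' tr <- makeHelixTrace(10)
#' nSites(tr)
#' head(coords(tr))
#' @export
setClass("CaTrace",
  representation(
    proteinId = "character",
    chainId = "character",
    siteLabels = "character",
    coords = "matrix",
    bfactors = "numeric"
  )
)

setValidity("CaTrace", function(object) {
  msg <- character()
  n <- nrow(object@coords)
  if (n < 2L) msg <- c(msg, "a CaTrace needs at least 2 sites")
  if (ncol(object@coords) != 3L) msg <- c(msg, "coords must be an N x 3 matrix")
  if (!is.numeric(object@coords) || anyNA(object@coords))
    msg <- c(msg, "coords must be numeric and free of NA")
  if (length(object@siteLabels) != n)
    msg <- c(msg, "siteLabels length must equal the number of coordinate rows")
  if (length(object@bfactors) > 0L) {
    if (length(object@bfactors) != n)
      msg <- c(msg, "bfactors, when present, must have one value per site")
    if (any(object@bfactors < 0))
      msg <- c(msg, "bfactors must be non-negative")
  }
  if (n >= 2L) {
    dm <- as.matrix(stats::dist(object@coords))
    if (min(dm[upper.tri(dm)]) <= 0)
      msg <- c(msg, "duplicated coordinates: all pairwise distances must be > 0")
  }
  if (length(msg)) msg else TRUE
})

#' SpringNetwork: pairwise springs over a CaTrace
#'
#' A symmetric matrix of force constants \code{kij} together with rest
#' lengths \code{d0} equal to the equilibrium inter-site distances, so that
#' every spring is relaxed at the native conformation. Two flavours are
#' supported: the parameter-free anisotropic network model (\code{"pfANM"},
#' kij = 1/d0^2 for every pair) and the cutoff anisotropic network model
#' (\code{"ANM"}, kij = 1 within \code{rcut}, else 0).
#'
#' @slot trace the [CaTrace-class] the network was built from.
#' @slot model `"pfANM"` or `"ANM"`.
#' @slot kij symmetric N x N matrix of force constants (energy in units of
#'   kT per Angstrom squared), zero diagonal.
#' @slot d0 symmetric N x N matrix of rest lengths (Angstrom).
#' @slot rcut cutoff distance in Angstrom (`NA` for pfANM).
#' @export
setClass("SpringNetwork",
  representation(
    trace = "CaTrace",
    model = "character",
    kij = "matrix",
    d0 = "matrix",
    rcut = "numeric"
  )
)

setValidity("SpringNetwork", function(object) {
  msg <- character()
  n <- nSites(object@trace)
  k <- object@kij
  if (!all(dim(k) == c(n, n))) msg <- c(msg, "kij must be N x N")
  if (!isTRUE(all.equal(k, t(k), tolerance = 1e-12)))
    msg <- c(msg, "kij must be symmetric")
  if (any(diag(k) != 0)) msg <- c(msg, "kij diagonal must be zero")
  if (any(k < 0)) msg <- c(msg, "kij must be non-negative")
  if (!object@model %in% c("pfANM", "ANM"))
    msg <- c(msg, "model must be 'pfANM' or 'ANM'")
  if (!all(dim(object@d0) == c(n, n))) msg <- c(msg, "d0 must be N x N")
  if (length(msg)) msg else TRUE
})

#' CovarianceResult: pseudo-inverse covariance of an ENM Hessian
#'
#' The 3N x 3N variance-covariance matrix obtained by Moore-Penrose
#' pseudo-inversion of the mass-weighted Hessian, together with the
#' eigenvalue spectrum and the number of eigenvalues treated as rigid-body
#' zero modes. A connected, non-collinear 3D network has exactly six
#' (three translations, three rotations).
#'
#' @slot covariance symmetric 3N x 3N matrix (Angstrom^2 per kT).
#' @slot nZeroModes integer, number of discarded null modes.
#' @slot eigenvalues full eigenvalue spectrum, ascending.
#' @export
setClass("CovarianceResult",
  representation(
    covariance = "matrix",
    nZeroModes = "integer",
    eigenvalues = "numeric"
  )
)

#' EnsembleParams: thermodynamic and mutational scale parameters
#'
#' @slot beta inverse temperature 1/kT (dimensionless with kT = 1). Also
#'   absorbs selection strength in the acceptance-rate expressions.
#' @slot alpha2 variance (Angstrom^2) of the random rest-length
#'   perturbations that model a mutation.
#' @export
setClass("EnsembleParams",
  representation(beta = "numeric", alpha2 = "numeric")
)

setValidity("EnsembleParams", function(object) {
  if (length(object@beta) != 1L || object@beta <= 0) return("beta must be a single positive number")
  if (length(object@alpha2) != 1L || object@alpha2 <= 0) return("alpha2 must be a single positive number")
  TRUE
})

#' SiteVector: a per-site scalar property aligned to a CaTrace
#'
#' @slot proteinId protein identifier the values belong to.
#' @slot values numeric vector, one value per site in trace order.
#' @slot quantity tag naming the property (MSF, MLmS, WCN, CN, ki, bfactor,
#'   rate, ...).
#' @slot normalized TRUE when the values are per-protein z-scores
#'   (population SD), FALSE for raw values.
#' @export
setClass("SiteVector",
  representation(
    proteinId = "character",
    values = "numeric",
    quantity = "character",
    normalized = "logical"
  )
)

setValidity("SiteVector", function(object) {
  msg <- character()
  if (anyNA(object@values)) msg <- c(msg, "values must not contain NA")
  if (isTRUE(object@normalized) && length(object@values) >= 2L) {
    v <- object@values
    if (abs(mean(v)) > 1e-10) msg <- c(msg, "normalized values must have mean 0")
    popSD <- sqrt(mean(v^2) - mean(v)^2)
    if (abs(popSD - 1) > 1e-10) msg <- c(msg, "normalized values must have population SD 1")
  }
  if (length(msg)) msg else TRUE
})

#' ModelComparison: stress vs flexibility model comparison results
#'
#' @slot scope `"per_protein"` or `"pooled"`.
#' @slot perProtein data.frame with one row per protein (per-protein scope)
#'   or per pooled fit; columns include AIC, AIC weights, Pearson and
#'   partial correlations for both models.
#' @slot summary data.frame with one row per model: total AIC, mean AIC
#'   weight, number of proteins won, mean correlation, mean partial
#'   correlation.
#' @slot excluded character vector of protein ids dropped from the analysis.
#' @export
setClass("ModelComparison",
  representation(
    scope = "character",
    perProtein = "data.frame",
    summary = "data.frame",
    excluded = "character"
  )
)

## ---- constructors -----------------------------------------------------

#' Create ensemble parameters
#'
#' @param beta inverse temperature (1/kT); default 1.
#' @param alpha2 mutational rest-length variance in Angstrom^2; default 1.
#' @return an [EnsembleParams-class] object.
#' @examples
#' EnsembleParams()
#' EnsembleParams(beta = 2, alpha2 = 0.5)
#' @export
EnsembleParams <- function(beta = 1, alpha2 = 1) {
  new("EnsembleParams", beta = as.numeric(beta), alpha2 = as.numeric(alpha2))
}

#' Create a CaTrace from coordinates
#'
#' @param coords numeric N x 3 matrix of C-alpha coordinates (Angstrom).
#' @param proteinId,chainId identifiers.
#' @param siteLabels residue labels; defaults to "1".."N".
#' @param bfactors optional per-site B-factors.
#' @return a [CaTrace-class] object.
#' @export
CaTrace <- function(coords, proteinId = "protein", chainId = "A",
                    siteLabels = as.character(seq_len(nrow(coords))),
                    bfactors = numeric(0)) {
  coords <- as.matrix(coords)
  dimnames(coords) <- NULL
  new("CaTrace", proteinId = proteinId, chainId = chainId,
      siteLabels = as.character(siteLabels), coords = coords,
      bfactors = as.numeric(bfactors))
}

SiteVector <- function(values, proteinId = "protein", quantity = "other",
                       normalized = FALSE) {
  new("SiteVector", proteinId = proteinId, values = as.numeric(values),
      quantity = quantity, normalized = normalized)
}

## ---- show methods -----------------------------------------------------

setMethod("show", "CaTrace", function(object) {
  cat(sprintf("CaTrace: %s chain %s, %d sites%s\n",
              object@proteinId, object@chainId, nrow(object@coords),
              if (length(object@bfactors)) ", with B-factors" else ""))
})

setMethod("show", "SpringNetwork", function(object) {
  nspr <- sum(object@kij[upper.tri(object@kij)] > 0)
  cat(sprintf("SpringNetwork (%s): %d sites, %d springs%s\n",
              object@model, nSites(object@trace), nspr,
              if (!is.na(object@rcut)) sprintf(", rcut = %g A", object@rcut) else ""))
})

setMethod("show", "CovarianceResult", function(object) {
  cat(sprintf("CovarianceResult: %d x %d, %d zero modes removed\n",
              nrow(object@covariance), ncol(object@covariance),
              object@nZeroModes))
})

setMethod("show", "EnsembleParams", function(object) {
  cat(sprintf("EnsembleParams: beta = %g (1/kT), alpha2 = %g A^2\n",
              object@beta, object@alpha2))
})

setMethod("show", "SiteVector", function(object) {
  cat(sprintf("SiteVector: %s, %s%s, %d sites\n", object@proteinId,
              object@quantity, if (object@normalized) " (z)" else "",
              length(object@values)))
})

setMethod("show", "ModelComparison", function(object) {
  cat(sprintf("ModelComparison (%s)\n", object@scope))
  print(object@summary, row.names = FALSE)
  if (length(object@excluded))
    cat("excluded proteins:", paste(object@excluded, collapse = ", "), "\n")
})
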