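#' @include AllClasses.R
NULL

#' Accessors for StressENM classes
#'
#' Small accessor generics so user code never reaches into slots:
#' `nSites()`, `coords()`, `bfactors()`, `siteLabels()`, `proteinId()`,
#' `chainId()` for [CaTrace-class]; `forceConstants()`, `restLengths()`,
#' `modelType()` for [SpringNetwork-class]; `covarianceMatrix()`,
#' `nZeroModes()`, `eigenvalues()` for [CovarianceResult-class];
#' `siteValues()`, `quantity()`, `isNormalized()` for [SiteVector-class];
#' `comparisonSummary()`, `perProteinStats()` for [ModelComparison-class].
#'
#' @param x an object of the class the accessor belongs to.
#' @return the slot contents (vector, matrix or data.frame as appropriate).
#' @name accessors
#' @aliases nSites coords bfactors siteLabels proteinId chainId
#'   forceConstants restLengths modelType covarianceMatrix nZeroModes
#'   eigenvalues siteValues quantity isNormalized comparisonSummary
#'   perProteinStats
#' @examples
#' tr <- makeHelixTrace(5)
#' nSites(tr)
#' siteLabels(tr)
NULL

#' @rdname accessors
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))
#' @rdname accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))
#' @rdname accessors
#' @export
setGeneric("bfactors", function(x) standardGeneric("bfactors"))
#' @rdname accessors
#' @export
setGeneric("siteLabels", function(x) standardGeneric("siteLabels"))
#' @rdname accessors
#' @export
setGeneric("proteinId", function(x) standardGeneric("proteinId"))
#' @rdname accessors
#' @export
setGeneric("chainId", function(x) standardGeneric("chainId"))
#' @rdname accessors
#' @export
setGeneric("forceConstants", function(x) standardGeneric("forceConstants"))
#' @rdname accessors
#' @export
setGeneric("restLengths", function(x) standardGeneric("restLengths"))
#' @rdname accessors
#' @export
setGeneric("modelType", function(x) standardGeneric("modelType"))
#' @rdname accessors
#' @export
setGeneric("covarianceMatrix", function(x) standardGeneric("covarianceMatrix"))
#' @rdname accessors
#' @export
setGeneric("nZeroModes", function(x) standardGeneric("nZeroModes"))
#' @rdname accessors
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))
#' @rdname accessors
#' @export
setGeneric("siteValues", function(x) standardGeneric("siteValues"))
#' @rdname accessors
#' @export
setGeneric("quantity", function(x) standardGeneric("quantity"))
#' @rdname accessors
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))
#' @rdname accessors
#' @export
setGeneric("comparisonSummary", function(x) standardGeneric("comparisonSummary"))
#' @rdname accessors
#' @export
setGeneric("perProteinStats", function(x) standardGeneric("perProteinStats"))

#' @rdname accessors
setMethod("nSites", "CaTrace", function(x) nrow(x@coords))
#' @rdname accessors
setMethod("coords", "CaTrace", function(x) x@coords)
#' @rdname accessors
setMethod("bfactors", "CaTrace", function(x) x@bfactors)
#' @rdname accessors
setMethod("siteLabels", "CaTrace", function(x) x@siteLabels)
#' @rdname accessors
setMethod("proteinId", "CaTrace", function(x) x@proteinId)
#' @rdname accessors
setMethod("chainId", "CaTrace", function(x) x@chainId)

#' @rdname accessors
setMethod("nSites", "SpringNetwork", function(x) nrow(x@kij))
#' @rdname accessors
setMethod("forceConstants", "SpringNetwork", function(x) x@kij)
#' @rdname accessors
setMethod("restLengths", "SpringNetwork", function(x) x@d0)
#' @rdname accessors
setMethod("modelType", "SpringNetwork", function(x) x@model)
#' @rdname accessors
setMethod("coords", "SpringNetwork", function(x) x@trace@coords)

#' @rdname accessors
setMethod("covarianceMatrix", "CovarianceResult", function(x) x@covariance)
#' @rdname accessors
setMethod("nZeroModes", "CovarianceResult", function(x) x@nZeroModes)
#' @rdname accessors
setMethod("eigenvalues", "CovarianceResult", function(x) x@eigenvalues)

#' @rdname accessors
setMethod("siteValues", "SiteVector", function(x) x@values)
#' @rdname accessors
setMethod("quantity", "SiteVector", function(x) x@quantity)
#' @rdname accessors
setMethod("isNormalized", "SiteVector", function(x) x@normalized)
#' @rdname accessors
setMethod("proteinId", "SiteVector", function(x) x@proteinId)

#' @rdname accessors
setMethod("comparisonSummary", "ModelComparison", function(x) x@summary)
#' @rdname accessors
setMethod("perProteinStats", "ModelComparison", function(x) x@perProtein)
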