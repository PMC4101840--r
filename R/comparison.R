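#' Ordinary least-squares fit of rate on one z-scored predictor
#'
#' Fits `y = a + b x` by OLS and reports the Gaussian maximum-likelihood
#' goodness of fit: `loglik = -(n/2) (log(2 pi rss/n) + 1)` and
#' `AIC = 2k - 2 loglik` with `k = 3` parameters (intercept, slope, error
#' variance) — the convention of `stats::AIC` for a simple linear model.
#' On z-scored inputs the intercept is ~0 and the slope equals the Pearson
#' correlation.
#'
#' @param y,x aligned [SiteVector-class] objects or numeric vectors,
#'   z-scored, length >= 3.
#' @param modelTag label stored in the result (`"stress"`,
#'   `"flexibility"`, ...).
#' @return a list with elements `modelTag`, `a`, `b`, `n`, `rss`,
#'   `loglik`, `aic`, `r`.
#' @examples
#' x <- znorm(rnorm(50))
#' y <- znorm(x + rnorm(50))
#' fitLinear(y, x)$r
#' @export
fitLinear <- function(y, x, modelTag = "model") {
  y <- .vals(y); x <- .vals(x)
  if (length(y) != length(x)) stop("y and x must have the same length")
  n <- length(y)
  if (n < 3L) stop("need at least 3 sites to fit")
  fit <- stats::lm(y ~ x)
  rss <- sum(stats::residuals(fit)^2)
  if (rss < 1e-12) stop("degenerate perfect fit: residual variance is zero")
  ll <- as.numeric(stats::logLik(fit))
  list(modelTag = modelTag,
       a = unname(stats::coef(fit)[1]),
       b = unname(stats::coef(fit)[2]),
       n = n, rss = rss, loglik = ll,
       aic = stats::AIC(fit),
       r = stats::cor(x, y))
}

#' Akaike weights of evidence
#'
#' `w_m` is proportional to `exp(-0.5 (AIC_m - min AIC))`, normalized to
#' sum to 1 over the compared models.
#'
#' @param aics numeric vector of AIC values (>= 2, all finite).
#' @return numeric vector of weights summing to 1.
#' @examples
#' aicWeights(c(100, 102))
#' @export
aicWeights <- function(aics) {
  if (length(aics) < 2L) stop("need at least 2 AIC values to compare")
  if (!all(is.finite(aics))) stop("AIC values must be finite")
  w <- exp(-0.5 * (aics - min(aics)))
  w / sum(w)
}

#' Pearson correlation with degenerate-input guards
#'
#' @param x,y aligned numeric vectors or [SiteVector-class]s, length >= 3,
#'   each with nonzero variance.
#' @return the product-moment correlation coefficient.
#' @export
pearsonCor <- function(x, y) {
  x <- .vals(x); y <- .vals(y)
  if (length(x) != length(y)) stop("x and y must have the same length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance: correlation undefined")
  stats::cor(x, y)
}

#' First-order partial correlation
#'
#' Correlation between `y` and `x` after linearly removing `z` from both:
#' `pr = (r_yx - r_yz r_xz) / sqrt((1 - r_yz^2)(1 - r_xz^2))`. Used to ask
#' how much rate-flexibility correlation remains once mutational stress is
#' controlled for, and vice versa.
#'
#' @param y,x,z aligned numeric vectors or [SiteVector-class]s (n >= 4).
#' @return the partial correlation coefficient.
#' @examples
#' set.seed(1)
#' z <- rnorm(100); y <- z + rnorm(100); x <- z + rnorm(100)
#' partialCorrelation(y, x, z)  # much smaller than cor(y, x)
#' @export
partialCorrelation <- function(y, x, z) {
  y <- .vals(y); x <- .vals(x); z <- .vals(z)
  n <- length(y)
  if (length(x) != n || length(z) != n) stop("y, x, z must have the same length")
  if (n < 4L) stop("need at least 4 observations for a partial correlation")
  ryx <- pearsonCor(y, x)
  ryz <- pearsonCor(y, z)
  rxz <- pearsonCor(x, z)
  if (abs(rxz) >= 1 - 1e-12)
    stop("collinear control variable: |cor(x, z)| = 1")
  (ryx - ryz * rxz) / sqrt((1 - ryz^2) * (1 - rxz^2))
}

# column names of the two competing predictors for a given potential
.modelColumns <- function(potential = c("pfANM", "ANM"),
                          flexPredictor = c("msf", "bfactor")) {
  potential <- match.arg(potential)
  flexPredictor <- match.arg(flexPredictor)
  suffix <- if (potential == "pfANM") "pfanm" else "anm"
  list(stress = paste0("zmlms_", suffix),
       flex = if (flexPredictor == "msf") paste0("zmsf_", suffix) else "zbfactor",
       stressTag = paste0("stress_", suffix),
       flexTag = if (flexPredictor == "msf") paste0("flexibility_", suffix)
                 else "flexibility_bfactor")
}

.fitPair <- function(dat, cols) {
  fs <- fitLinear(dat$zwr4s, dat[[cols$stress]], cols$stressTag)
  ff <- fitLinear(dat$zwr4s, dat[[cols$flex]], cols$flexTag)
  w <- aicWeights(c(fs$aic, ff$aic))
  prS <- partialCorrelation(dat$zwr4s, dat[[cols$stress]], dat[[cols$flex]])
  prF <- partialCorrelation(dat$zwr4s, dat[[cols$flex]], dat[[cols$stress]])
  data.frame(n = fs$n,
             aic_stress = fs$aic, aic_flex = ff$aic,
             waic_stress = w[1], waic_flex = w[2],
             r_stress = fs$r, r_flex = ff$r,
             pr_stress = prS, pr_flex = prF)
}

.comparisonSummary <- function(per, cols) {
  data.frame(
    model = c("stress", "flexibility"),
    x = c(cols$stress, cols$flex),
    aic = c(sum(per$aic_stress), sum(per$aic_flex)),
    mean_waic = c(mean(per$waic_stress), mean(per$waic_flex)),
    n_best = c(sum(per$aic_stress < per$aic_flex),
               sum(per$aic_flex < per$aic_stress)),
    mean_r = c(mean(per$r_stress), mean(per$r_flex)),
    mean_pr = c(mean(per$pr_stress), mean(per$pr_flex)),
    stringsAsFactors = FALSE
  )
}

#' Protein-by-protein stress vs flexibility comparison
#'
#' For every protein in the site table, fits the stress model
#' (rate ~ MLmS) and the flexibility model (rate ~ MSF, or ~ B-factor)
#' under the chosen ENM potential, and reports per-protein AIC, Akaike
#' weights, Pearson correlations of each predictor with the rate, and the
#' two partial correlations (each predictor controlling the other). The
#' summary aggregates: AIC summed over proteins, mean weight, number of
#' proteins each model wins, mean r and mean partial r. Proteins with
#' fewer than 4 usable sites, missing predictor columns, or degenerate
#' fits are excluded with a warning and listed in the result.
#'
#' @param table a site-table data.frame (see [buildSiteTable()]) with a
#'   `zwr4s` rate column.
#' @param potential `"pfANM"` or `"ANM"`: which potential's MLmS/MSF pair
#'   to compare.
#' @param flexPredictor `"msf"` (default) or `"bfactor"` for the
#'   B-factor-based flexibility variant.
#' @return a [ModelComparison-class] with scope `"per_protein"`.
#' @export
comparePerProtein <- function(table, potential = c("pfANM", "ANM"),
                              flexPredictor = c("msf", "bfactor")) {
  cols <- .modelColumns(match.arg(potential), match.arg(flexPredictor))
  need <- c("zwr4s", cols$stress, cols$flex)
  missingCols <- setdiff(need, names(table))
  if (length(missingCols))
    stop("site table is missing required column(s): ",
         paste(missingCols, collapse = ", "))
  rows <- list()
  excluded <- character(0)
  for (p in unique(table$pdb)) {
    dat <- table[table$pdb == p, , drop = FALSE]
    dat <- dat[stats::complete.cases(dat[, need]), , drop = FALSE]
    if (nrow(dat) < 4L) {
      warning(sprintf("protein %s: fewer than 4 complete sites; excluded", p))
      excluded <- c(excluded, p)
      next
    }
    row <- tryCatch(.fitPair(dat, cols), error = function(e) {
      warning(sprintf("protein %s: %s; excluded", p, conditionMessage(e)))
      NULL
    })
    if (is.null(row)) { excluded <- c(excluded, p); next }
    rows[[p]] <- cbind(data.frame(pdb = p, chain = dat$chain[1]), row)
  }
  if (!length(rows)) stop("no protein could be fitted")
  per <- do.call(rbind, rows)
  rownames(per) <- NULL
  new("ModelComparison", scope = "per_protein", perProtein = per,
      summary = .comparisonSummary(per, cols), excluded = excluded)
}

#' Pooled (global) stress vs flexibility comparison
#'
#' Same comparison as [comparePerProtein()] but with a single fit of each
#' model over all sites of all proteins pooled together (sites are already
#' z-scored within their protein, so pooling is scale-consistent).
#'
#' @inheritParams comparePerProtein
#' @return a [ModelComparison-class] with scope `"pooled"`; the
#'   `perProteinStats` slot holds the single pooled row.
#' @export
comparePooled <- function(table, potential = c("pfANM", "ANM"),
                          flexPredictor = c("msf", "bfactor")) {
  cols <- .modelColumns(match.arg(potential), match.arg(flexPredictor))
  need <- c("zwr4s", cols$stress, cols$flex)
  missingCols <- setdiff(need, names(table))
  if (length(missingCols))
    stop("site table is missing required column(s): ",
         paste(missingCols, collapse = ", "))
  dat <- table[stats::complete.cases(table[, need]), , drop = FALSE]
  if (nrow(dat) < 4L) stop("fewer than 4 complete sites in the pooled table")
  per <- cbind(data.frame(pdb = "(pooled)", chain = "*"), .fitPair(dat, cols))
  new("ModelComparison", scope = "pooled", perProtein = per,
      summary = .comparisonSummary(per, cols), excluded = character(0))
}

#' Equal-count binned profile of one site property against another
#'
#' Ranks the sites by `x` (stable tie-break by original order), splits them
#' into `nBins` contiguous bins of equal count (when `n` is not a multiple
#' of `nBins`, the first `n %% nBins` bins receive one extra site), and
#' reports per-bin means of `x` and `y` plus a 99% normal-approximation
#' confidence half-width for the mean of `y`
#' (`2.5758 sd(y_bin)/sqrt(n_bin)`). This is the smoothing used to
#' visualize rate-vs-flexibility and rate-vs-stress relationships.
#'
#' @param x,y aligned z-scored [SiteVector-class]s or numeric vectors.
#' @param nBins number of bins (default 20); requires `length(x) >= nBins`.
#' @return a data.frame with columns `bin`, `n`, `mean_x`, `mean_y`,
#'   `ci99` (NA for single-site bins).
#' @export
binnedProfile <- function(x, y, nBins = 20) {
  x <- .vals(x); y <- .vals(y)
  if (length(x) != length(y)) stop("x and y must have the same length")
  n <- length(x)
  nBins <- as.integer(nBins)
  if (n < nBins) stop(sprintf("need at least %d sites for %d bins", nBins, nBins))
  ord <- order(x)                     # stable: ties keep original order
  base <- n %/% nBins
  extra <- n %% nBins
  sizes <- rep(base, nBins) + c(rep(1L, extra), rep(0L, nBins - extra))
  binOf <- rep(seq_len(nBins), times = sizes)
  xs <- x[ord]; ys <- y[ord]
  out <- data.frame(
    bin = seq_len(nBins),
    n = sizes,
    mean_x = as.numeric(tapply(xs, binOf, mean)),
    mean_y = as.numeric(tapply(ys, binOf, mean)),
    ci99 = as.numeric(tapply(ys, binOf, function(v)
      if (length(v) > 1L) 2.5758 * stats::sd(v) / sqrt(length(v)) else NA_real_))
  )
  rownames(out) <- NULL
  out
}

#' Curvature test of a binned profile
#'
#' Tests whether the bin-level relationship `mean_y` vs `mean_x` has
#' significant curvature: an F-test of the quadratic term comparing
#' `mean_y ~ mean_x` against `mean_y ~ mean_x + mean_x^2`. On data
#' generated under the stress model the rate-vs-MSF profile is curved
#' (rates are approximately linear in stress, and MSF ~ 1/stress) while
#' the rate-vs-MLmS profile is not.
#'
#' @param profile a data.frame from [binnedProfile()].
#' @return the p-value of the quadratic-term F-test.
#' @export
profileCurvatureTest <- function(profile) {
  stopifnot(all(c("mean_x", "mean_y") %in% names(profile)))
  if (nrow(profile) < 4L) stop("need at least 4 bins to test curvature")
  m1 <- stats::lm(mean_y ~ mean_x, data = profile)
  m2 <- stats::lm(mean_y ~ mean_x + I(mean_x^2), data = profile)
  stats::anova(m1, m2)[["Pr(>F)"]][2]
}
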