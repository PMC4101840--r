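# population-SD z-score of a numeric vector; `what` names the property in
# error messages
.zn <- function(v, what = "site property") {
  if (length(v) < 2L) stop("need at least 2 sites to z-normalize ", what)
  m <- mean(v)
  s <- sqrt(mean(v^2) - m^2)
  if (!is.finite(s) || s == 0)
    stop("constant ", what, " cannot be z-normalized")
  (v - m) / s
}

#' Per-protein z-score normalization
#'
#' Standardizes a per-site property to mean 0 and unit population standard
#' deviation, `x~ = (x - <x>) / sqrt(<x^2> - <x>^2)`, with averages over
#' the sites of one protein. All headline quantities of the package (MSF,
#' MLmS, WCN, CN, B-factors, rates) are compared on this relative scale,
#' which removes the arbitrary energy, temperature and mutation-size units.
#'
#' @param x a raw [SiteVector-class] or a numeric vector.
#' @return the same type as the input, z-normalized.
#' @examples
#' znorm(c(-1, 0, 1))
#' @export
znorm <- function(x) {
  if (is(x, "SiteVector")) {
    SiteVector(.zn(x@values, x@quantity), proteinId = x@proteinId,
               quantity = x@quantity, normalized = TRUE)
  } else {
    .zn(as.numeric(x))
  }
}

#' Weighted contact number of each site
#'
#' `WCN_i = sum_{j != i} 1/dij^2`: an inverse-square-distance packing
#' density. Identical, site by site, to the stiffness of the pfANM network
#' built on the same trace.
#'
#' @param trace a [CaTrace-class].
#' @return a raw [SiteVector-class] tagged `"WCN"`.
#' @examples
#' wcnV <- wcn(makeHelixTrace(20))
#' @export
wcn <- function(trace) {
  stopifnot(is(trace, "CaTrace"))
  dm <- .distMatrix(trace@coords)
  if (min(dm[upper.tri(dm)]) <= 0) stop("coincident sites: WCN undefined")
  w <- 1 / dm^2
  diag(w) <- 0
  SiteVector(rowSums(w), proteinId = trace@proteinId, quantity = "WCN",
             normalized = FALSE)
}

#' Contact number of each site
#'
#' `CN_i` = number of other sites within `rcut` (boundary inclusive,
#' matching the ANM spring rule). Identical to the stiffness of the ANM
#' network at the same cutoff.
#'
#' @param trace a [CaTrace-class].
#' @param rcut cutoff distance in Angstrom.
#' @return a raw, integer-valued [SiteVector-class] tagged `"CN"`.
#' @export
cn <- function(trace, rcut = 13) {
  stopifnot(is(trace, "CaTrace"))
  if (rcut <= 0) stop("rcut must be positive")
  dm <- .distMatrix(trace@coords)
  a <- (dm <= rcut) * 1
  diag(a) <- 0
  SiteVector(rowSums(a), proteinId = trace@proteinId, quantity = "CN",
             normalized = FALSE)
}

.siteTableCols <- c("pdb", "chain", "site", "zwr4s", "zbfactor",
                    "zmsf_pfanm", "zmlms_pfanm", "zmsf_anm", "zmlms_anm")

# per-protein predictor block (z-scored), before any join with rates
.predictorBlock <- function(trace, rcut, params) {
  pfanm <- buildPfANM(trace)
  msfPf <- computeMSF(pfanm, params)
  mlmsPf <- mlmsAnalytic(siteStiffness(pfanm), params)
  anm <- buildANM(trace, rcut)
  mlmsAnm <- mlmsAnalytic(siteStiffness(anm), params)
  msfAnm <- tryCatch(computeMSF(anm, params), error = function(e) {
    warning(sprintf("protein %s: ANM MSF unavailable (%s); column set to NA",
                    trace@proteinId, conditionMessage(e)))
    NULL
  })
  zb <- if (length(trace@bfactors)) .zn(trace@bfactors, "B-factor") else NA_real_
  data.frame(
    pdb = trace@proteinId,
    chain = trace@chainId,
    site = trace@siteLabels,
    zwr4s = NA_real_,
    zbfactor = zb,
    zmsf_pfanm = .zn(siteValues(msfPf), "MSF (pfANM)"),
    zmlms_pfanm = .zn(siteValues(mlmsPf), "MLmS (pfANM)"),
    zmsf_anm = if (is.null(msfAnm)) NA_real_ else .zn(siteValues(msfAnm), "MSF (ANM)"),
    zmlms_anm = .zn(siteValues(mlmsAnm), "MLmS (ANM)"),
    stringsAsFactors = FALSE
  )
}

#' Assemble the per-site predictor table
#'
#' For each input trace, computes the exact MSF and the analytic MLmS under
#' both ENM flavours (plus the B-factor column when present), z-normalizes
#' every column within the protein, and inner-joins with per-protein
#' z-normalized evolutionary rates on (protein, chain, site). Rate rows
#' that do not match a structure site are dropped with a summary message;
#' proteins with fewer than 3 matched sites are excluded with a warning.
#' If the ANM network of a protein is disconnected at `rcut`, its ANM MSF
#' column is set to `NA` (the ANM MLmS, an exact per-site identity, is
#' still produced).
#'
#' @param traces a [CaTrace-class] or list of them.
#' @param rates optional data.frame with columns `pdb`, `chain`, `site`,
#'   `rate` (raw rates; z-normalized per protein here), e.g. parsed
#'   Rate4Site output. When `NULL` the `zwr4s` column is all `NA`.
#' @param rcut ANM cutoff in Angstrom.
#' @param params an [EnsembleParams-class].
#' @return a data.frame with columns `pdb, chain, site, zwr4s, zbfactor,
#'   zmsf_pfanm, zmlms_pfanm, zmsf_anm, zmlms_anm`, matching the package's
#'   site-table TSV schema.
#' @examples
#' tr <- makeGlobuleTrace(30, seed = 1)
#' tab <- buildSiteTable(tr)
#' colMeans(tab[, c("zmsf_pfanm", "zmlms_pfanm")])  # ~0 by construction
#' @export
buildSiteTable <- function(traces, rates = NULL, rcut = 13,
                           params = EnsembleParams()) {
  if (is(traces, "CaTrace")) traces <- list(traces)
  stopifnot(length(traces) >= 1L, all(vapply(traces, is, TRUE, "CaTrace")))
  blocks <- lapply(traces, .predictorBlock, rcut = rcut, params = params)
  tab <- do.call(rbind, blocks)
  if (anyDuplicated(tab[, c("pdb", "chain", "site")]))
    stop("duplicated (pdb, chain, site) keys across input traces")
  if (is.null(rates)) return(tab)

  stopifnot(all(c("pdb", "chain", "site", "rate") %in% names(rates)))
  rates$site <- as.character(rates$site)
  key <- function(d) paste(d$pdb, d$chain, d$site, sep = "|")
  rates$.key <- key(rates)
  tab$.key <- key(tab)
  if (anyDuplicated(rates$.key)) stop("duplicated (pdb, chain, site) keys in rates")
  nUnmatched <- sum(!rates$.key %in% tab$.key)
  if (nUnmatched > 0L)
    .msgf("dropped %d rate row(s) with no matching structure site", nUnmatched)

  out <- list()
  for (p in unique(tab$pdb)) {
    sub <- tab[tab$pdb == p, , drop = FALSE]
    rsub <- rates[rates$.key %in% sub$.key, , drop = FALSE]
    if (nrow(rsub) < 3L) {
      warning(sprintf("protein %s: fewer than 3 sites with rates; excluded", p))
      next
    }
    sub <- sub[match(rsub$.key, sub$.key), , drop = FALSE]
    sub$zwr4s <- .zn(rsub$rate, sprintf("rate (%s)", p))
    out[[p]] <- sub
  }
  if (!length(out)) stop("no protein retained after matching rates to structures")
  res <- do.call(rbind, out)
  res$.key <- NULL
  rownames(res) <- NULL
  res
}

#' Write / read a site table in the supplementary TSV schema
#'
#' Columns: `pdb, chain, site, zwr4s, zbfactor, zmsf_pfanm, zmlms_pfanm,
#' zmsf_anm, zmlms_anm`. `readSiteTable` checks the schema and errors
#' naming any missing columns.
#'
#' @param table a site-table data.frame from [buildSiteTable()].
#' @param path file path.
#' @param comments optional character vector written as `#`-prefixed header
#'   lines (provenance: seed, configuration).
#' @return `writeSiteTable` returns `path` invisibly; `readSiteTable`
#'   returns the data.frame.
#' @export
writeSiteTable <- function(table, path, comments = NULL) {
  stopifnot(all(.siteTableCols %in% names(table)))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(table[, .siteTableCols], con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeSiteTable
#' @export
readSiteTable <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          colClasses = c(site = "character"))
  missing <- setdiff(.siteTableCols, names(df))
  if (length(missing))
    stop("site table is missing required column(s): ",
         paste(missing, collapse = ", "))
  df[, .siteTableCols]
}
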