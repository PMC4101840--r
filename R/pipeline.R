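#' Read a per-site evolutionary rate table
#'
#' Parses a TSV with columns `pdb, chain, site, rate` (e.g. collated
#' Rate4Site output). Rates are consumed as given; no inference is done
#' here.
#'
#' @param path file path.
#' @return a data.frame with character `site` labels.
#' @export
readRateTable <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          colClasses = c(site = "character"))
  need <- c("pdb", "chain", "site", "rate")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("rate table is missing required column(s): ",
         paste(missing, collapse = ", "))
  df[, need]
}

#' Generate a synthetic multi-protein study
#'
#' Builds `nProteins` compact globular traces (seeds `seed`, `seed + 1`,
#' ...) and site-specific evolutionary rates generated under a chosen
#' model: under `"stress"`, raw rates are `-z(MLmS|pfANM) + noise`
#' (stressed, densely packed sites evolve slowly); under `"flexibility"`,
#' `+z(MSF|pfANM) + noise`. Noise is Gaussian with standard deviation
#' `noiseSD` on the z scale, and rates are re-z-scored per protein in the
#' returned table. Fully deterministic for a given seed.
#'
#' @param nProteins number of proteins (default 20).
#' @param nSites sites per protein (default 120).
#' @param noiseSD standard deviation of the rate noise (default 0.8).
#' @param seed integer seed; also the seed of the first globule.
#' @param generativeModel `"stress"` (default) or `"flexibility"`.
#' @param rcut ANM cutoff in Angstrom.
#' @param params an [EnsembleParams-class].
#' @return a list with `traces` (list of [CaTrace-class]), `table` (site
#'   table with `zwr4s` filled in) and `rates` (the raw generated rates).
#' @examples
#' \donttest{
#' study <- makeStressStudy(nProteins = 2, nSites = 40, seed = 1)
#' head(study$table)
#' }
#' @export
makeStressStudy <- function(nProteins = 20, nSites = 120, noiseSD = 0.8,
                            seed = 1, generativeModel = c("stress", "flexibility"),
                            rcut = 13, params = EnsembleParams()) {
  generativeModel <- match.arg(generativeModel)
  traces <- lapply(seq_len(nProteins) - 1L,
                   function(i) makeGlobuleTrace(nSites, seed = seed + i))
  tab <- buildSiteTable(traces, rates = NULL, rcut = rcut, params = params)
  signal <- if (generativeModel == "stress") -tab$zmlms_pfanm else tab$zmsf_pfanm
  raw <- .withSeed(seed, signal + stats::rnorm(nrow(tab), 0, noiseSD))
  rates <- data.frame(pdb = tab$pdb, chain = tab$chain, site = tab$site,
                      rate = raw, stringsAsFactors = FALSE)
  for (p in unique(tab$pdb)) {
    idx <- tab$pdb == p
    tab$zwr4s[idx] <- .zn(raw[idx], sprintf("rate (%s)", p))
  }
  list(traces = traces, table = tab, rates = rates)
}

.outputHeader <- function(seed, extra = character(0)) {
  ver <- tryCatch(as.character(utils::packageVersion("StressENM")),
                  error = function(e) "dev")
  cfg <- paste(extra, collapse = "; ")
  c(sprintf("StressENM %s", ver),
    sprintf("seed=%s", if (is.null(seed)) "NA" else seed),
    sprintf("config=[%s] hash=%08x", cfg,
            sum(utf8ToInt(cfg)) %% .Machine$integer.max))
}

#' Compute and write per-site predictor tables
#'
#' Runs the full predictor pipeline (both ENMs, z-normalization, optional
#' rate join) over a list of traces and writes one TSV per protein plus a
#' merged table, all in the site-table schema with a provenance header.
#'
#' @param traces a [CaTrace-class] or list of them (use [readCaTrace()] to
#'   build traces from PDB files).
#' @param rates optional rate data.frame (see [readRateTable()]).
#' @param outDir output directory, created if needed.
#' @param rcut ANM cutoff in Angstrom.
#' @param params an [EnsembleParams-class].
#' @param seed seed recorded in the output header (the computation itself
#'   is deterministic).
#' @return the merged site table, invisibly. Per-protein failures are
#'   isolated: a bad structure is skipped with a warning and the batch
#'   continues; the call errors only if every protein fails.
#' @export
runPredictors <- function(traces, rates = NULL, outDir = ".", rcut = 13,
                          params = EnsembleParams(), seed = NULL) {
  if (is(traces, "CaTrace")) traces <- list(traces)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  hdr <- .outputHeader(seed, c(sprintf("rcut=%g", rcut),
                               sprintf("beta=%g", params@beta),
                               sprintf("alpha2=%g", params@alpha2)))
  tabs <- list()
  for (tr in traces) {
    tab <- tryCatch(
      buildSiteTable(tr, rates = if (is.null(rates)) NULL else
        rates[rates$pdb == tr@proteinId, , drop = FALSE],
        rcut = rcut, params = params),
      error = function(e) {
        warning(sprintf("protein %s failed: %s", tr@proteinId,
                        conditionMessage(e)))
        NULL
      })
    if (is.null(tab)) next
    writeSiteTable(tab, file.path(outDir, paste0(tr@proteinId, "_sites.tsv")),
                   comments = hdr)
    tabs[[tr@proteinId]] <- tab
  }
  if (!length(tabs)) stop("all proteins failed; no site table produced")
  merged <- do.call(rbind, tabs)
  rownames(merged) <- NULL
  writeSiteTable(merged, file.path(outDir, "sites_merged.tsv"), comments = hdr)
  invisible(merged)
}

#' Run the full model comparison and write report tables
#'
#' Produces, for each ENM potential (and a B-factor flexibility variant
#' when `zbfactor` is available): the per-protein comparison table, its
#' summary, the pooled comparison, and 20-bin rate-vs-MSF and
#' rate-vs-MLmS profiles, written as TSV files with provenance headers.
#'
#' @param table a site table with a `zwr4s` column (from
#'   [buildSiteTable()] / [readSiteTable()]).
#' @param outDir output directory, created if needed.
#' @param nBins bins for the profiles (default 20).
#' @param seed seed recorded in the output headers.
#' @return invisibly, a nested list of [ModelComparison-class] objects and
#'   profile data.frames keyed by potential.
#' @export
runComparison <- function(table, outDir = ".", nBins = 20, seed = NULL) {
  missing <- setdiff(.siteTableCols, names(table))
  if (length(missing))
    stop("site table is missing required column(s): ",
         paste(missing, collapse = ", "))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  hdr <- .outputHeader(seed, sprintf("nBins=%d", nBins))
  writeTsv <- function(df, name) {
    con <- file(file.path(outDir, name), "w")
    on.exit(close(con))
    writeLines(paste0("# ", hdr), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out <- list()
  for (pot in c("pfANM", "ANM")) {
    per <- comparePerProtein(table, potential = pot)
    pool <- comparePooled(table, potential = pot)
    cols <- .modelColumns(pot)
    keep <- stats::complete.cases(table[, c("zwr4s", cols$stress, cols$flex)])
    profMSF <- binnedProfile(table[[cols$flex]][keep], table$zwr4s[keep], nBins)
    profMLmS <- binnedProfile(table[[cols$stress]][keep], table$zwr4s[keep], nBins)
    tag <- tolower(pot)
    writeTsv(perProteinStats(per), sprintf("per_protein_%s.tsv", tag))
    writeTsv(comparisonSummary(per), sprintf("summary_per_protein_%s.tsv", tag))
    writeTsv(comparisonSummary(pool), sprintf("summary_pooled_%s.tsv", tag))
    writeTsv(profMSF, sprintf("profile_rate_vs_msf_%s.tsv", tag))
    writeTsv(profMLmS, sprintf("profile_rate_vs_mlms_%s.tsv", tag))
    out[[pot]] <- list(perProtein = per, pooled = pool,
                       profileMSF = profMSF, profileMLmS = profMLmS)
  }
  if (!all(is.na(table$zbfactor))) {
    for (pot in c("pfANM", "ANM")) {
      perB <- tryCatch(
        comparePerProtein(table, potential = pot, flexPredictor = "bfactor"),
        error = function(e) NULL)
      if (!is.null(perB))
        writeTsv(comparisonSummary(perB),
                 sprintf("summary_per_protein_%s_vs_bfactor.tsv", tolower(pot)))
    }
  }
  invisible(out)
}

#' End-to-end synthetic demonstration
#'
#' Generates a synthetic study (default: 20 compact globules of 120 sites
#' with rates produced by the stress model plus noise), runs the predictor
#' pipeline and the full model comparison, prints a short summary, and
#' checks the headline qualitative result — the stress model must win the
#' AIC comparison in at least `minWins` of the proteins — stopping with an
#' error otherwise. Deterministic for a given seed.
#'
#' @param seed integer seed.
#' @param outDir optional directory for the report TSVs (a temporary
#'   directory by default).
#' @param nProteins,nSites,noiseSD study dimensions, passed to
#'   [makeStressStudy()].
#' @param minWins minimum number of proteins the stress model must win.
#' @return invisibly, a list with the study, the comparison objects and
#'   the headline numbers.
#' @examples
#' \donttest{
#' demo <- runDemo(seed = 1, nProteins = 3, nSites = 60, minWins = 2)
#' }
#' @export
runDemo <- function(seed = 1, outDir = tempfile("stressenm_demo"),
                    nProteins = 20, nSites = 120, noiseSD = 0.8,
                    minWins = ceiling(0.9 * nProteins)) {
  study <- makeStressStudy(nProteins = nProteins, nSites = nSites,
                           noiseSD = noiseSD, seed = seed)
  reports <- runComparison(study$table, outDir = outDir, seed = seed)
  sumPf <- comparisonSummary(reports$pfANM$perProtein)
  poolPf <- perProteinStats(reports$pfANM$pooled)
  nBest <- sumPf$n_best[sumPf$model == "stress"]
  headline <- list(
    n_proteins = nProteins,
    stress_wins_pfanm = nBest,
    pooled_waic_stress_pfanm = poolPf$waic_stress,
    pooled_r_stress_pfanm = poolPf$r_stress,
    pooled_r_flex_pfanm = poolPf$r_flex,
    pooled_pr_stress_pfanm = poolPf$pr_stress,
    pooled_pr_flex_pfanm = poolPf$pr_flex
  )
  cat(sprintf(paste0(
    "Synthetic study: %d proteins x %d sites (seed %d)\n",
    "  stress model wins AIC in %d/%d proteins (pfANM)\n",
    "  pooled: w(AIC)[stress] = %.4f, r(rate, MLmS) = %.3f, r(rate, MSF) = %.3f\n",
    "  pooled partial r: stress|flex = %.3f, flex|stress = %.3f\n"),
    nProteins, nSites, seed, nBest, nProteins,
    headline$pooled_waic_stress_pfanm, headline$pooled_r_stress_pfanm,
    headline$pooled_r_flex_pfanm, headline$pooled_pr_stress_pfanm,
    headline$pooled_pr_flex_pfanm))
  if (nBest < minWins)
    stop(sprintf("demo assertion failed: stress model won only %d/%d proteins",
                 nBest, nProteins))
  invisible(list(study = study, reports = reports, headline = headline))
}
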