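#' Read a C-alpha trace from a PDB file
#'
#' Extracts one chain's C-alpha coordinates and B-factors from a PDB file.
#' Only `ATOM` records are considered (HETATM and waters are ignored) and
#' only the first model of a multi-model file is used. Alternate locations
#' are resolved to the highest-occupancy conformer (ties: first in file);
#' residues without a CA atom are skipped with a warning. Residue order
#' follows the file order of each residue's first CA record.
#'
#' @param pdbFile path to a PDB file.
#' @param chain chain identifier to extract.
#' @param proteinId identifier stored in the result; defaults to the file
#'   name without extension.
#' @return a [CaTrace-class] with one site per residue carrying a CA atom.
#'   B-factors are taken from the CA atoms; if any are missing or negative
#'   the whole B-factor column is dropped with a warning.
#' @examples
#' pdb <- system.file("extdata", "demo_helix.pdb", package = "StressENM")
#' tr <- readCaTrace(pdb, chain = "A")
#' tr
#' @export
readCaTrace <- function(pdbFile, chain, proteinId = NULL) {
  if (!file.exists(pdbFile)) stop("PDB file not found: ", pdbFile)
  if (is.null(proteinId)) proteinId <- sub("\\.[^.]*$", "", basename(pdbFile))
  pdb <- suppressWarnings(bio3d::read.pdb(pdbFile, rm.alt = FALSE, verbose = FALSE))
  at <- pdb$atom
  ca <- at[at$type == "ATOM" & at$elety == "CA", , drop = FALSE]
  if (nrow(ca) == 0L) stop("no C-alpha atoms found in ", pdbFile)
  chains <- unique(ca$chain)
  if (!chain %in% chains)
    stop(sprintf("chain '%s' not found; available chains: {%s}",
                 chain, paste(sort(chains), collapse = ", ")))
  ca <- ca[ca$chain == chain, , drop = FALSE]

  # residues of this chain that have ATOM records but no CA are skipped
  atc <- at[at$type == "ATOM" & at$chain %in% chain, , drop = FALSE]
  resAll <- unique(paste(atc$resno, ifelse(is.na(atc$insert), "", atc$insert)))
  resCA <- unique(paste(ca$resno, ifelse(is.na(ca$insert), "", ca$insert)))
  nSkipped <- length(setdiff(resAll, resCA))
  if (nSkipped > 0L)
    warning(sprintf("%d residue(s) of chain %s lack a CA atom and were skipped",
                    nSkipped, chain))

  key <- paste(ca$resno, ifelse(is.na(ca$insert), "", ca$insert), sep = "|")
  keyLevels <- unique(key)        # file order of first CA occurrence
  pick <- integer(length(keyLevels))
  for (i in seq_along(keyLevels)) {
    rows <- which(key == keyLevels[i])
    if (length(rows) > 1L) {
      alt <- ca$alt[rows]
      if (anyDuplicated(alt) || all(is.na(alt)))
        stop(sprintf("duplicate CA records for residue %s of chain %s after altLoc resolution",
                     gsub("\\|", "", keyLevels[i]), chain))
      occ <- ca$o[rows]
      occ[is.na(occ)] <- 1
      rows <- rows[which.max(occ)]  # which.max keeps the first on ties
    }
    pick[i] <- rows
  }
  sel <- ca[pick, , drop = FALSE]

  labels <- paste0(sel$resno, ifelse(is.na(sel$insert), "", sel$insert))
  b <- sel$b
  if (anyNA(b) || any(b < 0, na.rm = TRUE)) {
    warning("missing or negative B-factors; dropping the B-factor column for chain ", chain)
    b <- numeric(0)
  }
  CaTrace(cbind(sel$x, sel$y, sel$z), proteinId = proteinId, chainId = chain,
          siteLabels = labels, bfactors = b)
}

#' Generate an ideal alpha-helical C-alpha trace
#'
#' Places CA atoms on a cylinder with textbook alpha-helix geometry:
#' radius 2.3 Angstrom, rise 1.5 Angstrom per residue and 100 degrees of
#' rotation per residue, giving consecutive CA-CA distances of about
#' 3.8 Angstrom. Deterministic (no randomness).
#'
#' @param n number of sites (>= 2).
#' @param proteinId identifier for the resulting trace.
#' @return a [CaTrace-class].
#' @examples
#' tr <- makeHelixTrace(50)
#' range(sqrt(rowSums(diff(coords(tr))^2)))  # ~3.80 A virtual bonds
#' @export
makeHelixTrace <- function(n, proteinId = sprintf("helix%d", n)) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("a helix trace needs n >= 2 sites")
  i <- seq_len(n) - 1L
  theta <- i * 100 * pi / 180
  CaTrace(cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * i),
          proteinId = proteinId)
}

# connectivity of an undirected adjacency matrix by breadth-first search
.isConnected <- function(adj) {
  n <- nrow(adj)
  seen <- logical(n)
  frontier <- 1L
  seen[1L] <- TRUE
  while (length(frontier)) {
    nxt <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

#' Generate a compact globular C-alpha trace
#'
#' Grows a self-avoiding chain with fixed 3.8 Angstrom virtual bonds inside
#' a sphere of radius `3.0 * n^(1/3)` Angstrom, the mean density of folded
#' globular proteins, keeping every inter-site distance at or above
#' 3.5 Angstrom. The chain is regrown until the resulting 13 Angstrom
#' cutoff network is a single connected component, so both ENM flavours are
#' well defined on the fixture. Reproducible for a given seed.
#'
#' @param n number of sites (>= 10).
#' @param seed integer seed; the caller's RNG stream is not disturbed.
#' @param proteinId identifier for the resulting trace.
#' @param maxRegrow maximum number of full regrow attempts before giving up.
#' @return a [CaTrace-class].
#' @examples
#' tr <- makeGlobuleTrace(120, seed = 1)
#' min(dist(coords(tr)))  # >= 3.5 A
#' @export
makeGlobuleTrace <- function(n, seed, proteinId = sprintf("globule%d_s%d", n, seed),
                             maxRegrow = 50L) {
  n <- as.integer(n)
  if (is.na(n) || n < 10L) stop("a globule trace needs n >= 10 sites")
  bond <- 3.8
  minSep <- 3.5
  radius <- 3.0 * n^(1 / 3)
  xyz <- .withSeed(seed, {
    out <- NULL
    for (attempt in seq_len(maxRegrow)) {
      pts <- matrix(NA_real_, n, 3)
      # start near the centre so the chain has room to fold back on itself
      repeat {
        p <- stats::runif(3, -radius / 2, radius / 2)
        if (sum(p^2) <= (radius / 2)^2) break
      }
      pts[1, ] <- p
      ok <- TRUE
      for (i in 2:n) {
        placed <- FALSE
        for (try in seq_len(200L)) {
          u <- stats::rnorm(3)
          cand <- pts[i - 1, ] + bond * u / sqrt(sum(u^2))
          if (sum(cand^2) > radius^2) next
          if (i > 2L) {
            d2 <- rowSums(sweep(pts[seq_len(i - 2), , drop = FALSE], 2, cand)^2)
            if (min(d2) < minSep^2) next
          }
          pts[i, ] <- cand
          placed <- TRUE
          break
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (!ok) next
      if (.isConnected(.distMatrix(pts) <= 13)) { out <- pts; break }
    }
    out
  })
  if (is.null(xyz))
    stop("globule generation failed after ", maxRegrow,
         " attempts; consider a larger confinement radius")
  CaTrace(xyz, proteinId = proteinId)
}

#' Write / read a CaTrace as TSV
#'
#' Serializes a trace to a plain-text table with columns
#' `protein_id, chain, site_label, x, y, z, bfactor` (bfactor is `NA` when
#' absent), and reads it back.
#'
#' @param trace a [CaTrace-class].
#' @param path file path.
#' @return `writeCaTraceTsv` returns `path` invisibly; `readCaTraceTsv`
#'   returns a [CaTrace-class].
#' @export
writeCaTraceTsv <- function(trace, path) {
  b <- if (length(trace@bfactors)) trace@bfactors else NA_real_
  df <- data.frame(protein_id = trace@proteinId, chain = trace@chainId,
                   site_label = trace@siteLabels,
                   x = trace@coords[, 1], y = trace@coords[, 2],
                   z = trace@coords[, 3], bfactor = b)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCaTraceTsv
#' @export
readCaTraceTsv <- function(path) {
  df <- utils::read.delim(path, colClasses = c(site_label = "character"))
  b <- if (anyNA(df$bfactor)) numeric(0) else df$bfactor
  CaTrace(cbind(df$x, df$y, df$z), proteinId = df$protein_id[1],
          chainId = df$chain[1], siteLabels = df$site_label, bfactors = b)
}
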