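# shared fixtures, memoized so expensive objects are built once per run

.fixtures <- new.env(parent = emptyenv())

.memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

globuleFixture <- function(seed, n = 120) {
  .memo(sprintf("glob_%d_%d", n, seed), makeGlobuleTrace(n, seed = seed))
}

helixFixture <- function(n = 50) {
  .memo(sprintf("helix_%d", n), makeHelixTrace(n))
}

pfanmFixture <- function(seed, n = 120) {
  .memo(sprintf("pfanm_%d_%d", n, seed), buildPfANM(globuleFixture(seed, n)))
}

msfFixture <- function(seed, n = 120) {
  .memo(sprintf("msf_%d_%d", n, seed), computeMSF(pfanmFixture(seed, n)))
}

stressStudyFixture <- function(seed = 1) {
  .memo(sprintf("study_%d", seed),
        makeStressStudy(nProteins = 20, nSites = 120, noiseSD = 0.8, seed = seed))
}

# tiny hand-checkable geometries
twoSiteTrace <- function(d = 1) CaTrace(rbind(c(0, 0, 0), c(d, 0, 0)))

triangleTrace <- function(side = 1) {
  CaTrace(side * rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0)))
}

collinearTrace <- function() {
  CaTrace(rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0)))
}

# central-difference Hessian of the network potential: the independent
# numerical oracle for buildHessian()
numericalHessian <- function(network, h = 1e-4) {
  xyz <- coords(network)
  n <- nrow(xyz)
  m <- 3L * n
  V <- function(flat) potentialEnergy(network, matrix(flat, n, 3, byrow = TRUE))
  x0 <- as.numeric(t(xyz))
  H <- matrix(0, m, m)
  for (a in seq_len(m)) {
    for (b in a:m) {
      xa <- x0; xa[a] <- xa[a] + h; xa[b] <- xa[b] + h; vpp <- V(xa)
      xa <- x0; xa[a] <- xa[a] + h; xa[b] <- xa[b] - h; vpm <- V(xa)
      xa <- x0; xa[a] <- xa[a] - h; xa[b] <- xa[b] + h; vmp <- V(xa)
      xa <- x0; xa[a] <- xa[a] - h; xa[b] <- xa[b] - h; vmm <- V(xa)
      H[a, b] <- (vpp - vpm - vmp + vmm) / (4 * h^2)
      H[b, a] <- H[a, b]
    }
  }
  H
}

# rigid-body displacement basis: 3 translations + 3 rotations about the
# centroid, as 3N-vectors
rigidBodyModes <- function(xyz) {
  n <- nrow(xyz)
  cen <- colMeans(xyz)
  rel <- sweep(xyz, 2, cen)
  modes <- matrix(0, 3 * n, 6)
  for (ax in 1:3) modes[seq(ax, 3 * n, by = 3), ax] <- 1
  e <- diag(3)
  for (ax in 1:3) {
    rot <- t(apply(rel, 1, function(r) pracma_cross(e[ax, ], r)))
    modes[, 3 + ax] <- as.numeric(t(rot))
  }
  modes
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# undirected connectivity by breadth-first search over an adjacency matrix:
# independent oracle for the generator's connectivity guarantee
bfsConnected <- function(adj) {
  n <- nrow(adj)
  visited <- rep(FALSE, n)
  queue <- 1L
  visited[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- which(adj[v, ] & !visited)
    visited[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(visited)
}

# PDB fixture text exercising altLocs, a CA-less residue and two chains
writeIoFixturePdb <- function(path) {
  writeLines(c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00 10.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00 12.50           C",
    "ATOM      3  CA AGLY A   2      12.000   9.000  -4.000  0.40 20.00           C",
    "ATOM      4  CA BGLY A   2      12.500   9.500  -4.500  0.60 21.00           C",
    "ATOM      5  CA  SER A   3      14.000  11.000  -2.000  1.00 30.00           C",
    "ATOM      6  N   THR A   4      16.000  12.000  -1.000  1.00 15.00           N",
    "ATOM      7  CA  LEU B  10       1.000   2.000   3.000  1.00  5.00           C",
    "ATOM      8  CA  VAL B  11       4.000   5.000   6.000  1.00  6.00           C",
    "END"), path)
  path
}

writeDuplicatePdb <- function(path) {
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00 10.00           C",
    "ATOM      2  CA  GLY A   1       1.000   1.000   1.000  1.00 10.00           C",
    "ATOM      3  CA  SER A   2       4.000   4.000   4.000  1.00 10.00           C",
    "END"), path)
  path
}
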