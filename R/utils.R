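# internal helpers

# accept either a SiteVector or a plain numeric vector
.vals <- function(x) {
  if (is(x, "SiteVector")) x@values else as.numeric(x)
}

# run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched, so seeded operations compose deterministically
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# pairwise distance matrix of an N x 3 coordinate matrix
.distMatrix <- function(xyz) as.matrix(stats::dist(xyz))

.msgf <- function(...) message(sprintf(...))
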