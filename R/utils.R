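# Internal numerics shared across modules.

# Separable 3-D Gaussian smoothing with a truncated, edge-renormalized
# kernel. fwhm is in voxel units; fwhm <= 0 is the identity. Used by the
# phantom generator; deterministic.
gaussianSmooth3d <- function(a, fwhm) {
  if (fwhm <= 0) return(a)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  half <- max(1L, ceiling(3 * sigma))
  offs <- (-half):half
  kern <- exp(-offs^2 / (2 * sigma^2))
  d <- dim(a)
  smooth1 <- function(n) {
    # n x n band matrix; rows renormalized so truncation at the grid edge
    # preserves the local mean
    K <- matrix(0, n, n)
    for (r in seq_len(n)) {
      idx <- r + offs
      ok <- idx >= 1L & idx <= n
      K[r, idx[ok]] <- kern[ok] / sum(kern[ok])
    }
    K
  }
  K1 <- smooth1(d[1]); K2 <- smooth1(d[2]); K3 <- smooth1(d[3])
  a <- array(K1 %*% matrix(a, d[1], d[2] * d[3]), d)
  a <- aperm(array(K2 %*% matrix(aperm(a, c(2, 1, 3)), d[2], d[1] * d[3]),
                   c(d[2], d[1], d[3])), c(2, 1, 3))
  aperm(array(K3 %*% matrix(aperm(a, c(3, 1, 2)), d[3], d[1] * d[2]),
              c(d[3], d[1], d[2])), c(2, 3, 1))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Run expr with a local RNG state: seeds deterministically, then restores
# whatever state the caller had.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derive a stream-specific 31-bit seed from a base seed, so independent
# stages (phantom GM vs WM, split vs training) never share a stream.
deriveSeed <- function(seed, stream) {
  (as.numeric(seed) * 7919 + stream * 104729) %% 2147483647
}

stopIfNot3d <- function(data, what = "image") {
  if (length(dim(data)) != 3L)
    stop(sprintf("non-3-D %s: got %d dimensions", what,
                 length(dim(data))), call. = FALSE)
}
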