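# Internal index bookkeeping for the rank-2 and rank-4 tensor storage.
#
# D is stored as 6 unique components, W as the 15 unique components of a fully
# symmetric rank-4 tensor. Multiplicities count how often each unique
# component occurs among the 9 (resp. 81) Cartesian components, so that
# contractions and Frobenius norms over the full Cartesian tensor can be done
# on the compact storage.

.dNames <- c("xx", "yy", "zz", "xy", "xz", "yz")
.dMult  <- c(1, 1, 1, 2, 2, 2)
.dIdx   <- cbind(i = c(1L, 2L, 3L, 1L, 1L, 2L),
                 j = c(1L, 2L, 3L, 2L, 3L, 3L))

.wNames <- c("xxxx", "yyyy", "zzzz",
             "xxxy", "xxxz", "xyyy", "yyyz", "xzzz", "yzzz",
             "xxyy", "xxzz", "yyzz",
             "xxyz", "xyyz", "xyzz")
.wMult  <- c(1, 1, 1, 4, 4, 4, 4, 4, 4, 6, 6, 6, 12, 12, 12)

# powers of (nx, ny, nz) in each unique component
.wPowers <- rbind(
  c(4, 0, 0), c(0, 4, 0), c(0, 0, 4),
  c(3, 1, 0), c(3, 0, 1), c(1, 3, 0), c(0, 3, 1), c(1, 0, 3), c(0, 1, 3),
  c(2, 2, 0), c(2, 0, 2), c(0, 2, 2),
  c(2, 1, 1), c(1, 2, 1), c(1, 1, 2))
rownames(.wPowers) <- .wNames

# map an arbitrary (i,j,k,l) in 1:3^4 to the unique-component index
.wComponentIndex <- function(i, j, k, l) {
  counts <- tabulate(c(i, j, k, l), nbins = 3L)
  which(.wPowers[, 1] == counts[1] &
        .wPowers[, 2] == counts[2] &
        .wPowers[, 3] == counts[3])
}

# one representative Cartesian index per unique component
.wPowersIdx <- local({
  m <- matrix(0L, 15L, 4L)
  for (r in 1:15)
    m[r, ] <- rep.int(1:3, .wPowers[r, ])
  m
})

# lookup table: 3x3x3x3 array of unique-component indices
.wIndexArray <- local({
  a <- array(0L, dim = c(3, 3, 3, 3))
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3)
    a[i, j, k, l] <- .wComponentIndex(i, j, k, l)
  a
})

# isotropic rank-4 tensor I4_{ijkl} = (d_ij d_kl + d_ik d_jl + d_il d_jk)/3
# in 15-component storage: 1 on xxxx-type, 1/3 on xxyy-type, 0 elsewhere
.i4 <- c(1, 1, 1, rep(0, 6), 1/3, 1/3, 1/3, rep(0, 3))

.checkFinite <- function(x, what) {
  if (!all(is.finite(x)))
    stop("invalid input: non-finite ", what, " components", call. = FALSE)
  invisible(x)
}

.checkUnit <- function(n, tol = 1e-8) {
  if (length(n) != 3L || !all(is.finite(n)))
    stop("direction must be a finite 3-vector", call. = FALSE)
  if (abs(sqrt(sum(n^2)) - 1) > tol)
    stop("direction must be unit norm (|n| = 1 within ", tol, ")",
         call. = FALSE)
  invisible(n)
}

# quadratic form row: D(n) = sum(q2row(n) * d6)
.q2row <- function(n) {
  c(n[1]^2, n[2]^2, n[3]^2, 2 * n[1] * n[2], 2 * n[1] * n[3], 2 * n[2] * n[3])
}

# quartic form row: W(n) = n_i n_j n_k n_l W_ijkl = sum(q4row(n) * w15)
.q4row <- function(n) {
  .wMult * n[1]^.wPowers[, 1] * n[2]^.wPowers[, 2] * n[3]^.wPowers[, 3]
}

# design rows for a 3xN direction matrix: N x 6 and N x 15
.q2rows <- function(dirs) {
  t(apply(dirs, 2L, .q2row))
}
.q4rows <- function(dirs) {
  t(apply(dirs, 2L, .q4row))
}

# run expr with a private, reproducible RNG state; restores global state
.withSeed <- function(seed, expr) {
  seed <- as.integer(seed %% 2147483647)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# per-realization sub-seed derived from an experiment seed (kept < 2^31)
.subSeed <- function(seed, index) {
  (as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483629
}
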