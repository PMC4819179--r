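# Independent brute-force oracles: everything here works on the full 3x3
# matrix / 3x3x3x3 array via explicit index loops, never through the
# package's compact-storage code paths.

randomDiffusionTensor <- function() {
  A <- matrix(stats::rnorm(9), 3L)
  diffusionTensor(crossprod(A) / 3 + 0.1 * diag(3))
}

randomKurtosisTensor <- function(scale = 1) {
  kurtosisTensor(stats::setNames(scale * stats::rnorm(15L),
                                 c("xxxx", "yyyy", "zzzz", "xxxy", "xxxz",
                                   "xyyy", "yyyz", "xzzz", "yzzz", "xxyy",
                                   "xxzz", "yyzz", "xxyz", "xyyz", "xyzz")))
}

randomUnitVector <- function() {
  v <- stats::rnorm(3L)
  v / sqrt(sum(v^2))
}

randomRotation <- function() {
  R <- qr.Q(qr(matrix(stats::rnorm(9L), 3L)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# quartic contraction n_i n_j n_k n_l W_ijkl by 81-term loop
bruteWContraction <- function(Warr, n) {
  s <- 0
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3)
    s <- s + n[i] * n[j] * n[k] * n[l] * Warr[i, j, k, l]
  s
}

# quadratic contraction n_i n_j D_ij by 9-term loop
bruteDContraction <- function(Dmat, n) {
  s <- 0
  for (i in 1:3) for (j in 1:3) s <- s + n[i] * n[j] * Dmat[i, j]
  s
}

bruteFrobenius <- function(Warr) sqrt(sum(Warr^2))

# isotropic rank-4 tensor from deltas, full 81 components
bruteI4 <- function() {
  d <- diag(3)
  a <- array(0, dim = c(3, 3, 3, 3))
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3)
    a[i, j, k, l] <- (d[i, j] * d[k, l] + d[i, k] * d[j, l] +
                        d[i, l] * d[j, k]) / 3
  a
}

bruteKfa <- function(Warr) {
  dirsAvg <- (Warr[1, 1, 1, 1] + Warr[2, 2, 2, 2] + Warr[3, 3, 3, 3] +
                2 * (Warr[1, 1, 2, 2] + Warr[1, 1, 3, 3] +
                       Warr[2, 2, 3, 3])) / 5
  dev <- Warr - dirsAvg * bruteI4()
  nw <- bruteFrobenius(Warr)
  if (nw == 0) 0 else bruteFrobenius(dev) / nw
}

# DKI forward signal by index loops for one measurement
bruteDkiSignal <- function(S0, Dmat, Warr, b, n) {
  md <- (Dmat[1, 1] + Dmat[2, 2] + Dmat[3, 3]) / 3
  S0 * exp(-b * bruteDContraction(Dmat, n) +
             b^2 / 6 * md^2 * bruteWContraction(Warr, n))
}

# rotate a rank-4 array by explicit 8-fold loop
bruteRotateW <- function(Warr, R) {
  out <- array(0, dim = c(3, 3, 3, 3))
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3) {
    s <- 0
    for (a in 1:3) for (b in 1:3) for (cc in 1:3) for (d in 1:3)
      s <- s + R[i, a] * R[j, b] * R[k, cc] * R[l, d] * Warr[a, b, cc, d]
    out[i, j, k, l] <- s
  }
  out
}

# dense spherical direction set for quadrature oracles (Fibonacci sphere)
fibonacciSphere <- function(n = 500L) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(1 - z^2)
  rbind(r * cos(phi), r * sin(phi), z)
}

# a well-posed multi-shell scheme for fit tests
standardFitScheme <- function(nDirs = 33L, bmax = 3, bstep = 0.2,
                              seed = 5) {
  dirs <- generateDirections(nDirs, seed = seed)
  bs <- seq(bstep, bmax, by = bstep)
  acquisitionScheme(c(0, rep(bs, each = nDirs)),
                    cbind(0, dirs[, rep(seq_len(nDirs), length(bs))]))
}
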