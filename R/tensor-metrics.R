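# Closed-form scalar metrics of the diffusion and kurtosis tensors.

# vectorized internals on n x 6 / n x 15 component matrices ------------------

.mdFromD6 <- function(D6) {
  (D6[, 1] + D6[, 2] + D6[, 3]) / 3
}

.faFromD6 <- function(D6) {
  n <- nrow(D6)
  fa <- numeric(n)
  for (v in seq_len(n)) {
    lam <- eigen(.d6ToMatrix(D6[v, ]), symmetric = TRUE,
                 only.values = TRUE)$values
    fa[v] <- .faFromEigen(lam)
  }
  fa
}

.d6ToMatrix <- function(v) {
  matrix(c(v[1], v[4], v[5], v[4], v[2], v[6], v[5], v[6], v[3]), 3L, 3L)
}

.faFromEigen <- function(lam) {
  ss <- sum(lam^2)
  if (ss == 0) return(0)
  md <- mean(lam)
  min(1, sqrt(1.5 * sum((lam - md)^2) / ss))
}

.wbarFromW15 <- function(W15) {
  (W15[, 1] + W15[, 2] + W15[, 3] +
     2 * (W15[, 10] + W15[, 11] + W15[, 12])) / 5
}

.wnormFromW15 <- function(W15) {
  sqrt(as.numeric(W15^2 %*% .wMult))
}

.kfaFromW15 <- function(W15) {
  wb <- .wbarFromW15(W15)
  dev <- W15 - outer(wb, .i4)
  nw <- .wnormFromW15(W15)
  kfa <- ifelse(nw > 0, .wnormFromW15(dev) / nw, 0)
  pmin(kfa, 1)
}

# exported single-tensor operations ------------------------------------------

#' Mean diffusivity and fractional anisotropy
#'
#' MD is the eigenvalue mean (trace/3). FA is the standard normalized
#' eigenvalue dispersion sqrt(3/2) * sqrt(sum((lambda - MD)^2)) /
#' sqrt(sum(lambda^2)), population-normalized, in [0, 1]; FA = 0 is returned
#' for the all-zero tensor. Eigenvalues are not clipped: negative
#' eigenvalues (possible in noisy fits) enter the formula as-is and are
#' reported by \code{\link{fitDki}} QC flags instead.
#'
#' @param D a \code{DiffusionTensor}.
#' @return named numeric c(MD, FA).
#' @examples
#' mdFA(diffusionTensor(2, 1, 1))  # MD = 4/3, FA = 1/sqrt(6)
#' @export
mdFA <- function(D) {
  stopifnot(is(D, "DiffusionTensor"))
  lam <- eigen(tensorMatrix(D), symmetric = TRUE, only.values = TRUE)$values
  c(MD = mean(lam), FA = .faFromEigen(lam))
}

#' Mean of the kurtosis tensor
#'
#' The spherical average of the quartic contraction n_i n_j n_k n_l W_ijkl,
#' which reduces to (Wxxxx + Wyyyy + Wzzzz + 2 Wxxyy + 2 Wxxzz + 2 Wyyzz)/5.
#' Linear in W; a fast mean-kurtosis surrogate.
#'
#' @param W a \code{KurtosisTensor}.
#' @return scalar Wbar (dimensionless).
#' @export
wbar <- function(W) {
  stopifnot(is(W, "KurtosisTensor"))
  as.numeric(.wbarFromW15(matrix(W@values, 1L)))
}

#' Frobenius norm of a kurtosis tensor
#'
#' Square root of the sum of squares over all 81 Cartesian components,
#' computed from the 15-component storage via multiplicity weights (1 for
#' xxxx-type, 4 for xxxy-type, 6 for xxyy-type, 12 for xxyz-type).
#'
#' @param W a \code{KurtosisTensor}.
#' @return scalar norm.
#' @export
wnorm <- function(W) {
  stopifnot(is(W, "KurtosisTensor"))
  as.numeric(.wnormFromW15(matrix(W@values, 1L)))
}

#' Kurtosis fractional anisotropy
#'
#' KFA = ||W - Wbar * I4||_F / ||W||_F, where I4 is the isotropic rank-4
#' tensor (delta_ij delta_kl + delta_ik delta_jl + delta_il delta_jk)/3 and
#' the Frobenius norm runs over all 81 Cartesian components. KFA lies in
#' [0, 1], is invariant to rotation and to scaling of W, and is defined as 0
#' when ||W||_F = 0 so that vanishing kurtosis does not poison maps.
#'
#' @param W a \code{KurtosisTensor}.
#' @return scalar KFA in [0, 1].
#' @examples
#' kfa(kurtosisTensor(xxxx = 1))   # sqrt(0.8)
#' kfa(isotropicKurtosisTensor(3)) # 0
#' @export
kfa <- function(W) {
  stopifnot(is(W, "KurtosisTensor"))
  as.numeric(.kfaFromW15(matrix(W@values, 1L)))
}

#' Apparent diffusivity and kurtosis along one direction
#'
#' D(n) = n_i n_j D_ij and K(n) = (MD^2 / D(n)^2) * n_i n_j n_k n_l W_ijkl,
#' the directional apparent kurtosis of the DKI expansion.
#'
#' @param D a \code{DiffusionTensor}.
#' @param W a \code{KurtosisTensor}.
#' @param n unit direction (|n| = 1 within 1e-8).
#' @param eps degenerate-direction threshold: D(n) <= eps is an error.
#' @return named numeric c(D, K).
#' @export
apparentDK <- function(D, W, n, eps = 1e-12) {
  stopifnot(is(D, "DiffusionTensor"), is(W, "KurtosisTensor"))
  .checkUnit(n)
  dn <- sum(.q2row(n) * D@values)
  if (dn <= eps)
    stop("degenerate direction: D(n) <= ", eps, call. = FALSE)
  md <- (D@values[[1]] + D@values[[2]] + D@values[[3]]) / 3
  wn <- sum(.q4row(n) * W@values)
  c(D = dn, K = md^2 / dn^2 * wn)
}

#' Uniform spherical quadrature directions (Fibonacci lattice)
#'
#' Deterministic, arbitrarily dense near-uniform direction set used for
#' spherical averaging. For the directional kurtosis integrand (a rational
#' function of n when D is anisotropic) about 4000 points keep the
#' quadrature error near 1e-4.
#'
#' @param n number of points.
#' @return 3 x n matrix of unit directions.
#' @export
sphereLattice <- function(n = 4096L) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(1 - z^2)
  rbind(r * cos(phi), r * sin(phi), z)
}

# memoized default quadrature set
.mkQuadCache <- new.env(parent = emptyenv())
.mkQuadratureSet <- function() {
  if (is.null(.mkQuadCache$dirs)) .mkQuadCache$dirs <- sphereLattice(4096L)
  .mkQuadCache$dirs
}

#' Mean kurtosis by spherical averaging
#'
#' MK is the average of the apparent kurtosis K(n) over an approximately
#' uniform direction set (default: a dense 4096-point Fibonacci lattice,
#' keeping the quadrature error well below the rotation-invariance
#' tolerance of 1e-3). For isotropic D, MK converges to Wbar as the set
#' densifies.
#'
#' @param D a \code{DiffusionTensor}.
#' @param W a \code{KurtosisTensor}.
#' @param directions 3 x m unit-direction matrix, m >= 60.
#' @return scalar MK.
#' @export
meanKurtosis <- function(D, W, directions = .mkQuadratureSet()) {
  stopifnot(is(D, "DiffusionTensor"), is(W, "KurtosisTensor"))
  directions <- as.matrix(directions)
  if (nrow(directions) != 3L && ncol(directions) == 3L)
    directions <- t(directions)
  if (ncol(directions) < 60L)
    stop("mean kurtosis needs >= 60 approximately uniform directions",
         call. = FALSE)
  dn <- as.numeric(.q2rows(directions) %*% D@values)
  if (any(dn <= 1e-12))
    stop("degenerate direction: D(n) <= 1e-12", call. = FALSE)
  md <- (D@values[[1]] + D@values[[2]] + D@values[[3]]) / 3
  wn <- as.numeric(.q4rows(directions) %*% W@values)
  mean(md^2 / dn^2 * wn)
}

#' All scalar metrics of a (D, W) pair
#'
#' Convenience wrapper returning MD, FA, Wbar, MK and KFA in one call.
#'
#' @inheritParams meanKurtosis
#' @return named numeric vector.
#' @export
scalarMetrics <- function(D, W, directions = .mkQuadratureSet()) {
  m <- mdFA(D)
  c(m, Wbar = wbar(W), MK = meanKurtosis(D, W, directions), KFA = kfa(W))
}

# vectorized MK over component matrices (used for map generation)
.mkFromComponents <- function(D6, W15, dirs) {
  Q2 <- .q2rows(dirs); Q4 <- .q4rows(dirs)
  dn <- tcrossprod(D6, Q2)           # n x m directional diffusivity
  wn <- tcrossprod(W15, Q4)
  md <- .mdFromD6(D6)
  kn <- (md^2 / dn^2) * wn
  kn[dn <= 1e-12] <- NA_real_
  rowMeans(kn)
}

# rotation helpers ------------------------------------------------------------

#' Rotate tensors
#'
#' Applies a proper rotation R to the stored components: D -> R D R^T and
#' W_ijkl -> R_ia R_jb R_kc R_ld W_abcd. Scalar metrics are invariant under
#' this operation.
#'
#' @param x a \code{DiffusionTensor} or \code{KurtosisTensor}.
#' @param R 3x3 rotation matrix.
#' @return rotated tensor of the same class.
#' @export
rotateTensor <- function(x, R) {
  R <- as.matrix(R)
  stopifnot(all(dim(R) == c(3L, 3L)))
  if (is(x, "DiffusionTensor"))
    return(diffusionTensor(R %*% tensorMatrix(x) %*% t(R)))
  stopifnot(is(x, "KurtosisTensor"))
  a <- tensorArray(x)
  # contract one index at a time
  for (ax in 1:4) {
    a <- apply(a, setdiff(1:4, ax), function(v) R %*% v)
    a <- aperm(a, append(2:4, 1, after = ax - 1))
  }
  v <- a[cbind(.wPowersIdx[, 1], .wPowersIdx[, 2],
               .wPowersIdx[, 3], .wPowersIdx[, 4])]
  kurtosisTensor(stats::setNames(v, .wNames))
}
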