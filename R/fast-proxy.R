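# Closed-form two-shell per-direction (D, K) estimation and the std/rms KFA
# proxy. The inversion uses only three signals per direction (b = 0 and the
# two shells), so the proxy needs no tensor fit at all.

#' Two-shell apparent diffusivity and kurtosis along one direction
#'
#' Exact inversion of the single-direction DKI expansion from signals at
#' b = 0, b1 and b2: with y1 = ln(S1/S0), y2 = ln(S2/S0),
#' D = (b1^2 y2 - b2^2 y1) / (b1 b2 (b2 - b1)) and
#' K = 6 (b1 y2 - b2 y1) / (D^2 b1 b2 (b2 - b1)).
#' All arguments are vectorized over directions/voxels.
#'
#' Non-positive signals or D <= eps yield a masked entry (validity FALSE,
#' values NA) rather than an error, so single bad directions do not void a
#' voxel at low SNR.
#'
#' @param S0,S1,S2 signals at b = 0 and the two shells.
#' @param b1,b2 shell b-values, 0 < b1 < b2 (ms/um^2).
#' @param eps degenerate-diffusivity threshold.
#' @return data.frame with columns D, K, valid.
#' @examples
#' s <- exp(c(0, -1 + 1/6, -2.5 + 6.25/6))  # D = 1, K = 1
#' twoShellDK(s[1], s[2], s[3], 1, 2.5)
#' @export
twoShellDK <- function(S0, S1, S2, b1, b2, eps = 1e-12) {
  if (length(b1) != 1L || length(b2) != 1L || !is.finite(b1) ||
      !is.finite(b2) || b1 <= 0 || b2 <= 0)
    stop("invalid scheme: shell b-values must be positive scalars",
         call. = FALSE)
  if (b1 == b2)
    stop("invalid scheme: b1 = b2 is not a valid combination", call. = FALSE)
  if (b1 > b2) stop("invalid scheme: need b1 < b2", call. = FALSE)
  valid <- is.finite(S0) & is.finite(S1) & is.finite(S2) &
    S0 > 0 & S1 > 0 & S2 > 0
  y1 <- ifelse(valid, log(S1 / S0), NA_real_)
  y2 <- ifelse(valid, log(S2 / S0), NA_real_)
  den <- b1 * b2 * (b2 - b1)
  D <- (b1^2 * y2 - b2^2 * y1) / den
  valid <- valid & is.finite(D) & D > eps
  D[!valid] <- NA_real_
  K <- 6 * (b1 * y2 - b2 * y1) / (D^2 * den)
  K[!valid] <- NA_real_
  data.frame(D = D, K = K, valid = valid)
}

#' KFA proxy from directional kurtosis values
#'
#' The proxy is std(K)/rms(K) over the valid directions, with population
#' (1/N) normalization in both the standard deviation and the
#' root-mean-square. It is 0 when all K are equal or when rms(K) = 0, and by
#' construction never exceeds 1 (std <= rms). No calibration to the true KFA
#' scale is applied; the two ranges are not expected to coincide.
#'
#' Negative K values are retained in the statistic (discarding them would
#' bias the proxy upward); callers may inspect the \code{valid} mask of
#' \code{\link{twoShellDK}} for per-direction failures.
#'
#' @param K per-direction apparent kurtosis values (NAs treated as invalid).
#' @param valid optional logical mask; masked-out entries are excluded.
#' @return scalar proxy value in [0, 1] for non-negative K patterns (and
#'   always <= 1).
#' @export
kfaProxy <- function(K, valid = NULL) {
  K <- as.numeric(K)
  if (is.null(valid)) valid <- !is.na(K)
  K <- K[valid & !is.na(K)]
  n <- length(K)
  if (n < 3L)
    stop("insufficient data: need >= 3 valid directional kurtosis values",
         call. = FALSE)
  rms2 <- mean(K^2)
  if (rms2 == 0) return(0)
  v <- mean((K - mean(K))^2)
  sqrt(v / rms2)
}

#' KFA proxy map over a voxel block
#'
#' Applies the two-shell inversion and the std/rms proxy to every voxel of a
#' signal block laid out as 1 + 2N measurements per voxel (b = 0, then shell
#' 1, then shell 2, both along the scheme's N directions). Voxels with fewer
#' than \code{minDirs} valid directions are masked (NA proxy). CSF-like
#' voxels can be removed afterwards by the caller via any external mask.
#'
#' @param volume n_voxel x (1 + 2N) signal matrix (or a vector for a single
#'   voxel).
#' @param scheme a \code{TwoShellScheme} with N directions.
#' @param minDirs minimum number of valid directions per voxel.
#' @param eps degenerate-diffusivity threshold passed to the inversion.
#' @return list with \code{proxy} (numeric per voxel), \code{valid} (logical
#'   per voxel) and \code{nValid} (valid direction count per voxel).
#' @export
proxyMap <- function(volume, scheme, minDirs = 3L, eps = 1e-12) {
  stopifnot(is(scheme, "TwoShellScheme"))
  if (is.null(dim(volume))) volume <- matrix(volume, 1L)
  volume <- as.matrix(volume)
  n <- ncol(scheme@directions)
  if (ncol(volume) != 1L + 2L * n)
    stop("invalid input: volume has ", ncol(volume),
         " measurements per voxel, scheme needs ", 1L + 2L * n, call. = FALSE)
  S0 <- volume[, 1L]
  S1 <- volume[, 1L + seq_len(n), drop = FALSE]
  S2 <- volume[, 1L + n + seq_len(n), drop = FALSE]
  ok <- is.finite(S0) & S0 > 0
  posS <- S1 > 0 & S2 > 0 & is.finite(S1) & is.finite(S2)
  y1 <- log(pmax(S1, .Machine$double.xmin) / S0)
  y2 <- log(pmax(S2, .Machine$double.xmin) / S0)
  b1 <- scheme@b1; b2 <- scheme@b2
  den <- b1 * b2 * (b2 - b1)
  D <- (b1^2 * y2 - b2^2 * y1) / den
  validDir <- posS & ok & is.finite(D) & D > eps
  K <- 6 * (b1 * y2 - b2 * y1) / (D^2 * den)
  K[!validDir] <- NA_real_
  nValid <- rowSums(validDir)
  # population std / rms over valid directions, rowwise
  mu <- rowMeans(K, na.rm = TRUE)
  m2 <- rowMeans(K^2, na.rm = TRUE)
  varp <- m2 - mu^2
  proxy <- ifelse(m2 > 0, sqrt(pmax(varp, 0) / m2), 0)
  bad <- nValid < minDirs
  proxy[bad] <- NA_real_
  list(proxy = unname(proxy), valid = unname(!bad), nValid = unname(nValid))
}
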