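# Reusable evaluation procedures: correlation, image statistics, FA-based
# tissue segmentation, the fiber-mixing metric curves and the
# average-then-fit comparison.

#' Pearson correlation with strict preconditions
#'
#' Standard linear correlation coefficient; errors (rather than returning
#' NA) on unequal lengths, fewer than three pairs, or zero variance in
#' either argument.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return scalar r in [-1, 1].
#' @export
pearson <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    stop("invalid input: x and y lengths differ", call. = FALSE)
  if (length(x) < 3L)
    stop("invalid input: need >= 3 pairs", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("undefined correlation: zero variance", call. = FALSE)
  stats::cor(x, y)
}

#' RMS contrast of a scalar map
#'
#' Min-max normalizes the map to [0, 1] and returns the population standard
#' deviation of the normalized intensities. Invariant to affine intensity
#' transforms a*M + c with a > 0; 0 for a constant map.
#'
#' @param map numeric array/vector of intensities.
#' @return scalar RMS contrast.
#' @export
rmsContrast <- function(map) {
  v <- as.numeric(map)
  v <- v[is.finite(v)]
  if (!length(v)) stop("invalid input: empty map", call. = FALSE)
  rng <- range(v)
  if (rng[1] == rng[2]) return(0)
  z <- (v - rng[1]) / (rng[2] - rng[1])
  sqrt(mean((z - mean(z))^2))
}

#' SNR with Rayleigh background correction
#'
#' SNR = mean(object) / (sd(background) / sqrt(2 - pi/2)): the background
#' standard deviation of a magnitude (Rayleigh-distributed) noise region is
#' converted back to the underlying Gaussian sigma before dividing.
#'
#' @param image numeric array of magnitude intensities.
#' @param objectMask logical mask of a homogeneous object region.
#' @param backgroundMask logical mask of a signal-free background region.
#' @return scalar SNR.
#' @export
estimateSnr <- function(image, objectMask, backgroundMask) {
  objectMask <- as.logical(objectMask); backgroundMask <- as.logical(backgroundMask)
  if (!any(objectMask, na.rm = TRUE) || !any(backgroundMask, na.rm = TRUE))
    stop("invalid input: empty mask", call. = FALSE)
  obj <- as.numeric(image)[which(objectMask)]
  bg <- as.numeric(image)[which(backgroundMask)]
  sdBg <- stats::sd(bg)
  if (!is.finite(sdBg) || sdBg == 0)
    stop("undefined SNR: zero background standard deviation", call. = FALSE)
  mean(obj) / (sdBg / sqrt(2 - pi / 2))
}

#' FA-based tissue segmentation
#'
#' Strict-inequality bands: gray-matter-like voxels have 0.1 < FA < 0.3,
#' white-matter-like voxels 0.6 < FA < 1. Voxels in [0.3, 0.6], at or below
#' 0.1, or at/above 1 belong to neither mask.
#'
#' @param faMap numeric FA values in [0, 1].
#' @return list with logical masks \code{wm} and \code{gm}.
#' @export
faSegmentation <- function(faMap) {
  fa <- as.numeric(faMap)
  out <- list(wm = fa > 0.6 & fa < 1, gm = fa > 0.1 & fa < 0.3)
  out$wm[!is.finite(fa)] <- FALSE
  out$gm[!is.finite(fa)] <- FALSE
  out
}

# default multi-b fitting scheme for the mixing sweep: b = 0..3 ms/um^2 in
# steps of 0.2, each nonzero shell along the packaged 36-direction set
.mixtureFitScheme <- function() {
  dirs <- loadDirections("36")
  bs <- seq(0.2, 3, by = 0.2)
  bvals <- c(0, rep(bs, each = ncol(dirs)))
  bvecs <- cbind(0, dirs[, rep(seq_len(ncol(dirs)), length(bs))])
  acquisitionScheme(bvals, bvecs)
}

#' Fiber-mixing metric curves
#'
#' Reproduces the tissue-complexity experiment: signals from three single
#' fibers along x, y and z are mixed as (1 - 2a) Sx + a Sy + a Sz over a
#' grid of mixing levels a in [0, 1/3], the DKI model is fitted to each
#' mixture, and MD, FA, Wbar, KFA plus the nine-direction two-shell proxy
#' are tabulated against the volume fraction index VI. Metrics are also
#' returned normalized to their per-sweep maxima, the form in which the
#' FA-vanishing/KFA-surviving contrast is usually displayed.
#'
#' @param kernels list of three \code{VoxelModel}s for the x, y and z fiber
#'   bundles (default: \code{\link{defaultFiberVoxel}} along each axis).
#' @param alphas mixing grid in [0, 1/3]; the default covers 0 to 0.33 in
#'   steps of 0.03 plus the exact equal-mixture endpoint 1/3.
#' @param scheme multi-shell fitting scheme (default b = 0..3 in 0.2 steps
#'   along the 36-direction set).
#' @param proxyScheme \code{TwoShellScheme} for the proxy curve (default
#'   nine directions, b1 = 1, b2 = 2.5 ms/um^2).
#' @param method fit method passed to \code{\link{fitDki}}.
#' @return data.frame with columns alpha, VI, MD, FA, Wbar, KFA, proxy,
#'   converged and their max-normalized versions (prefix "n").
#' @export
mixtureSweep <- function(kernels = NULL,
                         alphas = c(seq(0, 0.33, by = 0.03), 1 / 3),
                         scheme = .mixtureFitScheme(),
                         proxyScheme = twoShellScheme(1.0, 2.5,
                                                      loadDirections("9")),
                         method = "nlls") {
  if (is.null(kernels)) {
    axes <- diag(3)
    kernels <- lapply(1:3, function(a) defaultFiberVoxel(axes[, a]))
  }
  stopifnot(length(kernels) == 3L)
  if (any(alphas < 0 | alphas > 1 / 3 + 1e-12))
    stop("invalid parameter: alpha grid must lie in [0, 1/3]", call. = FALSE)
  S <- lapply(kernels, exactGaussianSignal, scheme = scheme)
  Sp <- lapply(kernels, exactGaussianSignal, scheme = proxyScheme)
  rows <- lapply(alphas, function(a) {
    sm <- mixSignals(S[[1]], S[[2]], S[[3]], a)
    fit <- fitDki(sm, scheme, method = method)
    m <- mdFA(fit@D)
    spm <- mixSignals(Sp[[1]], Sp[[2]], Sp[[3]], a)
    px <- proxyMap(spm, proxyScheme)$proxy
    data.frame(alpha = a,
               VI = volumeFractionIndex(c(1 - 2 * a, a, a)),
               MD = unname(m["MD"]), FA = unname(m["FA"]),
               Wbar = wbar(fit@W), KFA = kfa(fit@W), proxy = px,
               converged = fit@converged)
  })
  out <- do.call(rbind, rows)
  for (col in c("MD", "FA", "Wbar", "KFA", "proxy"))
    out[[paste0("n", col)]] <- out[[col]] / max(out[[col]])
  out
}

#' Average-then-fit versus fit-then-average
#'
#' Compares two estimates over a voxel mask: (i) average the signal of each
#' diffusion encoding across the mask, then fit the DKI model once
#' ("averageThenFit" - mimicking a low-resolution voxel containing all fiber
#' orientations); (ii) fit every voxel and average the resulting parameter
#' maps ("fitThenAverage"). On heterogeneous fiber arrangements FA collapses
#' under (i) while KFA is reduced far less and Wbar tends to increase.
#'
#' @param volume n_voxel x m signal matrix.
#' @param mask logical vector selecting the voxels to average.
#' @param scheme matching \code{AcquisitionScheme}.
#' @param method fit method.
#' @return data.frame with one row per metric (MD, FA, Wbar, KFA) and
#'   columns \code{averageThenFit} and \code{fitThenAverage}.
#' @export
averageThenFit <- function(volume, mask, scheme, method = "nlls") {
  volume <- as.matrix(volume)
  mask <- as.logical(mask)
  if (!any(mask)) stop("invalid input: empty mask", call. = FALSE)
  avgSignal <- colMeans(volume[mask, , drop = FALSE])
  fitA <- fitDki(avgSignal, scheme, method = method)
  mA <- mdFA(fitA@D)
  a <- c(MD = unname(mA["MD"]), FA = unname(mA["FA"]),
         Wbar = wbar(fitA@W), KFA = kfa(fitA@W))
  fits <- fitDkiMany(volume[mask, , drop = FALSE], scheme, method = method)
  b <- c(MD = mean(fits$metrics$MD), FA = mean(fits$metrics$FA),
         Wbar = mean(fits$metrics$Wbar), KFA = mean(fits$metrics$KFA))
  data.frame(metric = names(a), averageThenFit = unname(a),
             fitThenAverage = unname(b))
}
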