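#' @import methods
NULL

#' Rank-2 diffusion tensor
#'
#' Symmetric 3x3 diffusion tensor stored as its six unique components
#' (xx, yy, zz, xy, xz, yz) in units of um^2/ms. Symmetry is guaranteed by
#' construction; eigenvalues may be negative for noisy fits (flagged by
#' downstream QC, never rejected here).
#'
#' @slot values named numeric(6), components in um^2/ms.
#' @export
setClass("DiffusionTensor", representation(values = "numeric"),
         validity = function(object) {
  if (length(object@values) != 6L)
    return("diffusion tensor needs exactly 6 unique components")
  if (!all(is.finite(object@values)))
    return("diffusion tensor components must be finite")
  TRUE
})

#' Fully symmetric rank-4 kurtosis tensor
#'
#' Dimensionless kurtosis tensor W stored as its 15 unique components,
#' indexed by sorted multi-index (xxxx, yyyy, zzzz, xxxy, xxxz, xyyy, yyyz,
#' xzzz, yzzz, xxyy, xxzz, yyzz, xxyz, xyyz, xyzz). Full permutation symmetry
#' of the 81 Cartesian components is implied by the storage.
#'
#' @slot values named numeric(15), dimensionless.
#' @export
setClass("KurtosisTensor", representation(values = "numeric"),
         validity = function(object) {
  if (length(object@values) != 15L)
    return("kurtosis tensor needs exactly 15 unique components")
  if (!all(is.finite(object@values)))
    return("kurtosis tensor components must be finite")
  TRUE
})

#' Diffusion acquisition scheme
#'
#' A list of measurements, each a (b-value, unit direction) pair. b-values in
#' ms/um^2; directions are unit 3-vectors (zero vectors allowed where b = 0).
#'
#' @slot bvals numeric vector of b-values (ms/um^2).
#' @slot bvecs 3 x n matrix of directions, one column per measurement.
#' @export
setClass("AcquisitionScheme",
         representation(bvals = "numeric", bvecs = "matrix"),
         validity = function(object) {
  b <- object@bvals; v <- object@bvecs
  if (!is.numeric(v) || nrow(v) != 3L)
    return("bvecs must be a 3 x n numeric matrix")
  if (ncol(v) != length(b))
    return("bvals and bvecs describe different numbers of measurements")
  if (any(!is.finite(b)) || any(!is.finite(v)))
    return("scheme entries must be finite")
  if (any(b < 0))
    return("b-values must be non-negative")
  nrm <- sqrt(colSums(v^2))
  bad <- b > 0 & abs(nrm - 1) > 1e-6
  if (any(bad))
    return(sprintf("%d non-unit directions at b > 0", sum(bad)))
  if (any(b == 0 & nrm > 1e-6 & abs(nrm - 1) > 1e-6))
    return("b = 0 directions must be zero or unit vectors")
  TRUE
})

#' Two-shell acquisition scheme
#'
#' Special case used for fast kurtosis estimation: one b = 0 image plus the
#' same N directions measured on two shells b1 < b2.
#'
#' @slot b1 inner-shell b-value (ms/um^2).
#' @slot b2 outer-shell b-value (ms/um^2).
#' @slot directions 3 x N matrix of unit directions shared by both shells.
#' @export
setClass("TwoShellScheme",
         representation(b1 = "numeric", b2 = "numeric", directions = "matrix"),
         validity = function(object) {
  if (length(object@b1) != 1L || length(object@b2) != 1L ||
      !is.finite(object@b1) || !is.finite(object@b2))
    return("b1 and b2 must be finite scalars")
  if (object@b1 <= 0 || object@b2 <= 0)
    return("shell b-values must be positive")
  if (object@b1 == object@b2)
    return("invalid scheme: b1 = b2 is not a valid combination")
  if (object@b1 > object@b2)
    return("invalid scheme: need b1 < b2")
  d <- object@directions
  if (nrow(d) != 3L || ncol(d) < 3L)
    return("need a 3 x N direction matrix with N >= 3")
  if (any(abs(sqrt(colSums(d^2)) - 1) > 1e-6))
    return("shell directions must be unit vectors")
  TRUE
})

#' Axially symmetric fiber compartment
#'
#' One Gaussian compartment of a voxel model: a cylinder-symmetric diffusion
#' kernel with axial diffusivity d_par, radial diffusivity d_perp (um^2/ms)
#' along a unit orientation, occupying a volume fraction of the voxel.
#'
#' @slot orientation unit 3-vector.
#' @slot dpar axial diffusivity (um^2/ms).
#' @slot dperp radial diffusivity (um^2/ms).
#' @slot fraction volume fraction in [0, 1].
#' @export
setClass("FiberCompartment",
         representation(orientation = "numeric", dpar = "numeric",
                        dperp = "numeric", fraction = "numeric"),
         validity = function(object) {
  if (abs(sqrt(sum(object@orientation^2)) - 1) > 1e-8)
    return("orientation must be a unit vector")
  if (object@dperp < 0 || object@dpar < object@dperp)
    return("need d_par >= d_perp >= 0")
  if (object@fraction < 0 || object@fraction > 1)
    return("fraction must lie in [0, 1]")
  TRUE
})

#' Multi-compartment Gaussian voxel model
#'
#' A mixture of Gaussian compartments (anisotropic fibers and optionally an
#' isotropic pool), with fractions summing to one. The mixture has
#' analytically exact DKI cumulant tensors (see \code{mixtureCumulants}).
#'
#' @slot compartments list of \code{FiberCompartment}.
#' @export
setClass("VoxelModel", representation(compartments = "list"),
         validity = function(object) {
  if (length(object@compartments) < 1L)
    return("voxel model needs at least one compartment")
  ok <- vapply(object@compartments, is, logical(1), "FiberCompartment")
  if (!all(ok))
    return("compartments must all be FiberCompartment objects")
  f <- vapply(object@compartments, function(c) c@fraction, numeric(1))
  if (abs(sum(f) - 1) > 1e-9)
    return("compartment fractions must sum to 1")
  TRUE
})

#' Synthetic voxel population with exact ground truth
#'
#' Result of \code{syntheticPopulation}: per-voxel mixture models together
#' with their exact cumulant tensors (rows of D in 6-component storage, rows
#' of W in 15-component storage) and precomputed scalar metrics.
#'
#' @slot models list of \code{VoxelModel}.
#' @slot D n x 6 matrix of diffusion-tensor components (um^2/ms).
#' @slot W n x 15 matrix of kurtosis-tensor components.
#' @slot metrics data.frame with columns MD, FA, Wbar, KFA per voxel.
#' @slot profile generation profile used.
#' @slot seed RNG seed used.
#' @export
setClass("VoxelPopulation",
         representation(models = "list", D = "matrix", W = "matrix",
                        metrics = "data.frame", profile = "character",
                        seed = "numeric"),
         validity = function(object) {
  n <- length(object@models)
  if (nrow(object@D) != n || nrow(object@W) != n || nrow(object@metrics) != n)
    return("ground-truth arrays must have one row per voxel")
  if (ncol(object@D) != 6L || ncol(object@W) != 15L)
    return("D must be n x 6 and W n x 15")
  TRUE
})

#' Voxel-wise DKI fit result
#'
#' @slot s0 fitted b = 0 signal (original signal scale).
#' @slot D fitted \code{DiffusionTensor}.
#' @slot W fitted \code{KurtosisTensor}.
#' @slot residual residual norm of the normalized-signal fit.
#' @slot converged logical convergence flag.
#' @slot qc named logical QC flags (negative eigenvalue, strongly negative
#'   directional kurtosis).
#' @slot method fit method used ("nlls" or "wls").
#' @export
setClass("DkiFit",
         representation(s0 = "numeric", D = "DiffusionTensor",
                        W = "KurtosisTensor", residual = "numeric",
                        converged = "logical", qc = "logical",
                        method = "character"),
         validity = function(object) {
  if (isTRUE(object@converged) && !is.finite(object@residual))
    return("converged fits must report a finite residual norm")
  TRUE
})

#' Monte-Carlo sweep result grid
#'
#' Mean Pearson correlation between true KFA and the two-shell proxy on a
#' grid of sweep axes (direction count x SNR, or b1 x b2), with per-cell
#' dispersion across noise realizations.
#'
#' @slot axis1 values of the first sweep axis.
#' @slot axis2 values of the second sweep axis.
#' @slot meanR matrix (length(axis1) x length(axis2)) of mean correlations.
#' @slot sdR matching matrix of across-realization standard deviations.
#' @slot flagged logical matrix marking cells where more than half of the
#'   voxels were invalid (or that are undefined, e.g. b1 >= b2).
#' @slot nRealizations realizations per cell.
#' @slot seed experiment seed.
#' @slot axisNames names of the two axes.
#' @export
setClass("SweepResult",
         representation(axis1 = "numeric", axis2 = "numeric",
                        meanR = "matrix", sdR = "matrix",
                        flagged = "matrix",
                        nRealizations = "numeric", seed = "numeric",
                        axisNames = "character"),
         validity = function(object) {
  if (!all(dim(object@meanR) == c(length(object@axis1),
                                  length(object@axis2))))
    return("grid shape must match the axes")
  r <- object@meanR[is.finite(object@meanR)]
  if (length(r) && (any(r < -1 - 1e-9) || any(r > 1 + 1e-9)))
    return("correlations must lie in [-1, 1]")
  TRUE
})

#' 4-D diffusion data set with its acquisition scheme
#'
#' @slot image 4-D signal array (x, y, z, measurement).
#' @slot scheme matching \code{AcquisitionScheme}.
#' @slot header NIfTI header template (or NULL-like empty list) carried
#'   through unchanged on write.
#' @slot mask optional logical 3-D array.
#' @slot meta provenance list (seed, config, source paths).
#' @export
setClass("DatasetBundle",
         representation(image = "array", scheme = "AcquisitionScheme",
                        header = "ANY", mask = "ANY", meta = "list"),
         validity = function(object) {
  d <- dim(object@image)
  if (length(d) != 4L)
    return("image must be a 4-D array")
  if (d[4] != length(object@scheme@bvals))
    return("4th image axis must match the scheme length")
  TRUE
})
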