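#' Create a diffusion tensor from its six unique components
#'
#' @param xx,yy,zz,xy,xz,yz tensor components in um^2/ms. Alternatively pass
#'   a symmetric 3x3 matrix or a length-6 vector (order xx, yy, zz, xy, xz,
#'   yz) as \code{xx}.
#' @return a \code{DiffusionTensor}.
#' @examples
#' diffusionTensor(2, 1, 1)            # diag(2, 1, 1)
#' diffusionTensor(diag(3))            # isotropic, d = 1
#' @export
diffusionTensor <- function(xx, yy = 0, zz = 0, xy = 0, xz = 0, yz = 0) {
  if (is.matrix(xx)) {
    m <- xx
    stopifnot(all(dim(m) == c(3L, 3L)))
    if (max(abs(m - t(m))) > 1e-8)
      stop("matrix must be symmetric", call. = FALSE)
    v <- c(m[1, 1], m[2, 2], m[3, 3], m[1, 2], m[1, 3], m[2, 3])
  } else if (length(xx) == 6L) {
    v <- as.numeric(xx)
  } else {
    v <- c(xx, yy, zz, xy, xz, yz)
  }
  names(v) <- .dNames
  .checkFinite(v, "diffusion tensor")
  new("DiffusionTensor", values = v)
}

#' Create a kurtosis tensor from its 15 unique components
#'
#' Components are named by sorted multi-index; unnamed arguments are taken in
#' the canonical order xxxx, yyyy, zzzz, xxxy, xxxz, xyyy, yyyz, xzzz, yzzz,
#' xxyy, xxzz, yyzz, xxyz, xyyz, xyzz. Missing components default to zero.
#'
#' @param ... named unique components (e.g. \code{xxxx = 1, xxyy = 1/3}), or
#'   a single length-15 vector in canonical order.
#' @return a \code{KurtosisTensor}.
#' @examples
#' kurtosisTensor(xxxx = 1)
#' isotropicKurtosisTensor(1)    # the rank-4 isotropic tensor
#' @export
kurtosisTensor <- function(...) {
  args <- list(...)
  v <- stats::setNames(numeric(15L), .wNames)
  if (length(args) == 1L && is.null(names(args)) &&
      length(args[[1L]]) == 15L) {
    v[] <- as.numeric(args[[1L]])
  } else if (length(args)) {
    nm <- names(args)
    if (is.null(nm) || any(nm == ""))
      stop("components must be named (e.g. xxxx = 1)", call. = FALSE)
    bad <- setdiff(nm, .wNames)
    if (length(bad))
      stop("unknown component(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    v[nm] <- vapply(args, as.numeric, numeric(1))
  }
  .checkFinite(v, "kurtosis tensor")
  new("KurtosisTensor", values = v)
}

#' @rdname kurtosisTensor
#' @param scale multiple of the isotropic rank-4 tensor I4.
#' @export
isotropicKurtosisTensor <- function(scale = 1) {
  kurtosisTensor(stats::setNames(scale * .i4, .wNames))
}

#' Build an acquisition scheme
#'
#' @param bvals numeric b-values (ms/um^2).
#' @param bvecs 3 x n or n x 3 matrix of directions (zero rows allowed at
#'   b = 0).
#' @return an \code{AcquisitionScheme}.
#' @export
acquisitionScheme <- function(bvals, bvecs) {
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != 3L && ncol(bvecs) == 3L) bvecs <- t(bvecs)
  new("AcquisitionScheme", bvals = as.numeric(bvals), bvecs = bvecs)
}

#' Build a two-shell scheme
#'
#' @param b1,b2 shell b-values with 0 < b1 < b2 (ms/um^2).
#' @param directions 3 x N or N x 3 unit-direction matrix shared by both
#'   shells, or an integer count resolved via \code{loadDirections}.
#' @return a \code{TwoShellScheme}.
#' @export
twoShellScheme <- function(b1, b2, directions) {
  if (length(directions) == 1L && is.numeric(directions))
    directions <- loadDirections(as.character(directions))
  directions <- as.matrix(directions)
  if (nrow(directions) != 3L && ncol(directions) == 3L)
    directions <- t(directions)
  new("TwoShellScheme", b1 = as.numeric(b1), b2 = as.numeric(b2),
      directions = directions)
}

#' Expand a two-shell scheme to a full measurement list
#'
#' Layout is one b = 0 measurement followed by shell 1 then shell 2, both
#' along the same directions (1 + 2N measurements).
#'
#' @param x a \code{TwoShellScheme}.
#' @return an \code{AcquisitionScheme}.
#' @export
asAcquisitionScheme <- function(x) {
  stopifnot(is(x, "TwoShellScheme"))
  n <- ncol(x@directions)
  acquisitionScheme(c(0, rep(x@b1, n), rep(x@b2, n)),
                    cbind(0, x@directions, x@directions))
}

#' @rdname fiberCompartment
#' @export
fiberCompartment <- function(orientation, dpar, dperp, fraction = 1) {
  orientation <- as.numeric(orientation)
  nrm <- sqrt(sum(orientation^2))
  if (nrm > 0) orientation <- orientation / nrm
  new("FiberCompartment", orientation = orientation, dpar = dpar,
      dperp = dperp, fraction = fraction)
}

#' Create fiber compartments and voxel models
#'
#' \code{fiberCompartment} describes one axially symmetric Gaussian
#' compartment; \code{voxelModel} bundles compartments into a mixture whose
#' fractions must sum to one. \code{isotropicCompartment} is a convenience
#' for a spherical pool (d_par = d_perp).
#'
#' @param orientation 3-vector (normalized internally).
#' @param dpar,dperp axial/radial diffusivities (um^2/ms).
#' @param fraction volume fraction.
#' @param ... \code{FiberCompartment} objects (or a single list of them).
#' @return \code{voxelModel} returns a \code{VoxelModel}.
#' @examples
#' voxelModel(fiberCompartment(c(1, 0, 0), 2, 0.4, 0.5),
#'            fiberCompartment(c(0, 1, 0), 2, 0.4, 0.5))
#' @export
voxelModel <- function(...) {
  comps <- list(...)
  if (length(comps) == 1L && is.list(comps[[1L]]) &&
      !is(comps[[1L]], "FiberCompartment"))
    comps <- comps[[1L]]
  new("VoxelModel", compartments = comps)
}

#' @rdname fiberCompartment
#' @param d isotropic diffusivity (um^2/ms).
#' @export
isotropicCompartment <- function(d, fraction = 1) {
  fiberCompartment(c(0, 0, 1), d, d, fraction)
}

# ---- accessors ------------------------------------------------------------

#' Tensor component accessors
#'
#' @param x a \code{DiffusionTensor} or \code{KurtosisTensor}.
#' @return named numeric vector of unique components.
#' @export
tensorValues <- function(x) x@values

#' @describeIn tensorValues full symmetric 3x3 matrix of a diffusion tensor.
#' @export
tensorMatrix <- function(x) {
  stopifnot(is(x, "DiffusionTensor"))
  v <- x@values
  matrix(c(v["xx"], v["xy"], v["xz"],
           v["xy"], v["yy"], v["yz"],
           v["xz"], v["yz"], v["zz"]), 3L, 3L,
         dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
}

#' @describeIn tensorValues full 3x3x3x3 Cartesian array of a kurtosis
#'   tensor (all 81 components populated by symmetry).
#' @export
tensorArray <- function(x) {
  stopifnot(is(x, "KurtosisTensor"))
  array(x@values[.wIndexArray], dim = c(3, 3, 3, 3))
}

#' Scheme accessors
#'
#' @param x an \code{AcquisitionScheme} or \code{TwoShellScheme}.
#' @return \code{bValues}: numeric b-values; \code{bVectors}: 3 x n direction
#'   matrix; \code{shells}: sorted unique b-values with measurement counts.
#' @export
bValues <- function(x) {
  if (is(x, "TwoShellScheme")) return(c(b1 = x@b1, b2 = x@b2))
  x@bvals
}

#' @rdname bValues
#' @export
bVectors <- function(x) {
  if (is(x, "TwoShellScheme")) return(x@directions)
  x@bvecs
}

#' @rdname bValues
#' @export
shells <- function(x) {
  if (is(x, "TwoShellScheme")) x <- asAcquisitionScheme(x)
  tab <- table(x@bvals)
  data.frame(b = as.numeric(names(tab)), n = as.integer(tab))
}

#' Population accessors
#'
#' @param x a \code{VoxelPopulation}.
#' @return \code{trueMetrics}: per-voxel data.frame of MD, FA, Wbar, KFA;
#'   \code{groundTruth}: list with D (n x 6) and W (n x 15) matrices.
#' @export
trueMetrics <- function(x) x@metrics

#' @rdname trueMetrics
#' @export
groundTruth <- function(x) list(D = x@D, W = x@W)

# ---- show methods ---------------------------------------------------------

setMethod("show", "DiffusionTensor", function(object) {
  cat("DiffusionTensor (um^2/ms)\n")
  print(round(tensorMatrix(object), 6))
})

setMethod("show", "KurtosisTensor", function(object) {
  cat("KurtosisTensor, 15 unique components\n")
  print(round(object@values, 6))
})

setMethod("show", "AcquisitionScheme", function(object) {
  s <- shells(object)
  cat(sprintf("AcquisitionScheme: %d measurements, %d shells\n",
              length(object@bvals), nrow(s)))
  cat("  b (ms/um^2):",
      paste(sprintf("%g (x%d)", s$b, s$n), collapse = ", "), "\n")
})

setMethod("show", "TwoShellScheme", function(object) {
  cat(sprintf("TwoShellScheme: b1 = %g, b2 = %g ms/um^2, %d directions\n",
              object@b1, object@b2, ncol(object@directions)))
})

setMethod("show", "VoxelModel", function(object) {
  f <- vapply(object@compartments, function(c) c@fraction, numeric(1))
  cat(sprintf("VoxelModel: %d compartments (fractions %s)\n",
              length(f), paste(round(f, 3), collapse = ", ")))
})

setMethod("show", "VoxelPopulation", function(object) {
  cat(sprintf("VoxelPopulation: %d voxels, profile '%s', seed %g\n",
              length(object@models), object@profile, object@seed))
  cat(sprintf("  FA  median %.3f, KFA median %.3f\n",
              stats::median(object@metrics$FA),
              stats::median(object@metrics$KFA)))
})

setMethod("show", "DkiFit", function(object) {
  cat(sprintf("DkiFit (%s): S0 = %.4g, residual = %.3g, converged = %s\n",
              object@method, object@s0, object@residual, object@converged))
  if (any(object@qc))
    cat("  QC flags:", paste(names(object@qc)[object@qc], collapse = ", "),
        "\n")
})

setMethod("show", "SweepResult", function(object) {
  cat(sprintf("SweepResult: %s x %s grid (%d x %d), %d realizations\n",
              object@axisNames[1], object@axisNames[2],
              length(object@axis1), length(object@axis2),
              object@nRealizations))
  cat(sprintf("  mean r range: %.3f .. %.3f\n",
              min(object@meanR, na.rm = TRUE),
              max(object@meanR, na.rm = TRUE)))
})

setMethod("show", "DatasetBundle", function(object) {
  d <- dim(object@image)
  cat(sprintf("DatasetBundle: %d x %d x %d volume, %d measurements\n",
              d[1], d[2], d[3], d[4]))
})
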