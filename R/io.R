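# NIfTI + FSL bval/bvec I/O. Internal units are fixed (b in ms/um^2, D in
# um^2/ms); s/mm^2 b-value files are auto-detected and converted at the I/O
# boundary. bvecs are interpreted in image coordinates per the FSL
# convention; the NIfTI affine is carried through unchanged on write.

#' Read a 4-D DWI data set with FSL-style gradient tables
#'
#' @param imagePath NIfTI image (4th axis = measurements).
#' @param bvalPath whitespace-separated b-value row; values with max > 100
#'   are taken as s/mm^2 and converted to ms/um^2.
#' @param bvecPath three whitespace-separated rows of N columns. Nonzero
#'   vectors must be unit within 1e-3 (renormalized on load); zero vectors
#'   are allowed only where b = 0.
#' @return a \code{DatasetBundle}.
#' @export
readDwi <- function(imagePath, bvalPath, bvecPath) {
  for (p in c(imagePath, bvalPath, bvecPath))
    if (!file.exists(p))
      stop("unreadable file: ", p, call. = FALSE)
  img <- RNifti::readNifti(imagePath)
  arr <- array(as.numeric(img), dim = dim(img))
  if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
  if (length(dim(arr)) != 4L)
    stop("invalid input: image must be 4-D", call. = FALSE)
  bvals <- scan(bvalPath, quiet = TRUE)
  bvecRows <- utils::read.table(bvecPath)
  bvecs <- as.matrix(bvecRows)
  if (nrow(bvecs) != 3L) {
    if (ncol(bvecs) == 3L) bvecs <- t(bvecs)
    else stop("invalid input: bvec must have 3 rows", call. = FALSE)
  }
  n <- dim(arr)[4]
  if (length(bvals) != n)
    stop("length mismatch: ", length(bvals), " b-values for ", n,
         " volumes", call. = FALSE)
  if (ncol(bvecs) != n)
    stop("length mismatch: ", ncol(bvecs), " bvecs for ", n, " volumes",
         call. = FALSE)
  if (max(bvals) > 100) bvals <- bvals / 1000   # s/mm^2 -> ms/um^2
  nrm <- sqrt(colSums(bvecs^2))
  nz <- bvals > 0
  if (any(nz & abs(nrm - 1) > 1e-3))
    stop("invalid input: non-unit bvec at b > 0 (deviation > 1e-3)",
         call. = FALSE)
  if (any(nz & nrm == 0))
    stop("invalid input: zero bvec at b > 0", call. = FALSE)
  bvecs[, nz] <- sweep(bvecs[, nz, drop = FALSE], 2L, nrm[nz], "/")
  bvecs[, !nz] <- 0
  new("DatasetBundle", image = arr,
      scheme = acquisitionScheme(bvals, bvecs), header = img, mask = NULL,
      meta = list(source = imagePath))
}

#' Assemble a dataset bundle in memory
#'
#' @param image 4-D array (or voxel x measurement matrix, reshaped to
#'   n x 1 x 1 x m).
#' @param scheme matching \code{AcquisitionScheme}.
#' @param header optional NIfTI template whose geometry is reused on write.
#' @param meta provenance list (seed, config, ...).
#' @return a \code{DatasetBundle}.
#' @export
datasetBundle <- function(image, scheme, header = NULL, meta = list()) {
  if (is.matrix(image)) {
    dim(image) <- c(nrow(image), 1L, 1L, ncol(image))
  }
  new("DatasetBundle", image = image, scheme = scheme, header = header,
      mask = NULL, meta = meta)
}

# voxel x measurement view of a bundle
.flattenBundle <- function(bundle) {
  d <- dim(bundle@image)
  matrix(bundle@image, prod(d[1:3]), d[4])
}

#' Write metric maps as NIfTI with a JSON sidecar
#'
#' One float32 NIfTI per metric, reusing the reference bundle's geometry
#' (affine/header unchanged); masked-out voxels are stored as
#' \code{fillValue}. A sidecar JSON records the provenance metadata
#' (configuration and RNG seed).
#'
#' @param maps named list of 3-D arrays (or vectors matching the reference
#'   grid).
#' @param referenceBundle \code{DatasetBundle} supplying grid and header.
#' @param outDir output directory (created if missing).
#' @param mask optional logical mask; voxels outside get \code{fillValue}.
#' @param fillValue value stored outside the mask.
#' @return invisible character vector of files written.
#' @export
writeMaps <- function(maps, referenceBundle, outDir, mask = NULL,
                      fillValue = 0) {
  stopifnot(is.list(maps), !is.null(names(maps)))
  d3 <- dim(referenceBundle@image)[1:3]
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in names(maps)) {
    m <- maps[[nm]]
    if (length(m) != prod(d3))
      stop("shape mismatch: map '", nm, "' does not match the reference ",
           "grid", call. = FALSE)
    m <- array(as.numeric(m), dim = d3)
    if (!is.null(mask)) m[!mask] <- fillValue
    m[!is.finite(m)] <- fillValue
    path <- file.path(outDir, paste0(nm, ".nii.gz"))
    if (!is.null(referenceBundle@header)) {
      img <- RNifti::asNifti(m, reference = referenceBundle@header)
      RNifti::writeNifti(img, path, datatype = "float")
    } else {
      RNifti::writeNifti(RNifti::asNifti(m), path, datatype = "float")
    }
    files <- c(files, path)
  }
  sidecar <- file.path(outDir, "maps.json")
  jsonlite::write_json(referenceBundle@meta, sidecar, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(c(files, sidecar))
}

#' Write a bundle as NIfTI + bval/bvec
#'
#' @param bundle a \code{DatasetBundle}.
#' @param prefix output path prefix; writes prefix.nii.gz, prefix.bval,
#'   prefix.bvec.
#' @return invisible character vector of the three paths.
#' @export
writeBundle <- function(bundle, prefix) {
  dir.create(dirname(prefix), showWarnings = FALSE, recursive = TRUE)
  nii <- paste0(prefix, ".nii.gz")
  if (!is.null(bundle@header)) {
    RNifti::writeNifti(RNifti::asNifti(bundle@image,
                                       reference = bundle@header), nii,
                       datatype = "float")
  } else {
    RNifti::writeNifti(RNifti::asNifti(bundle@image), nii,
                       datatype = "float")
  }
  bval <- paste0(prefix, ".bval")
  bvec <- paste0(prefix, ".bvec")
  writeLines(paste(format(bundle@scheme@bvals, trim = TRUE,
                          scientific = FALSE), collapse = " "), bval)
  write.table(format(bundle@scheme@bvecs, trim = TRUE, scientific = FALSE),
              bvec, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(c(nii, bval, bvec))
}

#' Extract a two-shell sub-scheme from a bundle
#'
#' Finds the b = 0 volume(s) and the measurements matching the requested
#' shells (within tolerance), pairs shell-2 directions to shell-1 directions
#' by maximum |dot product|, and returns the 1 + 2N signal layout expected
#' by \code{\link{proxyMap}}.
#'
#' @param bundle a \code{DatasetBundle}.
#' @param b1,b2 shell b-values (ms/um^2).
#' @param tol b-value matching tolerance.
#' @return list with \code{volume} (n_voxel x (1 + 2N)) and \code{scheme}
#'   (a \code{TwoShellScheme}).
#' @export
extractTwoShell <- function(bundle, b1, b2, tol = 0.05) {
  b <- bundle@scheme@bvals
  i0 <- which(b == 0)
  i1 <- which(abs(b - b1) <= tol)
  i2 <- which(abs(b - b2) <= tol)
  if (!length(i0) || !length(i1) || !length(i2))
    stop("invalid input: bundle lacks b = 0 or the requested shells",
         call. = FALSE)
  v1 <- bundle@scheme@bvecs[, i1, drop = FALSE]
  v2 <- bundle@scheme@bvecs[, i2, drop = FALSE]
  if (ncol(v1) != ncol(v2))
    stop("invalid input: shells carry different direction counts",
         call. = FALSE)
  # pair shell-2 columns to shell-1 directions
  dots <- abs(crossprod(v1, v2))
  order2 <- apply(dots, 1L, which.max)
  if (anyDuplicated(order2))
    stop("invalid input: shell directions cannot be paired one-to-one",
         call. = FALSE)
  sig <- .flattenBundle(bundle)
  s0 <- rowMeans(sig[, i0, drop = FALSE])
  volume <- cbind(s0, sig[, i1, drop = FALSE],
                  sig[, i2[order2], drop = FALSE])
  list(volume = volume, scheme = twoShellScheme(b1, b2, v1))
}
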