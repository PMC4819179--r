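# Monte-Carlo characterization of the KFA proxy: direction-count x SNR
# sweeps and b1 x b2 grid optimization on a synthetic voxel population.
#
# Signals are simulated from each voxel's exact (D, W) through the DKI
# forward model; Rician noise is added per realization; the per-realization
# Pearson correlation between the proxy map and true KFA is averaged over
# realizations (never pooled across realizations).

# noise-free two-shell signal block for a population: n_voxel x (1 + 2N)
.populationTwoShellSignals <- function(population, tss) {
  .predictSignalMatrix(population@D, population@W, asAcquisitionScheme(tss))
}

# mean/sd of per-realization correlation for one cell; Inf SNR = one
# noise-free pass
.proxyCorrelationCell <- function(signals, tss, kfaTrue, snr, nReal, seed,
                                  counterBase) {
  nVox <- nrow(signals)
  rs <- numeric(0)
  invalidFrac <- 0
  nPasses <- if (is.infinite(snr)) 1L else nReal
  for (ri in seq_len(nPasses)) {
    noised <- addRicianNoise(signals, snr, S0ref = 1, seed = seed,
                             realization = counterBase + ri)
    pm <- proxyMap(noised, tss)
    ok <- pm$valid & is.finite(pm$proxy)
    invalidFrac <- invalidFrac + mean(!ok) / nPasses
    if (sum(ok) >= 3L && stats::var(pm$proxy[ok]) > 0 &&
        stats::var(kfaTrue[ok]) > 0)
      rs <- c(rs, stats::cor(kfaTrue[ok], pm$proxy[ok]))
  }
  list(mean = if (length(rs)) mean(rs) else NA_real_,
       sd = if (length(rs) > 1L) stats::sd(rs) else 0,
       flagged = invalidFrac > 0.5)
}

.checkSweepPopulation <- function(population) {
  stopifnot(is(population, "VoxelPopulation"))
  kfaTrue <- population@metrics$KFA
  if (length(kfaTrue) < 50L || stats::var(kfaTrue) == 0)
    stop("invalid input: population needs >= 50 voxels with KFA variance",
         call. = FALSE)
  kfaTrue
}

#' Direction-count x SNR proxy correlation sweep
#'
#' For every (N, SNR) cell: simulate b = 0 plus two shells at (b1, b2) along
#' N directions from each voxel's exact tensors, add Rician noise, compute
#' the two-shell proxy map, correlate it with true KFA across voxels, and
#' average the correlation over noise realizations. SNR = Inf runs a single
#' noise-free pass.
#'
#' @param population a \code{VoxelPopulation} (>= 50 voxels with KFA
#'   variance).
#' @param directionCounts direction counts (builtin sets used where
#'   available, otherwise generated by electrostatic repulsion).
#' @param snrLevels SNR levels at b = 0 (may include Inf).
#' @param b1,b2 shell b-values (ms/um^2).
#' @param nRealizations Rician realizations per finite-SNR cell.
#' @param seed experiment seed; one global stream, realization index
#'   advances a counter so each realization is reproducible in isolation.
#' @return a \code{SweepResult} with axes (directions, SNR).
#' @export
directionSnrSweep <- function(population,
                              directionCounts = c(3, 5, 9, 15, 25, 36, 46,
                                                  65, 86),
                              snrLevels = c(10, 20, 30, 40, 50, 80, 100,
                                            Inf),
                              b1 = 1.0, b2 = 2.5, nRealizations = 100L,
                              seed = 1) {
  kfaTrue <- .checkSweepPopulation(population)
  nN <- length(directionCounts); nS <- length(snrLevels)
  meanR <- sdR <- matrix(NA_real_, nN, nS,
                         dimnames = list(directionCounts, snrLevels))
  flagged <- matrix(FALSE, nN, nS)
  cell <- 0L
  for (i in seq_len(nN)) {
    N <- directionCounts[i]
    dirs <- if (as.character(N) %in% as.character(.builtinCounts))
      loadDirections(as.character(N)) else generateDirections(N, seed = seed)
    tss <- twoShellScheme(b1, b2, dirs)
    signals <- .populationTwoShellSignals(population, tss)
    for (j in seq_len(nS)) {
      cell <- cell + 1L
      res <- .proxyCorrelationCell(signals, tss, kfaTrue, snrLevels[j],
                                   nRealizations, seed,
                                   (cell - 1L) * nRealizations)
      meanR[i, j] <- res$mean; sdR[i, j] <- res$sd
      flagged[i, j] <- res$flagged
    }
  }
  new("SweepResult", axis1 = as.numeric(directionCounts),
      axis2 = as.numeric(snrLevels), meanR = meanR, sdR = sdR,
      flagged = flagged, nRealizations = as.numeric(nRealizations),
      seed = as.numeric(seed), axisNames = c("directions", "SNR"))
}

#' b-value grid optimization for the proxy
#'
#' Varies the two-shell b-value combination at a fixed direction count and
#' SNR, reporting the realization-averaged correlation between the proxy
#' and true KFA for every valid cell. Cells with b1 >= b2 are masked (equal
#' shells make the inversion singular).
#'
#' @param population a \code{VoxelPopulation}.
#' @param b1Grid,b2Grid candidate b-values (ms/um^2); defaults cover
#'   0.2-6.0 in 0.2 steps.
#' @param nDirections direction count for both shells.
#' @param snr SNR at b = 0.
#' @param nRealizations Rician realizations per cell.
#' @param seed experiment seed.
#' @return a \code{SweepResult} with axes (b1, b2); the best cell is
#'   available via \code{\link{argmaxCell}}.
#' @export
bvalueGridSearch <- function(population, b1Grid = seq(0.2, 6, by = 0.2),
                             b2Grid = seq(0.2, 6, by = 0.2),
                             nDirections = 9L, snr = 100,
                             nRealizations = 100L, seed = 1) {
  kfaTrue <- .checkSweepPopulation(population)
  valid <- outer(b1Grid, b2Grid, `<`)
  if (!any(valid))
    stop("invalid parameter: grid contains no b1 < b2 cells", call. = FALSE)
  dirs <- if (as.character(nDirections) %in% as.character(.builtinCounts))
    loadDirections(as.character(nDirections))
  else generateDirections(nDirections, seed = seed)
  n1 <- length(b1Grid); n2 <- length(b2Grid)
  meanR <- sdR <- matrix(NA_real_, n1, n2, dimnames = list(b1Grid, b2Grid))
  flagged <- !valid
  cell <- 0L
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    cell <- cell + 1L
    if (!valid[i, j]) next
    tss <- twoShellScheme(b1Grid[i], b2Grid[j], dirs)
    signals <- .populationTwoShellSignals(population, tss)
    res <- .proxyCorrelationCell(signals, tss, kfaTrue, snr, nRealizations,
                                 seed, (cell - 1L) * nRealizations)
    meanR[i, j] <- res$mean; sdR[i, j] <- res$sd
    flagged[i, j] <- res$flagged
  }
  new("SweepResult", axis1 = as.numeric(b1Grid), axis2 = as.numeric(b2Grid),
      meanR = meanR, sdR = sdR, flagged = flagged,
      nRealizations = as.numeric(nRealizations), seed = as.numeric(seed),
      axisNames = c("b1", "b2"))
}

#' Best cell of a sweep grid
#'
#' @param sweep a \code{SweepResult}.
#' @return list with axis1, axis2 values and mean r of the cell with the
#'   highest mean correlation.
#' @export
argmaxCell <- function(sweep) {
  stopifnot(is(sweep, "SweepResult"))
  idx <- which(sweep@meanR == max(sweep@meanR, na.rm = TRUE),
               arr.ind = TRUE)[1, ]
  out <- list(axis1 = sweep@axis1[idx[1]], axis2 = sweep@axis2[idx[2]],
              meanR = sweep@meanR[idx[1], idx[2]])
  names(out)[1:2] <- sweep@axisNames
  out
}

#' Long-format table of a sweep grid
#'
#' @param sweep a \code{SweepResult}.
#' @return data.frame with columns axis1, axis2, mean_r, sd_r, n (named
#'   after the sweep axes).
#' @export
sweepTable <- function(sweep) {
  stopifnot(is(sweep, "SweepResult"))
  g <- expand.grid(a1 = sweep@axis1, a2 = sweep@axis2)
  out <- data.frame(g$a1, g$a2, mean_r = as.numeric(sweep@meanR),
                    sd_r = as.numeric(sweep@sdR),
                    n = sweep@nRealizations,
                    flagged = as.logical(sweep@flagged))
  names(out)[1:2] <- sweep@axisNames
  out
}
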