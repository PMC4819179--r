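# DKI forward signal model and voxel-wise (S0, D, W) estimation.
#
# ln S(b, n) = ln S0 - b n_i n_j D_ij + (b^2/6) MD^2 n_i n_j n_k n_l W_ijkl
#
# The estimation parameterization is 1 (ln S0) + 6 (D) + 15 (V = MD^2 W,
# grouped as one linear block) = 22 unknowns; W is recovered by dividing the
# fitted quartic-form coefficients by MD^2 from the same fit. This keeps the
# log-domain linear initializer exact.

# design blocks: X2 (m x 6) multiplies D, X4 (m x 15) multiplies V = MD^2 W
.designBlocks <- function(scheme) {
  b <- scheme@bvals
  dirs <- scheme@bvecs
  X2 <- b * .q2rows(dirs)
  X4 <- (b^2 / 6) * .q4rows(dirs)
  list(X2 = X2, X4 = X4, X = cbind(1, -X2, X4))
}

#' Predict DKI signals
#'
#' Evaluates the exponentiated DKI Taylor form for every measurement of a
#' scheme. At b = 0 the prediction is exactly S0.
#'
#' @param S0 b = 0 signal, > 0.
#' @param D a \code{DiffusionTensor}.
#' @param W a \code{KurtosisTensor}.
#' @param scheme an \code{AcquisitionScheme} (or \code{TwoShellScheme},
#'   expanded as b0 + shell1 + shell2).
#' @return numeric signal vector aligned to the scheme.
#' @export
predictSignal <- function(S0, D, W, scheme) {
  stopifnot(S0 > 0, is(D, "DiffusionTensor"), is(W, "KurtosisTensor"))
  if (is(scheme, "TwoShellScheme")) scheme <- asAcquisitionScheme(scheme)
  as.numeric(.predictSignalMatrix(matrix(D@values, 1L),
                                  matrix(W@values, 1L), scheme, S0))
}

# vectorized forward model: rows of D6/W15 -> n_voxel x m signal matrix
.predictSignalMatrix <- function(D6, W15, scheme, S0 = 1) {
  blocks <- .designBlocks(scheme)
  md <- .mdFromD6(D6)
  V <- W15 * md^2
  logS <- log(S0) - tcrossprod(D6, blocks$X2) + tcrossprod(V, blocks$X4)
  exp(logS)
}

.checkDesign <- function(scheme) {
  b <- scheme@bvals
  m <- length(b)
  if (m < 22L)
    stop("design error: ", m, " measurements cannot determine 22 unknowns",
         call. = FALSE)
  if (length(unique(b)) < 3L || !any(b == 0))
    stop("design error: need >= 3 distinct b-values including b = 0",
         call. = FALSE)
  blocks <- .designBlocks(scheme)
  if (qr(blocks$X)$rank < 22L)
    stop("design error: rank-deficient scheme (directions do not span both ",
         "tensor orders)", call. = FALSE)
  blocks
}

#' Fit the DKI model to one voxel
#'
#' Signals are normalized to the mean b = 0 signal so the fitted signal lies
#' in (0, ~1]. The default method is unweighted nonlinear least squares on
#' the normalized signal (Levenberg-Marquardt with analytic Jacobian),
#' initialized from the exact linear log-domain solution; "wls" performs
#' weighted linear least squares on the log signal (weights = squared
#' predicted signal from an OLS first pass) as a fast fallback. No positivity
#' or directional-kurtosis constraints are imposed; QC flags mark voxels
#' with a negative diffusion eigenvalue or apparent kurtosis below -3/7.
#'
#' @param signals non-negative signal vector aligned to \code{scheme}.
#' @param scheme an \code{AcquisitionScheme} with >= 22 measurements over
#'   >= 3 distinct b-values (including b = 0) and full-rank design.
#' @param method "nlls" (default) or "wls".
#' @param maxit maximum Levenberg-Marquardt iterations.
#' @return a \code{DkiFit}.
#' @examples
#' sch <- acquisitionScheme(rep(c(0, 1, 2.5), each = 9),
#'                          cbind(matrix(0, 3, 9),
#'                                loadDirections("9"), loadDirections("9")))
#' \dontrun{fitDki(predictSignal(1, diffusionTensor(1.2, .5, .5),
#'                               kurtosisTensor(xxxx = 2), sch), sch)}
#' @export
fitDki <- function(signals, scheme, method = c("nlls", "wls"),
                   maxit = 500L) {
  method <- match.arg(method)
  if (is(scheme, "TwoShellScheme")) scheme <- asAcquisitionScheme(scheme)
  signals <- as.numeric(signals)
  if (length(signals) != length(scheme@bvals))
    stop("signals and scheme lengths differ", call. = FALSE)
  if (!all(is.finite(signals)) || any(signals < 0))
    stop("invalid input: signals must be finite and non-negative",
         call. = FALSE)
  blocks <- .checkDesign(scheme)
  fit <- .fitDkiCore(signals, scheme, blocks, method, maxit)
  .asDkiFit(fit, scheme, method)
}

# core fit on one voxel; returns plain list (used by the vectorized wrapper)
.fitDkiCore <- function(signals, scheme, blocks, method, maxit = 500L) {
  b <- scheme@bvals
  s0ref <- mean(signals[b == 0])
  if (!is.finite(s0ref) || s0ref <= 0)
    stop("invalid input: non-positive b = 0 signal", call. = FALSE)
  y <- signals / s0ref
  X <- blocks$X

  pos <- y > 0
  theta <- qr.solve(qr(X[pos, , drop = FALSE]), log(y[pos]))
  converged <- TRUE

  if (method == "wls") {
    w <- as.numeric(exp(X %*% theta))^2
    w[!pos] <- 0
    fitw <- stats::lm.wfit(X[pos, , drop = FALSE], log(y[pos]), w[pos])
    theta <- fitw$coefficients
    resid <- sqrt(sum((exp(as.numeric(X %*% theta)) - y)^2))
  } else {
    res <- minpack.lm::nls.lm(
      par = theta,
      fn = function(p) exp(as.numeric(X %*% p)) - y,
      jac = function(p) as.numeric(exp(X %*% p)) * X,
      control = minpack.lm::nls.lm.control(
        ftol = 1e-10, ptol = 1e-10, maxiter = maxit))
    theta <- res$par
    resid <- sqrt(res$deviance)
    converged <- res$info %in% 1:4
  }
  list(theta = theta, s0 = exp(theta[1]) * s0ref, resid = resid,
       converged = converged)
}

.asDkiFit <- function(fit, scheme, method) {
  theta <- fit$theta
  d6 <- theta[2:7]
  v <- theta[8:22]
  md <- (d6[1] + d6[2] + d6[3]) / 3
  if (md^2 > 1e-12) {
    w15 <- v / md^2
  } else {
    w15 <- numeric(15L)
    fit$converged <- FALSE
  }
  D <- diffusionTensor(d6)
  W <- kurtosisTensor(stats::setNames(w15, .wNames))
  lam <- eigen(tensorMatrix(D), symmetric = TRUE, only.values = TRUE)$values
  dirs <- scheme@bvecs[, scheme@bvals > 0, drop = FALSE]
  dirs <- dirs[, !duplicated(round(t(dirs), 6)), drop = FALSE]
  dn <- as.numeric(.q2rows(dirs) %*% d6)
  kn <- ifelse(dn^2 > 1e-12,
               md^2 / dn^2 * as.numeric(.q4rows(dirs) %*% w15), 0)
  qc <- c(negativeEigenvalue = min(lam) < 0,
          negativeKurtosis = any(kn < -3 / 7))
  new("DkiFit", s0 = unname(fit$s0), D = D, W = W,
      residual = unname(fit$resid), converged = fit$converged, qc = qc,
      method = method)
}

#' Fit the DKI model to many voxels
#'
#' Vectorized convenience wrapper around the single-voxel fit: shares the
#' design matrix across voxels and returns compact component matrices plus
#' scalar metrics.
#'
#' @param signalMatrix n_voxel x m matrix of signals.
#' @param scheme matching \code{AcquisitionScheme}.
#' @param method "nlls" or "wls".
#' @return list with S0 (n), D (n x 6), W (n x 15), residual, converged, and
#'   a metrics data.frame (MD, FA, Wbar, KFA).
#' @export
fitDkiMany <- function(signalMatrix, scheme, method = c("nlls", "wls")) {
  method <- match.arg(method)
  if (is(scheme, "TwoShellScheme")) scheme <- asAcquisitionScheme(scheme)
  signalMatrix <- as.matrix(signalMatrix)
  blocks <- .checkDesign(scheme)
  n <- nrow(signalMatrix)
  S0 <- resid <- numeric(n)
  conv <- logical(n)
  D6 <- matrix(0, n, 6L); W15 <- matrix(0, n, 15L)
  for (vx in seq_len(n)) {
    fit <- .fitDkiCore(signalMatrix[vx, ], scheme, blocks, method)
    theta <- fit$theta
    S0[vx] <- fit$s0; resid[vx] <- fit$resid; conv[vx] <- fit$converged
    D6[vx, ] <- theta[2:7]
    md <- mean(theta[2:4])
    W15[vx, ] <- if (md^2 > 1e-12) theta[8:22] / md^2 else 0
  }
  metrics <- data.frame(MD = .mdFromD6(D6), FA = .faFromD6(D6),
                        Wbar = .wbarFromW15(W15), KFA = .kfaFromW15(W15))
  list(S0 = S0, D = D6, W = W15, residual = resid, converged = conv,
       metrics = metrics)
}
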