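# Gradient direction sets: packaged electrostatic-repulsion fixtures for the
# canonical counts, plus a seeded generator for arbitrary N.

.builtinCounts <- c(3L, 5L, 9L, 15L, 25L, 36L, 46L, 65L, 86L, 256L)

#' Generate a direction set by electrostatic repulsion
#'
#' Minimizes the antipodally symmetric Coulomb energy
#' sum_{i<j} (1/|u_i - u_j| + 1/|u_i + u_j|) by projected gradient descent on
#' the unit sphere, from a seeded random start. Antipodal symmetry makes the
#' sets suitable for diffusion encoding, where n and -n are equivalent.
#'
#' @param n number of directions.
#' @param seed RNG seed (default 42, matching the packaged fixtures).
#' @param iterations descent iterations.
#' @return 3 x n matrix of unit directions.
#' @export
generateDirections <- function(n, seed = 42, iterations = 2000L) {
  stopifnot(n >= 1)
  u <- .withSeed(seed, {
    m <- matrix(stats::rnorm(3L * n), 3L, n)
    sweep(m, 2L, sqrt(colSums(m^2)), "/")
  })
  if (n == 1L) return(u)
  step <- 0.05
  energy <- function(u) {
    dm <- 2 - 2 * crossprod(u)          # |ui - uj|^2
    sm <- 2 + 2 * crossprod(u)          # |ui + uj|^2
    diag(dm) <- Inf; diag(sm) <- Inf
    sum(1 / sqrt(dm) + 1 / sqrt(sm)) / 2
  }
  eOld <- energy(u)
  for (it in seq_len(iterations)) {
    g <- crossprod(u)                   # u_i . u_j
    dm <- pmax(2 - 2 * g, 1e-12)
    sm <- pmax(2 + 2 * g, 1e-12)
    diag(dm) <- Inf; diag(sm) <- Inf
    cd <- dm^(-1.5)                     # gradient weights
    cs <- sm^(-1.5)
    # dE/du_i = -sum_j (u_i - u_j) cd_ij - sum_j (u_i + u_j) cs_ij
    grad <- -(u %*% (diag(rowSums(cd)) - cd)) - (u %*% (diag(rowSums(cs)) + cs))
    cand <- u - step * grad
    cand <- sweep(cand, 2L, sqrt(colSums(cand^2)), "/")
    eNew <- energy(cand)
    if (eNew <= eOld) {
      u <- cand; eOld <- eNew; step <- step * 1.1
    } else {
      step <- step / 2
      if (step < 1e-12) break
    }
  }
  dimnames(u) <- NULL
  u
}

#' Load a direction set
#'
#' Resolves either a packaged builtin (by count: "3", "5", "9", "15", "25",
#' "36", "46", "65", "86" or "256"; electrostatic-repulsion fixtures shipped
#' with the package) or a plain-text file with three whitespace-separated
#' columns, one unit direction per row.
#'
#' @param pathOrName builtin name or path to a 3-column text file.
#' @return 3 x n matrix of unit-normalized directions.
#' @export
loadDirections <- function(pathOrName) {
  pathOrName <- as.character(pathOrName)
  if (pathOrName %in% as.character(.builtinCounts)) {
    path <- system.file("extdata", "directions",
                        paste0("dirs_", pathOrName, ".txt"),
                        package = "DKImetrics", mustWork = TRUE)
  } else if (file.exists(pathOrName)) {
    path <- pathOrName
  } else {
    stop("unknown direction set '", pathOrName,
         "': not a builtin count (", paste(.builtinCounts, collapse = ", "),
         ") and not a readable file", call. = FALSE)
  }
  m <- as.matrix(utils::read.table(path))
  if (ncol(m) != 3L)
    stop("malformed direction file: need 3 columns", call. = FALSE)
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0))
    stop("malformed direction file: zero row", call. = FALSE)
  t(m / nrm)
}

#' Minimum pairwise angle of a direction set
#'
#' Angles are computed modulo antipodal identification (n and -n count as
#' the same axis).
#'
#' @param dirs 3 x n direction matrix.
#' @return smallest pairwise angle in degrees.
#' @export
minimumAngle <- function(dirs) {
  g <- abs(crossprod(dirs))
  diag(g) <- 0
  acos(min(1, max(pmin(g, 1)))) / pi * 180
}
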