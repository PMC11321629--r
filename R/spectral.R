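#' Laplacian spectrum of a weighted graph
#'
#' Eigenvalues of `L = diag(rowSums(W)) - W` in ascending order. The matrix
#' is interpreted as a weighted adjacency: symmetric, non-negative, zero
#' diagonal. The smallest eigenvalue is always 0 (up to round-off) and is
#' clipped to exactly 0.
#'
#' @param W square symmetric non-negative matrix with zero diagonal.
#' @return numeric vector of eigenvalues, ascending.
#' @export
laplacianSpectrum <- function(W) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  if (max(abs(W - base::t(W))) > 1e-9)
    stop("adjacency matrix is asymmetric beyond 1e-9")
  if (min(W) < -1e-12) stop("adjacency weights must be non-negative")
  L <- diag(rowSums(W)) - W
  ev <- rev(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  ev[ev < 0 & ev > -1e-8] <- 0
  if (ev[1L] < 0 || ev[1L] > 1e-8 * max(1, max(ev)))
    warning("smallest Laplacian eigenvalue deviates from 0: ", ev[1L])
  ev[1L] <- 0
  ev
}

## vibrational frequencies: omega_i = sqrt(lambda_i), trivial zero dropped.
## Degenerate extra zeros (disconnected graphs) are kept as omega = 0 modes.
.vibrationalFrequencies <- function(W) {
  ev <- laplacianSpectrum(W)
  sqrt(pmax(ev[-1L], 0))
}

## Lorentzian-smoothed spectral density rho(w) = K sum_i gamma/((w-om_i)^2+gamma^2)
## with K chosen analytically so that the integral over [0, Inf) is exactly 1:
## each term integrates to pi/2 + atan(om_i/gamma).
.densityNormConstant <- function(omegas, gamma) {
  1 / sum(pi / 2 + atan(omegas / gamma))
}

.spectralDensityFun <- function(omegas, gamma) {
  K <- .densityNormConstant(omegas, gamma)
  function(w) {
    K * gamma * colSums(1 / ((outer(omegas, w, `-`))^2 + gamma^2))
  }
}

## squared-L2 distance between two densities, from the frequency lists.
.imDistanceSpectra <- function(om1, om2, gamma,
                               abs.tol = 1e-8) {
  r1 <- .spectralDensityFun(om1, gamma)
  r2 <- .spectralDensityFun(om2, gamma)
  upper <- max(om1, om2, 0) + 10 * gamma
  f <- function(w) (r1(w) - r2(w))^2
  val <- tryCatch(
    stats::integrate(f, 0, upper, abs.tol = abs.tol,
                     subdivisions = 2000L, stop.on.error = TRUE)$value,
    error = function(e) {
      w <- seq(0, upper, length.out = 20001L)
      y <- f(w)
      sum((y[-1L] + y[-length(y)]) / 2) * (w[2L] - w[1L])
    }
  )
  sqrt(max(val, 0))
}

#' Calibrate the Lorentzian half-width for a given graph size
#'
#' Finds the unique `gamma` for which the Ipsen-Mikhailov distance between
#' the empty and the complete unit-weight graph on `n` nodes equals 1. Both
#' endpoint spectra are known in closed form (all-zero frequencies vs. n-1
#' frequencies at `sqrt(n)`), so the calibration needs no eigendecomposition.
#' The distance is strictly decreasing in `gamma`, so the root is unique;
#' it is located by `uniroot` on an automatically expanded bracket.
#'
#' @param n number of nodes (diseases), >= 2.
#' @param tol absolute tolerance on the calibration identity.
#' @return the calibrated `gamma` (scalar, deterministic in `n`).
#' @examples
#' g <- calibrateGamma(10)
#' @export
calibrateGamma <- function(n, tol = 1e-8) {
  stopifnot(n >= 2)
  omEmpty <- rep(0, n - 1L)
  omComplete <- rep(sqrt(n), n - 1L)
  f <- function(g) .imDistanceSpectra(omEmpty, omComplete, g) - 1
  lo <- 0.01; hi <- 2
  while (f(lo) < 0 && lo > 1e-8) lo <- lo / 4
  while (f(hi) > 0 && hi < 1e6) hi <- hi * 4
  if (f(lo) < 0 || f(hi) > 0)
    stop("gamma calibration failed to bracket a root for n = ", n,
         " (f(", lo, ") = ", f(lo), ", f(", hi, ") = ", f(hi), ")")
  stats::uniroot(f, c(lo, hi), tol = tol)$root
}

#' Ipsen-Mikhailov spectral distance between two matrices
#'
#' The vibrational-frequency densities of the two graph Laplacians are
#' smoothed by Lorentzians of half-width `gamma`, normalized to integrate to
#' 1 on `[0, Inf)` (normalization constant computed in closed form), and the
#' distance is the L2 norm of their difference, integrated by adaptive
#' quadrature on `[0, max(omega) + 10 gamma]` with a 20,001-point trapezoid
#' fallback.
#'
#' @param W1,W2 square symmetric non-negative matrices of equal size.
#' @param gamma Lorentzian half-width (use [calibrateGamma()] so that
#'   empty-vs-complete equals 1).
#' @return non-negative scalar distance.
#' @examples
#' n <- 5
#' g <- calibrateGamma(n)
#' empty <- matrix(0, n, n)
#' complete <- matrix(1, n, n); diag(complete) <- 0
#' imDistance(empty, complete, g)  # 1 by calibration
#' @export
imDistance <- function(W1, W2, gamma) {
  if (!all(dim(W1) == dim(W2))) stop("matrix size mismatch")
  stopifnot(gamma > 0)
  .imDistanceSpectra(.vibrationalFrequencies(W1),
                     .vibrationalFrequencies(W2), gamma)
}

#' Pairwise Ipsen-Mikhailov distances within a matrix family
#'
#' Used to compare the six metric matrices of one dimension, the six
#' dimension matrices, or dimensions against an ICD-derived matrix. `gamma`
#' is calibrated once for the family's common disease count and reused for
#' every pair. By default each distance matrix is passed verbatim as the
#' weighted adjacency (`interpretation = "distance"`, replicating what
#' feeding a distance matrix to a graph-spectral routine does);
#' `interpretation = "similarity"` uses `1 - D` off-diagonal instead.
#'
#' @param matrices named list of [DiseaseDistanceMatrix-class] objects over
#'   the identical ordered disease set.
#' @param gamma optional half-width; calibrated from the disease count when
#'   `NULL`.
#' @param interpretation `"distance"` (default) or `"similarity"`.
#' @return symmetric numeric matrix of IM distances with the family labels
#'   as dimnames and attributes `gamma` and `interpretation`.
#' @export
matrixFamilyDistance <- function(matrices, gamma = NULL,
                                 interpretation = c("distance", "similarity")) {
  interpretation <- match.arg(interpretation)
  stopifnot(is.list(matrices), length(matrices) >= 2L)
  if (is.null(names(matrices)) || anyDuplicated(names(matrices)))
    stop("'matrices' must be a uniquely named list")
  ids <- diseaseIds(matrices[[1L]])
  for (m in matrices)
    if (!identical(diseaseIds(m), ids))
      stop("inconsistent disease ordering across the matrix family")
  n <- length(ids)
  if (is.null(gamma)) gamma <- calibrateGamma(n)
  asAdjacency <- function(m) {
    v <- as.matrix(m)
    if (interpretation == "similarity") {
      v <- 1 - v
      diag(v) <- 0
    }
    v
  }
  spectra <- lapply(matrices, function(m)
    .vibrationalFrequencies(asAdjacency(m)))
  k <- length(matrices)
  out <- matrix(0, k, k, dimnames = list(names(matrices), names(matrices)))
  if (k > 1L) {
    for (i in seq_len(k - 1L)) {
      for (j in seq((i + 1L), k)) {
        d <- .imDistanceSpectra(spectra[[i]], spectra[[j]], gamma)
        out[i, j] <- out[j, i] <- d
      }
    }
  }
  attr(out, "gamma") <- gamma
  attr(out, "interpretation") <- interpretation
  out
}
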