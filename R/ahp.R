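# Analytic hierarchy process: principal-eigenvector weights from a
# reciprocal pairwise judgment matrix, with Saaty's consistency ratio.

validateJudgment <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m) || nrow(m) < 1L)
    stop("judgment matrix must be square")
  if (any(!is.finite(m)) || any(m <= 0))
    stop("judgment matrix entries must be positive finite numbers")
  tol <- 1e-9
  if (any(abs(diag(m) - 1) > tol))
    stop("judgment matrix diagonal must be 1")
  if (any(abs(m * t(m) - 1) > 1e-6))
    stop("judgment matrix must be reciprocal (m[j,i] = 1/m[i,j])")
  if (any(m < 1 / 9 - 1e-9 | m > 9 + 1e-9))
    stop("judgment matrix entries must lie on Saaty's [1/9, 9] scale")
  invisible(m)
}

#' AHP weights from a pairwise judgment matrix
#'
#' Computes the principal right eigenvector of a positive reciprocal
#' judgment matrix by power iteration (relative tolerance 1e-10),
#' normalised to sum 1, together with the dominant eigenvalue
#' \eqn{\lambda_{max}}. This is the classical eigenvector method; the
#' row-geometric-mean weights are returned alongside as a cross-check.
#'
#' @param m square positive reciprocal matrix (entries on the 1/9..9
#'   scale, unit diagonal). Row/column names, if any, name the weights.
#' @return A list with \code{weights} (named numeric summing to 1),
#'   \code{lambdaMax}, and \code{gmWeights} (row geometric mean
#'   normalised to sum 1).
#' @examples
#' m <- matrix(c(1, 5, 1/5, 1), 2, 2, byrow = TRUE)
#' weightsFromMatrix(m)$weights      # 0.8333, 0.1667
#' @export
weightsFromMatrix <- function(m) {
  validateJudgment(m)
  n <- nrow(m)
  w <- rep(1 / n, n)
  lambda <- n
  for (it in seq_len(10000L)) {
    v <- as.vector(m %*% w)
    w2 <- v / sum(v)
    lambdaNew <- sum(v)  # since sum(w) == 1, Rayleigh-type estimate
    if (max(abs(w2 - w)) < 1e-10 * max(w2) &&
        abs(lambdaNew - lambda) < 1e-10 * lambdaNew) {
      w <- w2; lambda <- lambdaNew
      break
    }
    w <- w2; lambda <- lambdaNew
  }
  gm <- exp(rowMeans(log(m)))
  nm <- rownames(m)
  if (!is.null(nm)) names(w) <- names(gm) <- nm
  list(weights = w, lambdaMax = lambda, gmWeights = gm / sum(gm))
}

# Saaty's random consistency index, n = 1..15.
saatyRI <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49,
             1.51, 1.54, 1.56, 1.57, 1.58)

#' Consistency ratio of a judgment matrix
#'
#' \eqn{CI = (\lambda_{max} - n) / (n - 1)} and \eqn{CR = CI / RI(n)}
#' with Saaty's random-index table (RI = 0 for n <= 2, 0.58 for n = 3,
#' 0.90 for n = 4, ...; tabulated through n = 15). CR is defined as 0
#' for n <= 2 (a 2 x 2 reciprocal matrix is always consistent).
#'
#' @param m square positive reciprocal judgment matrix.
#' @return The consistency ratio (a single non-negative number).
#' @seealso [isConsistent()]
#' @export
consistencyRatio <- function(m) {
  validateJudgment(m)
  n <- nrow(m)
  if (n <= 2L) return(0)
  if (n > length(saatyRI))
    stop(sprintf("random-index table covers n <= %d", length(saatyRI)))
  lambda <- weightsFromMatrix(m)$lambdaMax
  ci <- (lambda - n) / (n - 1)
  max(ci, 0) / saatyRI[n]
}

#' Consistency acceptance gate
#'
#' @param m square positive reciprocal judgment matrix.
#' @param threshold acceptance threshold (default 0.1).
#' @return TRUE when CR < threshold.
#' @export
isConsistent <- function(m, threshold = 0.1) {
  consistencyRatio(m) < threshold
}
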