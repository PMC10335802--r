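#' @title Geometry of symmetric positive-definite matrices
#' @description Channel covariances are treated as points on the manifold of
#'   symmetric positive-definite (SPD) matrices. The default metric is the
#'   affine-invariant Riemannian metric (AIRM), the congruence-invariant
#'   standard for EEG covariances; the log-Euclidean metric is available as a
#'   cheaper alternative.
#' @name spd_geometry
NULL

#' Assert/construct an SPD matrix
#'
#' @param m Numeric square matrix; symmetry is required to `1e-10` and the
#'   smallest eigenvalue must be strictly positive.
#' @return `m` with class `spd`.
#' @export
as_spd <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("matrix must be square", call. = FALSE)
  if (max(abs(m - t(m))) > 1e-10) {
    stop("matrix is not symmetric", call. = FALSE)
  }
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop("matrix is not positive definite", call. = FALSE)
  }
  structure((m + t(m)) / 2, class = c("spd", "matrix"))
}

#' @export
print.spd <- function(x, ...) {
  cat(sprintf("<spd %d x %d>\n", nrow(x), ncol(x)))
  print(unclass(x))
  invisible(x)
}

# f applied to the eigenvalues of a symmetric matrix.
sym_matfun <- function(m, f) {
  e <- eigen(m, symmetric = TRUE)
  e$vectors %*% (f(e$values) * t(e$vectors))
}

spd_logm <- function(m) sym_matfun(m, log)
spd_expm <- function(m) sym_matfun(m, exp)
spd_powm <- function(m, p) sym_matfun(m, function(v) v^p)

#' Covariance estimation specification
#'
#' Empirical covariance with optional shrinkage towards a scaled identity:
#' `C = (1 - lambda) C_emp + lambda (trace(C_emp) / p) I`. The default
#' `lambda = 0.05` guarantees positive definiteness for short epochs while
#' perturbing well-conditioned estimates only mildly.
#'
#' @param estimator Only `"empirical"` is implemented.
#' @param shrinkage Shrinkage weight `lambda` in `[0, 1)`.
#' @return An object of class `cov_spec`.
#' @export
cov_spec <- function(estimator = "empirical", shrinkage = 0.05) {
  estimator <- match.arg(estimator)
  if (!(shrinkage >= 0 && shrinkage < 1)) {
    stop("shrinkage must lie in [0, 1)", call. = FALSE)
  }
  structure(list(estimator = estimator, shrinkage = shrinkage),
            class = "cov_spec")
}

#' Covariance of an epoch
#'
#' Row-mean-centred empirical covariance `X X' / (n - 1)` followed by
#' shrinkage regularisation.
#'
#' @param epoch An `epoch` (channels x samples, `>= 2` samples) or a bare
#'   channels-by-samples matrix.
#' @param spec A [cov_spec()].
#' @return An `spd` matrix.
#' @export
epoch_covariance <- function(epoch, spec = cov_spec()) {
  x <- if (inherits(epoch, "epoch")) epoch$data else as.matrix(epoch)
  ns <- ncol(x)
  if (ns < 2L) stop("need at least 2 samples", call. = FALSE)
  x <- x - rowMeans(x)
  c_emp <- tcrossprod(x) / (ns - 1)
  p <- nrow(c_emp)
  lam <- spec$shrinkage
  s <- sum(diag(c_emp)) / p
  if (s == 0 && lam > 0) s <- 1  # zero-variance data: shrink to unit prior
  c_reg <- (1 - lam) * c_emp + lam * s * diag(p)
  tr <- sum(diag(c_reg))
  ev <- eigen(c_reg, symmetric = TRUE, only.values = TRUE)$values
  if (tr <= 0 || min(ev) < -1e-10 * max(tr, 1)) {
    stop("singular covariance (constant epoch?); use shrinkage > 0",
         call. = FALSE)
  }
  # lam = 0 on rank-deficient data is allowed to return a boundary matrix;
  # manifold operations will reject it if actually used there
  structure((c_reg + t(c_reg)) / 2, class = c("spd", "matrix"))
}

#' Affine-invariant Riemannian distance
#'
#' `delta(A, B) = ||log(A^{-1/2} B A^{-1/2})||_F =
#' sqrt(sum(log^2 lambda_i(A^{-1} B)))`. Invariant under congruence
#' `A -> W A W'` for any invertible `W`, i.e. under any affine
#' re-referencing of the sensor space.
#'
#' @param a,b SPD matrices of equal dimension.
#' @return Nonnegative distance; zero iff `a == b`.
#' @export
airm_distance <- function(a, b) {
  a <- as_spd(a); b <- as_spd(b)
  if (nrow(a) != nrow(b)) stop("dimension mismatch", call. = FALSE)
  w <- spd_powm(a, -0.5)
  m <- w %*% b %*% w
  ev <- eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values
  sqrt(sum(log(ev)^2))
}

#' Log-Euclidean distance
#'
#' `||logm(A) - logm(B)||_F`; cheaper than AIRM but only invariant under
#' orthogonal congruence.
#' @inheritParams airm_distance
#' @return Nonnegative distance.
#' @export
logeuclid_distance <- function(a, b) {
  a <- as_spd(a); b <- as_spd(b)
  if (nrow(a) != nrow(b)) stop("dimension mismatch", call. = FALSE)
  d <- spd_logm(a) - spd_logm(b)
  sqrt(sum(d^2))
}

#' Distance on the SPD manifold
#' @inheritParams airm_distance
#' @param metric `"airm"` (default) or `"logeuclid"`.
#' @return Nonnegative distance.
#' @export
spd_distance <- function(a, b, metric = c("airm", "logeuclid")) {
  metric <- match.arg(metric)
  switch(metric, airm = airm_distance(a, b),
         logeuclid = logeuclid_distance(a, b))
}

#' Riemannian (Fréchet) mean of SPD matrices
#'
#' For the AIRM metric: the standard fixed-point iteration
#' `M <- M^{1/2} exp(mean_i log(M^{-1/2} C_i M^{-1/2})) M^{1/2}`,
#' initialised at the arithmetic mean, stopping when the Frobenius norm of
#' the tangent-space mean (the Riemannian gradient) falls below `tol`. For
#' the log-Euclidean metric the mean is closed-form,
#' `exp(mean_i log C_i)`.
#'
#' @param covs Non-empty list of SPD matrices of common dimension.
#' @param metric `"airm"` or `"logeuclid"`.
#' @param tol Gradient-norm stopping tolerance (AIRM).
#' @param max_iter Maximum fixed-point iterations (AIRM).
#' @param weights Optional nonnegative weights (normalised internally).
#' @return An `spd` matrix minimising the summed squared distances.
#' @export
riemannian_mean <- function(covs, metric = c("airm", "logeuclid"),
                            tol = 1e-8, max_iter = 50L, weights = NULL) {
  metric <- match.arg(metric)
  if (length(covs) == 0L) stop("empty list of matrices", call. = FALSE)
  covs <- lapply(covs, as_spd)
  p <- nrow(covs[[1L]])
  if (any(vapply(covs, nrow, 1L) != p)) {
    stop("dimension mismatch", call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1, length(covs))
  stopifnot(length(weights) == length(covs), all(weights >= 0),
            sum(weights) > 0)
  weights <- weights / sum(weights)
  if (length(covs) == 1L) return(covs[[1L]])
  if (metric == "logeuclid") {
    acc <- matrix(0, p, p)
    for (i in seq_along(covs)) acc <- acc + weights[i] * spd_logm(covs[[i]])
    return(as_spd(spd_expm(acc)))
  }
  m <- Reduce(`+`, Map(`*`, covs, weights))
  for (iter in seq_len(max_iter)) {
    m_half <- spd_powm(m, 0.5)
    m_ihalf <- spd_powm(m, -0.5)
    tangent <- matrix(0, p, p)
    for (i in seq_along(covs)) {
      w <- m_ihalf %*% covs[[i]] %*% m_ihalf
      tangent <- tangent + weights[i] * spd_logm((w + t(w)) / 2)
    }
    grad_norm <- sqrt(sum(tangent^2))
    if (grad_norm <= tol) return(as_spd(m))
    m <- m_half %*% spd_expm(tangent) %*% m_half
    m <- (m + t(m)) / 2
  }
  stop(sprintf(
    "Riemannian mean did not converge in %d iterations (gradient norm %.3g)",
    max_iter, grad_norm), call. = FALSE)
}

#' Random SPD matrix
#'
#' `A A' + eps I` for a square standard-normal `A`; handy for tests and
#' simulations.
#' @param p Dimension.
#' @param eps Ridge added to guarantee strict positive definiteness.
#' @return An `spd` matrix.
#' @export
random_spd <- function(p, eps = 0.1) {
  a <- matrix(stats::rnorm(p * p), p, p)
  as_spd(tcrossprod(a) / p + eps * diag(p))
}
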