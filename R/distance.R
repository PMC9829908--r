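#' Squared Mahalanobis population-vector distance
#'
#' Distance of each score vector from a reference group: `(y - mu)' S^+ (y -
#' mu)` with `mu` and `S` the reference sample mean and covariance (n - 1
#' denominator). The covariance is inverted through an SVD pseudo-inverse
#' (singular values below `1e-10 * max` dropped), so near-singular reference
#' covariances — unavoidable when the reference group is barely larger than
#' the dimension — yield finite distances; a warning is raised whenever
#' `n_ref <= d + 1`.
#'
#' @param points Query score vectors: matrix (rows = samples) or a score
#'   tibble from [project_samples()].
#' @param reference Reference-group score vectors, same format, `n_ref >= 2`.
#' @return Numeric vector of squared distances (one per query row).
#' @export
mahalanobis_sq <- function(points, reference) {
  Y <- score_matrix(points)
  R <- score_matrix(reference)
  if (is.null(dim(Y))) Y <- matrix(Y, nrow = 1)
  if (nrow(R) < 2) stop("reference needs at least 2 samples.", call. = FALSE)
  d <- ncol(R)
  if (ncol(Y) != d) stop("dimension mismatch between points and reference.",
                         call. = FALSE)
  if (nrow(R) <= d + 1) {
    warning("reference group (n = ", nrow(R), ") barely exceeds dimension ",
            d, "; covariance is near-singular, using pseudo-inverse.",
            call. = FALSE)
  }
  mu <- colMeans(R)
  S <- stats::cov(R)
  Sinv <- pseudo_inverse(S, rtol = 1e-10)
  D <- sweep(Y, 2, mu)
  rowSums((D %*% Sinv) * D)
}

# symmetric pseudo-inverse via SVD with relative tolerance
pseudo_inverse <- function(S, rtol = 1e-10) {
  sv <- svd(S)
  keep <- sv$d > rtol * max(sv$d, 0)
  if (!any(keep)) return(matrix(0, nrow(S), ncol(S)))
  sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
}

#' Angle between a score vector and a reference mean vector
#'
#' `A = acos((u . v) / (|u| |v|))`, in radians within \[0, pi\]. The cosine
#' argument is clamped to \[-1, 1\] against floating-point overshoot.
#'
#' @param u Query vector (or matrix of row vectors).
#' @param v Reference vector (typically the reference-group mean score).
#' @return Angle(s) in radians.
#' @export
vector_angle <- function(u, v) {
  v <- as.numeric(v)
  if (sqrt(sum(v^2)) == 0) stop("reference vector has zero norm.", call. = FALSE)
  U <- if (is.matrix(u)) u else matrix(as.numeric(u), nrow = 1)
  nu <- sqrt(rowSums(U^2))
  if (any(nu == 0)) stop("zero query vector.", call. = FALSE)
  cosA <- pmin(1, pmax(-1, drop(U %*% v) / (nu * sqrt(sum(v^2)))))
  acos(cosA)
}
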