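#' Spatial transforms for pre-alignment
#'
#' Pre-alignment brings the unlabeled cloud into each labeled cloud's frame
#' in two steps: a landmark-based affine or thin-plate-spline fit from a
#' small manual correspondence table, followed by correspondence-free
#' coherent-point-drift refinement.  All three produce a
#' \code{spatial_transform} consumed by [apply_transform()].
#'
#' @name spatial_transform
NULL

new_transform <- function(kind, ...) {
  structure(list(kind = kind, ...), class = "spatial_transform")
}

#' @export
print.spatial_transform <- function(x, ...) {
  cat("<spatial_transform> kind:", x$kind, "\n")
  invisible(x)
}

as_points <- function(x) {
  if (inherits(x, "landmark_cloud")) x$points else as.matrix(x)
}

#' Affine least-squares fit from correspondences
#'
#' Finds the 3x3 matrix \eqn{A} and translation \eqn{t} minimizing
#' \eqn{\sum_i \|A x_i + t - y_i\|^2} over the correspondence pairs.
#'
#' @param src,dst matrices of corresponding 3D positions (>= 4 pairs;
#'   \code{src} must span 3 dimensions).
#' @return An affine \code{spatial_transform} with elements \code{A},
#'   \code{t} and the fit's RMS \code{residual}.
#' @export
affine_fit <- function(src, dst) {
  src <- as_points(src); dst <- as_points(dst)
  if (nrow(src) != nrow(dst)) stop("src and dst must pair up row by row")
  if (nrow(src) < 4L) stop("affine fit needs at least 4 correspondences")
  X <- cbind(src, 1)
  qr_x <- qr(X)
  if (qr_x$rank < 4L)
    stop("source points are rank-deficient (coplanar or collinear); ",
         "affine fit is underdetermined (rank ", qr_x$rank, " of 4)")
  B <- qr.coef(qr_x, dst)             # 4 x 3: rows = (A cols, t)
  fitted <- X %*% B
  new_transform("affine", A = t(B[1:3, , drop = FALSE]), t = as.numeric(B[4, ]),
                residual = sqrt(mean(rowSums((fitted - dst)^2))))
}

# 3D thin-plate kernel: U(r) = r (biharmonic in 3D)
tps_kernel <- function(a, b) {
  n <- nrow(a); m <- nrow(b)
  d2 <- outer(rowSums(a^2), rep(1, m)) + outer(rep(1, n), rowSums(b^2)) -
    2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

#' Thin-plate-spline fit from correspondences
#'
#' Standard 3D TPS with the \eqn{U(r) = r} kernel and an affine part.  With
#' \code{lambda = 0} the spline interpolates every control point exactly;
#' positive \code{lambda} trades exactness for smoothness, and in the large
#' lambda limit the map approaches the affine least-squares fit.
#'
#' @param src,dst matrices of corresponding 3D positions (>= 5 pairs in
#'   general position; \code{src} points must be pairwise distinct).
#' @param lambda regularization >= 0, in units of the mean control-point
#'   separation (scale-invariant).
#' @return A tps \code{spatial_transform} with control points and
#'   coefficients.
#' @export
tps_fit <- function(src, dst, lambda = 0) {
  src <- as_points(src); dst <- as_points(dst)
  if (nrow(src) != nrow(dst)) stop("src and dst must pair up row by row")
  n <- nrow(src)
  if (n < 5L) stop("TPS fit needs at least 5 correspondences")
  if (lambda < 0) stop("lambda must be >= 0")
  K <- tps_kernel(src, src)
  off <- K[upper.tri(K)]
  if (any(off <= 1e-6 * max(off)))
    stop("coincident source control points make the TPS kernel singular")
  P <- cbind(1, src)
  # Regularization scaled by the mean kernel entry keeps lambda unitless.
  # Sign: with U(r) = r the projected kernel Q2' K Q2 is negative definite,
  # so the ridge must be subtracted to move eigenvalues away from zero
  # (adding it would cross a singularity at intermediate lambda).
  Kl <- K - lambda * mean(off) * diag(n)
  # null-space solve of (Kl W + P A = dst, P' W = 0): well conditioned for
  # any lambda, unlike the naive bordered system
  qrp <- qr(P)
  if (qrp$rank < 4L)
    stop("source control points are coplanar/collinear; TPS underdetermined")
  Q <- qr.Q(qrp, complete = TRUE)
  Q1 <- Q[, 1:4, drop = FALSE]
  Q2 <- Q[, -(1:4), drop = FALSE]
  gam <- solve(crossprod(Q2, Kl %*% Q2), crossprod(Q2, dst))
  W <- Q2 %*% gam
  A <- solve(qr.R(qrp)[1:4, 1:4], crossprod(Q1, dst - Kl %*% W))
  new_transform("tps", control = src, W = W, A = A, lambda = lambda)
}

#' Coherent point drift refinement
#'
#' Correspondence-free nonrigid registration of the (already roughly
#' aligned) source cloud onto the target: a Gaussian-mixture EM in which the
#' source points move as a coherently regularized displacement field, so
#' nearby points move similarly.  Both clouds are normalized internally to
#' zero mean and unit RMS scale.
#'
#' @param src moving [landmark_cloud] (or matrix); the returned displacement
#'   field is defined at exactly these points.
#' @param dst fixed [landmark_cloud] (or matrix).
#' @param beta width of the Gaussian coherence kernel (normalized units).
#' @param lambda weight of the coherence regularizer.
#' @param outlier_weight uniform-component weight in [0, 1) absorbing
#'   unmatched points.
#' @param max_iters,tol EM stopping: iteration cap and minimum relative
#'   objective change.  On non-convergence the best iterate is returned with
#'   \code{converged = FALSE}, never an error.
#' @return A displacement-field \code{spatial_transform} valid only for the
#'   cloud it was fitted on (checked by [apply_transform()]).
#' @export
cpd_refine <- function(src, dst, beta = 2.0, lambda = 3.0,
                       outlier_weight = 0.1, max_iters = 100L, tol = 1e-6) {
  Y0 <- as_points(src); X0 <- as_points(dst)
  M <- nrow(Y0); N <- nrow(X0); D <- 3
  my <- colMeans(Y0); mx <- colMeans(X0)
  sy <- sqrt(mean(rowSums(sweep(Y0, 2, my)^2)))
  sx <- sqrt(mean(rowSums(sweep(X0, 2, mx)^2)))
  Y <- sweep(Y0, 2, my) / sy
  X <- sweep(X0, 2, mx) / sx
  G <- exp(-tps_kernel(Y, Y)^2 / (2 * beta^2))
  W <- matrix(0, M, D)
  TY <- Y
  sigma2 <- sum(tps_kernel(X, TY)^2) / (D * M * N)
  w <- outlier_weight
  prev_obj <- Inf
  converged <- FALSE
  for (it in seq_len(max_iters)) {
    # E-step: posteriors of mixture components given targets
    d2 <- outer(rep(1, M), rowSums(X^2)) + outer(rowSums(TY^2), rep(1, N)) -
      2 * tcrossprod(TY, X)
    num <- exp(-pmax(d2, 0) / (2 * sigma2))
    cconst <- (2 * pi * sigma2)^(D / 2) * w * M / ((1 - w) * N)
    den <- colSums(num) + cconst
    P <- sweep(num, 2, den, "/")
    P1 <- rowSums(P)
    Np <- sum(P1)
    # M-step: coherent displacement field
    A <- G * P1 + lambda * sigma2 * diag(M)   # diag(P1) %*% G + reg
    rhs <- P %*% X - P1 * Y
    W <- solve(A, rhs)
    TY <- Y + G %*% W
    xPx <- sum(colSums(P) * rowSums(X^2))
    yPy <- sum(P1 * rowSums(TY^2))
    trPXY <- sum(TY * (P %*% X))
    sigma2 <- max((xPx - 2 * trPXY + yPy) / (Np * D), 1e-10)
    obj <- -Np * D / 2 * log(sigma2)
    if (is.finite(prev_obj) &&
        abs(obj - prev_obj) < tol * (abs(prev_obj) + tol)) {
      converged <- TRUE
      break
    }
    prev_obj <- obj
  }
  disp <- sweep(TY * sx, 2, mx, "+") - Y0   # back to physical units
  new_transform("displacement_field", displacement = disp,
                source_points = Y0, converged = converged)
}

#' Apply a spatial transform to a landmark cloud
#'
#' Positions are mapped; names and metadata are untouched.  A displacement
#' field only applies to the exact cloud it was fitted on.
#'
#' @param t a \code{spatial_transform}.
#' @param cloud a [landmark_cloud] or position matrix.
#' @return Same type as \code{cloud}, with transformed positions.
#' @export
apply_transform <- function(t, cloud) {
  pts <- as_points(cloud)
  new_pts <- switch(t$kind,
    affine = sweep(pts %*% t(t$A), 2, t$t, "+"),
    tps = {
      U <- tps_kernel(pts, t$control)
      cbind(1, pts) %*% t$A + U %*% t$W
    },
    displacement_field = {
      if (!isTRUE(all.equal(pts, t$source_points, check.attributes = FALSE,
                            tolerance = 1e-12)))
        stop("displacement field applied to a cloud it was not fitted on")
      pts + t$displacement
    },
    stop("unknown transform kind: ", t$kind))
  dimnames(new_pts) <- list(NULL, c("x", "y", "z"))
  if (inherits(cloud, "landmark_cloud")) {
    cloud$points <- new_pts
    cloud
  } else new_pts
}

# landmark pre-fit from a correspondence table: warps the unlabeled cloud
# toward one labeled member's frame
prealign_fit <- function(labeled, unlabeled, corr, cfg) {
  if (!all(corr$identity %in% labeled$names))
    stop("correspondence identities missing from labeled cloud: ",
         paste(setdiff(corr$identity, labeled$names), collapse = ", "))
  src <- unlabeled$points[corr$index, , drop = FALSE]
  dst <- labeled$points[match(corr$identity, labeled$names), , drop = FALSE]
  if (cfg$prealign_mode == "tps") tps_fit(src, dst, lambda = cfg$tps_lambda)
  else affine_fit(src, dst)
}
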