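#' Least-squares fit of a general 9-coefficient ellipsoid
#'
#' Fits the general quadric
#' \deqn{Ax^2 + By^2 + Cz^2 + Dxy + Exz + Fyz + Gx + Hy + Iz = 1}
#' to a point cloud by linear least squares, then recovers the centre
#' (\eqn{-\tfrac12 M^{-1} (G,H,I)^T} with \eqn{M} the symmetric coefficient
#' matrix), semi-axes and rotation from the eigen-decomposition of the
#' centred quadric. Noiseless points on a true ellipsoid are recovered
#' exactly. When fed atomic coordinates (a filled cloud) the fitted surface
#' passes through a mean shell of the cloud, which is exactly what the
#' quadric-fit shape descriptor is meant to report.
#'
#' @param points An n x 3 matrix of coordinates (angstrom) or a
#'   `structure_model` (all atoms used).
#' @return An `ellipsoid_fit`: list with `coefficients` (A..I), `center`,
#'   `radii` (ascending), `rotation` (orthonormal, det +1; columns match
#'   `radii`), and `rss`.
#' @examples
#' u <- rbind(diag(3), -diag(3), c(1,1,0)/sqrt(2), c(1,0,1)/sqrt(2),
#'            c(0,1,1)/sqrt(2), c(-1,1,0)/sqrt(2), c(-1,0,1)/sqrt(2),
#'            c(0,-1,1)/sqrt(2))
#' fit_ellipsoid(u)$radii  # unit sphere: (1, 1, 1)
#' @export
fit_ellipsoid <- function(points) {
  P <- as_points_matrix(points)
  n <- nrow(P)
  if (n < 9L) stopf("need at least 9 points to fit 9 coefficients (got %d)", n)
  x <- P[, 1]; y <- P[, 2]; z <- P[, 3]
  X <- cbind(x^2, y^2, z^2, x * y, x * z, y * z, x, y, z)
  qrX <- qr(X)
  if (qrX$rank < 9L) {
    stopf("degenerate point set (design rank %d < 9): points may be coplanar or too few distinct positions",
          qrX$rank)
  }
  beta <- qr.coef(qrX, rep(1, n))
  rss <- sum((X %*% beta - 1)^2)
  names(beta) <- c("A", "B", "C", "D", "E", "F", "G", "H", "I")

  M <- matrix(c(beta["A"], beta["D"] / 2, beta["E"] / 2,
                beta["D"] / 2, beta["B"], beta["F"] / 2,
                beta["E"] / 2, beta["F"] / 2, beta["C"]), 3, 3)
  g <- beta[c("G", "H", "I")]
  center <- as.numeric(-0.5 * solve(M, g))
  # Centred quadric: y' M y = s with s = 1 + c' M c (since g = -2 M c).
  s <- 1 + as.numeric(center %*% M %*% center)
  eg <- eigen(M, symmetric = TRUE)
  if (any(eg$values / s <= 0)) {
    stopf("fitted quadric is not an ellipsoid (eigenvalue signs: %s; constant %s) - hyperboloid or degenerate fit",
          paste(sign(eg$values), collapse = ", "), format(s))
  }
  radii <- sqrt(s / eg$values)
  ord <- order(radii)
  radii <- radii[ord]
  rot <- eg$vectors[, ord, drop = FALSE]
  if (det(rot) < 0) rot[, 3] <- -rot[, 3]
  structure(list(coefficients = beta, center = center, radii = radii,
                 rotation = rot, rss = rss, n = n),
            class = "ellipsoid_fit")
}

#' @export
print.ellipsoid_fit <- function(x, ...) {
  cat(sprintf("<ellipsoid_fit> radii (%.2f, %.2f, %.2f) A, center (%.2f, %.2f, %.2f), rss %.3g (n = %d)\n",
              x$radii[1], x$radii[2], x$radii[3],
              x$center[1], x$center[2], x$center[3], x$rss, x$n))
  invisible(x)
}

#' Reduce an ellipsoid fit to a polar/equatorial spheroid
#'
#' The two most similar of the three semi-axes (smallest absolute difference;
#' ties broken by the lower-index pair after ascending sort) are averaged into
#' the equatorial radius; the remaining axis is the polar radius. Prolate
#' means polar > equatorial (rugby ball), oblate the reverse (disk).
#'
#' @param fit An `ellipsoid_fit`, or a numeric vector of 3 radii (angstrom).
#' @param sphere_tolerance Relative band within which the shape is classed as
#'   a sphere. Default 0.02.
#' @return A `spheroid_summary`: list with `r_polar`, `r_equatorial`,
#'   `shape_class` (`"prolate"`, `"oblate"` or `"sphere"`), `axis_direction`
#'   (unit vector; `NA` when no rotation is available) and `radii`.
#' @examples
#' spheroid_summary(c(26.9, 17.4, 20.7))  # prolate, r_eq = 19.05
#' @export
spheroid_summary <- function(fit, sphere_tolerance = 0.02) {
  if (is.numeric(fit) && length(fit) == 3L) {
    radii <- sort(fit)
    rot <- NULL
  } else {
    stopifnot(inherits(fit, "ellipsoid_fit"))
    radii <- fit$radii
    rot <- fit$rotation
  }
  pairs <- rbind(c(1, 2), c(1, 3), c(2, 3))
  diffs <- abs(radii[pairs[, 1]] - radii[pairs[, 2]])
  best <- which(diffs == min(diffs))[1]  # tie -> smaller-index pair
  eq_idx <- pairs[best, ]
  pol_idx <- setdiff(1:3, eq_idx)
  r_eq <- mean(radii[eq_idx])
  r_pol <- radii[pol_idx]
  shape <- if (abs(r_pol - r_eq) / r_eq < sphere_tolerance) {
    "sphere"
  } else if (r_pol > r_eq) "prolate" else "oblate"
  axis <- if (is.null(rot)) rep(NA_real_, 3) else rot[, pol_idx]
  structure(list(r_polar = r_pol, r_equatorial = r_eq, shape_class = shape,
                 axis_direction = axis, radii = radii),
            class = "spheroid_summary")
}

#' @export
print.spheroid_summary <- function(x, ...) {
  cat(sprintf("<spheroid_summary> %s: R_polar %.2f A, R_equatorial %.2f A\n",
              x$shape_class, x$r_polar, x$r_equatorial))
  invisible(x)
}

#' Extent radii of a filled cloud from its covariance
#'
#' For points uniformly filling a solid ellipsoid the covariance eigenvalues
#' equal (semi-axis)^2 / 5, so the semi-axes are recovered as
#' \eqn{\sqrt{5\lambda_i}}. This covariance-to-extent estimator complements
#' [fit_ellipsoid()] (which reports the mean-shell quadric of a filled cloud,
#' not its outer extent).
#'
#' @param points n x 3 matrix or `structure_model`.
#' @return List with `radii` (ascending), `rotation`, `center`.
#' @export
cloud_extent_radii <- function(points) {
  P <- as_points_matrix(points)
  if (nrow(P) < 4L) stopf("need at least 4 points")
  cv <- stats::cov(P)
  eg <- eigen(cv, symmetric = TRUE)
  radii <- sqrt(5 * pmax(eg$values, 0))
  ord <- order(radii)
  rot <- eg$vectors[, ord, drop = FALSE]
  if (det(rot) < 0) rot[, 3] <- -rot[, 3]
  list(radii = radii[ord], rotation = rot, center = colMeans(P))
}
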