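#' Direct least-squares ellipse fit from contour points
#'
#' `fit_conic()` fits the conic `A x^2 + B x y + C y^2 + D x + E y + F = 0`
#' minimizing the algebraic residual subject to the ellipse constraint
#' `4AC - B^2 = 1` (the ellipse-specific direct least-squares fit, computed
#' with the numerically stable partitioned eigen formulation). The constraint
#' guarantees that the returned conic is an ellipse whenever a fit exists.
#' Input coordinates are centered and scaled internally for conditioning; the
#' returned coefficients refer to the original coordinates and are normalized
#' to unit Euclidean norm.
#'
#' @param points two-column matrix (or data frame) of contour points; at
#'   least 5 distinct points are required, and they must not be collinear.
#' @return Named numeric vector `c(A, B, C, D, E, F)` of class
#'   `"conic_coefficients"` with `B^2 - 4AC < 0`.
#' @seealso [conic_to_ellipse()], [fit_pupil_ellipse()]
#' @export
fit_conic <- function(points) {
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 2) {
    stop("points must be a two-column numeric matrix")
  }
  if (nrow(points) < 5) stop("at least 5 contour points are required")
  if (anyDuplicated(signif(points, 12)) &&
      nrow(unique(signif(points, 12))) < 5) {
    stop("at least 5 distinct contour points are required")
  }

  # center and scale for numerical conditioning
  ctr <- colMeans(points)
  x0 <- points[, 1] - ctr[1]
  y0 <- points[, 2] - ctr[2]
  scl <- sqrt(mean(x0^2 + y0^2))
  if (scl < .Machine$double.eps) stop("no ellipse fit: degenerate point set")
  x <- x0 / scl
  y <- y0 / scl

  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  if (rcond(S3) < 1e-12) stop("no ellipse fit: degenerate or collinear points")
  Tm <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tm
  # premultiply by inverse of the constraint matrix [[0,0,2],[0,-1,0],[2,0,0]]
  M2 <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M2)
  V <- Re(ev$vectors)
  # the ellipse solution is the eigenvector with 4ac - b^2 > 0
  cond <- 4 * V[1, ] * V[3, ] - V[2, ]^2
  ok <- which(cond > 0)
  if (length(ok) == 0) stop("no ellipse fit: points do not determine an ellipse")
  a1 <- V[, ok[1]]
  a2 <- drop(Tm %*% a1)
  co <- c(a1, a2) # (A, B, C, D, E, F) in scaled coordinates

  # undo scaling: substitute x -> (x - cx)/s, y -> (y - cy)/s
  A <- co[1] / scl^2
  B <- co[2] / scl^2
  C <- co[3] / scl^2
  D <- -2 * co[1] * ctr[1] / scl^2 - co[2] * ctr[2] / scl^2 + co[4] / scl
  E <- -co[2] * ctr[1] / scl^2 - 2 * co[3] * ctr[2] / scl^2 + co[5] / scl
  F <- co[1] * ctr[1]^2 / scl^2 + co[2] * ctr[1] * ctr[2] / scl^2 +
    co[3] * ctr[2]^2 / scl^2 - co[4] * ctr[1] / scl - co[5] * ctr[2] / scl +
    co[6]
  out <- c(A = A, B = B, C = C, D = D, E = E, F = F)
  out <- out / sqrt(sum(out^2))
  if (out["B"]^2 - 4 * out["A"] * out["C"] >= 0) {
    stop("no ellipse fit: fitted conic is not an ellipse")
  }
  structure(out, class = "conic_coefficients")
}

#' Convert a conic to ellipse parameters
#'
#' Closed-form conversion of ellipse conic coefficients to center, semi-axes
#' and minor-axis angle. The angle reported is that of the MINOR axis with the
#' x-axis, in `[0, 180)` — for a projected pupil this equals the gaze
#' direction angle (RDA) modulo 180. Near-circular conics
#' (`semi_major/semi_minor` below `circularity_threshold`) have an
#' ill-conditioned axis direction and are flagged `degenerate`.
#'
#' @param conic a `"conic_coefficients"` vector from [fit_conic()], or any
#'   numeric vector `(A, B, C, D, E, F)` with `B^2 - 4AC < 0`.
#' @param circularity_threshold minimum axis ratio below which the minor-axis
#'   direction is considered unreliable.
#' @return A single-row [pupil_ellipses] object.
#' @export
conic_to_ellipse <- function(conic, circularity_threshold = 1.001) {
  co <- as.numeric(conic)
  if (length(co) != 6) stop("conic must have 6 coefficients (A,B,C,D,E,F)")
  A <- co[1]; B <- co[2]; C <- co[3]; D <- co[4]; E <- co[5]; F <- co[6]
  if (B^2 - 4 * A * C >= 0) stop("conic is not an ellipse")
  # the conic is defined up to global sign; canonicalize so A + C > 0
  if (A + C < 0) {
    A <- -A; B <- -B; C <- -C; D <- -D; E <- -E; F <- -F
  }
  Q <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  ctr <- solve(2 * Q, -c(D, E))
  # conic value at the center; axes satisfy lambda_i * s_i^2 = -F0
  F0 <- A * ctr[1]^2 + B * ctr[1] * ctr[2] + C * ctr[2]^2 +
    D * ctr[1] + E * ctr[2] + F
  eg <- eigen(Q, symmetric = TRUE)
  lam <- eg$values
  if (any(-F0 / lam <= 0)) stop("conic is not a real ellipse")
  axes <- sqrt(-F0 / lam)
  # smaller eigenvalue <-> longer axis; minor axis along the larger eigenvalue
  i_min <- which.max(lam)
  semi_minor <- axes[i_min]
  semi_major <- axes[which.min(lam)]
  minor_dir <- eg$vectors[, i_min]
  ang <- norm_angle180(rad2deg(atan2(minor_dir[2], minor_dir[1])))
  degen <- semi_major / semi_minor < circularity_threshold
  pupil_ellipses(ctr[1], ctr[2], semi_major, semi_minor,
                 if (degen) NA_real_ else ang,
                 label = "fit", degenerate = degen)
}

#' Fit a pupil ellipse from a contour
#'
#' Convenience wrapper: [fit_conic()] followed by [conic_to_ellipse()].
#'
#' @inheritParams fit_conic
#' @inheritParams conic_to_ellipse
#' @return A single-row [pupil_ellipses] object.
#' @examples
#' e <- pupil_ellipses(100, 100, 50, 25, 30)
#' fit_pupil_ellipse(ellipse_contour_points(e, 64))
#' @export
fit_pupil_ellipse <- function(points, circularity_threshold = 1.001) {
  conic_to_ellipse(fit_conic(points), circularity_threshold)
}

#' Algebraic residual of points on a conic
#'
#' @param conic coefficients `(A,B,C,D,E,F)`.
#' @param points two-column matrix.
#' @return Numeric vector of `A x^2 + B xy + C y^2 + D x + E y + F` values.
#' @keywords internal
conic_residual <- function(conic, points) {
  co <- as.numeric(conic)
  x <- points[, 1]; y <- points[, 2]
  co[1] * x^2 + co[2] * x * y + co[3] * y^2 + co[4] * x + co[5] * y + co[6]
}
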