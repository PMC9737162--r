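#' Slope of the minor-axis line from the gaze direction angle
#'
#' The minor-axis line of a projected pupil has slope `tan(RDA)`. The slope
#' form is singular at RDA = 90 degrees (a vertical line); use
#' [minor_axis_line()], whose normal-form representation covers that case.
#'
#' @param rda gaze direction angle, degrees in `[0, 180)`, excluding 90.
#' @return The slope `tan(rda)`.
#' @examples
#' gradient_from_rda(45) # 1
#' @export
gradient_from_rda <- function(rda) {
  stopifnot(is.numeric(rda), all(rda >= 0), all(rda < 180))
  if (any(abs(rda - 90) < 1e-9)) {
    stop("vertical line at rda = 90 degrees: tan undefined; use minor_axis_line()")
  }
  tan(deg2rad(rda))
}

#' Minor-axis line of a projected pupil
#'
#' Converts each ellipse into the straight line that extends its minor axis,
#' in normal form `a*x + b*y = c` with `a = sin(theta)`, `b = -cos(theta)`,
#' `c = a*cx + b*cy`, where `theta` is the minor-axis angle. This coincides
#' with the slope form `y = G x - G xc + yc`, `G = tan(theta)`, wherever the
#' slope is defined, and additionally covers vertical lines. All minor-axis
#' lines of one eye pass through its rotational center.
#'
#' Coefficients are normalized (`a^2 + b^2 = 1`) and sign-canonicalized
#' (`a > 0`, or `b > 0` when `a = 0`), so equal lines have equal coefficient
#' tuples.
#'
#' @param e a [pupil_ellipses] object; direction-degenerate ellipses (flagged,
#'   or with axis ratio below `circularity_threshold`) are refused.
#' @param circularity_threshold minimum `semi_major/semi_minor` ratio for the
#'   minor-axis direction to be considered defined.
#' @return A data frame of class `"minor_axis_lines"` with columns `a`, `b`,
#'   `c` (line `a*x + b*y = c`), `anchor_x`, `anchor_y` (the ellipse center)
#'   and `angle` (degrees).
#' @examples
#' minor_axis_line(pupil_ellipses(100, 100, 50, 30, 45))
#' @export
minor_axis_line <- function(e, circularity_threshold = 1.001) {
  e <- as_pupil_ellipses(e)
  ratio <- ifelse(e$semi_minor > 0, e$semi_major / e$semi_minor, Inf)
  bad <- e$degenerate | is.na(e$minor_axis_angle) | ratio < circularity_threshold
  if (any(bad)) {
    stop("undefined minor axis: ", sum(bad),
         " direction-degenerate (near-circular) ellipse(s)")
  }
  th <- deg2rad(e$minor_axis_angle)
  a <- sin(th)
  b <- -cos(th)
  # canonical sign: a > 0, or b > 0 when a == 0
  flip <- a < 0 | (a == 0 & b < 0)
  a[flip] <- -a[flip]
  b[flip] <- -b[flip]
  cc <- a * e$cx + b * e$cy
  out <- data.frame(a = a, b = b, c = cc,
                    anchor_x = e$cx, anchor_y = e$cy,
                    angle = e$minor_axis_angle)
  class(out) <- c("minor_axis_lines", "data.frame")
  out
}

#' Least-squares intersection of a set of lines
#'
#' Stacks the line equations `a_i x + b_i y = c_i` into an overdetermined
#' linear system and solves for the single point that all lines (nearly) pass
#' through, using the Moore-Penrose pseudo-inverse computed by singular value
#' decomposition. When the lines are concurrent the common point is returned
#' exactly (to numerical precision); otherwise the least-squares solution
#' minimizes the sum of squared perpendicular distances to the (unit-normal)
#' lines.
#'
#' @param lines a `"minor_axis_lines"` data frame (or any data frame with
#'   numeric columns `a`, `b`, `c`), at least two rows.
#' @param tol relative singular-value cutoff for the rank decision.
#' @return Named numeric vector `c(x, y)`.
#' @examples
#' ln <- minor_axis_line(pupil_ellipses(c(500, 250), c(250, 500),
#'                                      c(50, 50), c(30, 30), c(0, 90)))
#' intersect_lines(ln) # c(250, 250)
#' @export
intersect_lines <- function(lines, tol = 1e-12) {
  if (!is.data.frame(lines) || !all(c("a", "b", "c") %in% names(lines))) {
    stop("lines must be a data frame with columns a, b, c")
  }
  if (nrow(lines) < 2) stop("at least two lines are required")
  sol <- svd_lsq(cbind(lines$a, lines$b), lines$c, tol)
  if (is.null(sol)) stop("no unique intersection: lines are all parallel (rank < 2)")
  c(x = sol[1], y = sol[2])
}

# Minimum-norm least-squares solution of M %*% x = rhs via SVD pseudo-inverse;
# NULL when rank < ncol(M) at relative cutoff `tol`.
svd_lsq <- function(M, rhs, tol = 1e-12) {
  sv <- svd(M)
  keep <- sv$d > tol * sv$d[1]
  if (sum(keep) < ncol(M)) return(NULL)
  drop(sv$v %*% ((crossprod(sv$u, rhs)) / sv$d))
}

#' Angular residual of an ellipse with respect to a candidate center
#'
#' The unsigned angle, in degrees within `[0, 90]`, between an ellipse's
#' minor-axis direction and the direction from its center to `point`, both
#' taken modulo 180 (lines are undirected). A zero residual means the
#' minor-axis line passes exactly through `point`. This is the inlier metric
#' of the RANSAC consensus test: an ellipse supports a candidate rotational
#' center when its residual is at most the allowable angle error.
#'
#' A point coincident with the ellipse center (within 1e-9 px) has residual 0:
#' a line passes through its own anchor. Direction-degenerate ellipses return
#' `NA`.
#'
#' @param e a [pupil_ellipses] object.
#' @param point numeric `c(x, y)`.
#' @return Numeric vector of residuals in degrees, one per ellipse.
#' @examples
#' angular_residual(pupil_ellipses(0, 0, 50, 30, 0), c(1, 1)) # 45
#' @export
angular_residual <- function(e, point) {
  e <- as_pupil_ellipses(e)
  stopifnot(is.numeric(point), length(point) == 2)
  dx <- point[1] - e$cx
  dy <- point[2] - e$cy
  ang <- rad2deg(atan2(dy, dx))
  d <- abs((ang - e$minor_axis_angle) %% 180)
  d <- pmin(d, 180 - d)
  d[dx * dx + dy * dy < 1e-18] <- 0
  d[e$degenerate] <- NA_real_
  d
}

#' Orbit radius from inlier ellipses and an estimated center
#'
#' For an ideal projected pupil, the distance of the ellipse center from the
#' rotational center is `d = R * sin(RAE)` while the foreshortening gives
#' `cos(RAE) = semi_minor / semi_major`; hence each ellipse yields a radius
#' estimate `R_i = d_i / sin(RAE_i)`. The returned estimate is the unweighted
#' mean of `R_i` over admissible ellipses — those with `sin(RAE_i) >=
#' min_sin`, since `R_i` is ill-conditioned as the projection approaches a
#' circle.
#'
#' @param e a [pupil_ellipses] object (typically the inliers of a fit).
#' @param orcp numeric `c(x, y)`, the estimated rotational center.
#' @param min_sin admissibility threshold on `sin(RAE)`; default 0.1
#'   (RAE of about 5.7 degrees).
#' @return Estimated orbit radius, pixels.
#' @export
estimate_orbit_radius <- function(e, orcp, min_sin = 0.1) {
  e <- as_pupil_ellipses(e)
  stopifnot(is.numeric(orcp), length(orcp) == 2)
  ratio <- ifelse(e$semi_major > 0, pmin(e$semi_minor / e$semi_major, 1), NA_real_)
  s <- sin(acos(ratio))
  d <- sqrt((e$cx - orcp[1])^2 + (e$cy - orcp[2])^2)
  ok <- !is.na(s) & s >= min_sin
  if (!any(ok)) stop("radius undetermined: no ellipse with sin(RAE) >= ", min_sin)
  mean(d[ok] / s[ok])
}
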