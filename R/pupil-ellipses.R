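#' Construct a set of projected-pupil ellipses
#'
#' A projected pupil contour (PPC) is the image of the circular pupil seen by
#' the camera: an ellipse whose minor-axis direction encodes the gaze
#' direction. `pupil_ellipses()` builds the data frame used throughout the
#' package: one row per ellipse, with its center, semi-axes and the angle of
#' its minor axis.
#'
#' The minor-axis angle is stored modulo 180 degrees because the minor-axis
#' line is undirected. An ellipse that is exactly circular has no defined
#' minor-axis direction; such rows are marked `degenerate = TRUE` and carry an
#' `NA` angle so that downstream line extraction can refuse them explicitly
#' instead of working with an arbitrary direction.
#'
#' @param cx,cy ellipse center coordinates, pixels.
#' @param semi_major,semi_minor semi-axis lengths, pixels; `semi_major >=
#'   semi_minor >= 0` is required row-wise.
#' @param minor_axis_angle angle of the minor axis with the x-axis, degrees;
#'   normalized into `[0, 180)`. May be `NA` only where `degenerate` is `TRUE`.
#' @param label character tag per ellipse, conventionally `"ideal"` or
#'   `"noise"`; recycled.
#' @param degenerate logical, `TRUE` where the minor-axis direction is
#'   undefined (circular projection); recycled.
#' @return A `data.frame` of class `"pupil_ellipses"` with columns `cx`, `cy`,
#'   `semi_major`, `semi_minor`, `minor_axis_angle`, `label`, `degenerate`.
#' @examples
#' pupil_ellipses(100, 120, 50, 40, 30)
#' @export
pupil_ellipses <- function(cx, cy, semi_major, semi_minor, minor_axis_angle,
                           label = "ideal", degenerate = FALSE) {
  n <- length(cx)
  recycle1 <- function(v) if (length(v) == 1L && n > 1L) rep_len(v, n) else v
  cy <- recycle1(cy)
  semi_major <- recycle1(semi_major)
  semi_minor <- recycle1(semi_minor)
  minor_axis_angle <- recycle1(minor_axis_angle)
  stopifnot(
    length(cy) == n, length(semi_major) == n, length(semi_minor) == n,
    length(minor_axis_angle) == n
  )
  label <- rep_len(as.character(label), n)
  degenerate <- rep_len(as.logical(degenerate), n)
  if (any(!is.finite(cx)) || any(!is.finite(cy))) {
    stop("ellipse centers must be finite")
  }
  if (any(semi_minor < 0) || any(semi_major < semi_minor)) {
    stop("semi-axes must satisfy semi_major >= semi_minor >= 0")
  }
  ang <- ifelse(degenerate, NA_real_, norm_angle180(minor_axis_angle))
  if (any(!degenerate & !is.finite(ang))) {
    stop("minor_axis_angle must be finite for non-degenerate ellipses")
  }
  out <- data.frame(
    cx = as.numeric(cx), cy = as.numeric(cy),
    semi_major = as.numeric(semi_major), semi_minor = as.numeric(semi_minor),
    minor_axis_angle = as.numeric(ang),
    label = label, degenerate = degenerate,
    stringsAsFactors = FALSE
  )
  class(out) <- c("pupil_ellipses", "data.frame")
  out
}

as_pupil_ellipses <- function(x) {
  if (inherits(x, "pupil_ellipses")) return(x)
  req <- c("cx", "cy", "semi_major", "semi_minor", "minor_axis_angle")
  if (!is.data.frame(x) || !all(req %in% names(x))) {
    stop("expected a pupil_ellipses object or a data frame with columns ",
         paste(req, collapse = ", "))
  }
  pupil_ellipses(
    x$cx, x$cy, x$semi_major, x$semi_minor, x$minor_axis_angle,
    label = if ("label" %in% names(x)) x$label else "ideal",
    degenerate = if ("degenerate" %in% names(x)) x$degenerate
                 else is.na(x$minor_axis_angle)
  )
}

#' @export
print.pupil_ellipses <- function(x, ...) {
  cat(sprintf(
    "Projected-pupil ellipse set: %d ellipses (%s)\n", nrow(x),
    paste(sprintf("%d %s", as.vector(table(x$label)),
                  names(table(x$label))), collapse = ", ")
  ))
  if (any(x$degenerate)) {
    cat(sprintf("  %d direction-degenerate (circular) ellipses\n",
                sum(x$degenerate)))
  }
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat(sprintf("  ... %d more rows\n", nrow(x) - 10))
  invisible(x)
}

#' Read and write pupil-ellipse tables
#'
#' Plain CSV interchange format with fixed columns
#' `cx,cy,semi_major,semi_minor,minor_axis_angle,label` (angles in degrees).
#' Direction-degenerate ellipses are written with an empty angle field and
#' recovered as degenerate on read.
#'
#' @param x a [pupil_ellipses] object.
#' @param path path to a CSV file.
#' @return `read_pupils()` returns a [pupil_ellipses] object;
#'   `write_pupils()` returns `path` invisibly.
#' @export
write_pupils <- function(x, path) {
  x <- as_pupil_ellipses(x)
  utils::write.csv(
    as.data.frame(x)[c("cx", "cy", "semi_major", "semi_minor",
                       "minor_axis_angle", "label")],
    path, row.names = FALSE, quote = FALSE, na = ""
  )
  invisible(path)
}

#' @rdname write_pupils
#' @export
read_pupils <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("cx", "cy", "semi_major", "semi_minor", "minor_axis_angle", "label")
  if (!all(req %in% names(df))) {
    stop("pupil CSV must have columns ", paste(req, collapse = ","))
  }
  pupil_ellipses(df$cx, df$cy, df$semi_major, df$semi_minor,
                 df$minor_axis_angle, label = df$label,
                 degenerate = is.na(df$minor_axis_angle))
}

#' Sample points on an ellipse boundary
#'
#' Generates `n_points` points at uniformly spaced parametric angles on the
#' boundary of one ellipse, optionally perturbed by isotropic Gaussian noise.
#' Used to emulate a pupil contour extracted from a camera frame, i.e. the
#' input that [fit_pupil_ellipse()] consumes.
#'
#' @param e a single-row [pupil_ellipses] object (or a list with fields `cx`,
#'   `cy`, `semi_major`, `semi_minor`, `minor_axis_angle`).
#' @param n_points number of boundary points, at least 5 (a conic has five
#'   degrees of freedom).
#' @param noise_sd standard deviation of the isotropic point noise, pixels.
#' @param seed optional integer seed; the caller's RNG stream is restored.
#' @return A two-column numeric matrix with columns `x`, `y`.
#' @examples
#' e <- pupil_ellipses(0, 0, 50, 30, 45)
#' pts <- ellipse_contour_points(e, 16)
#' @export
ellipse_contour_points <- function(e, n_points = 64, noise_sd = 0, seed = NULL) {
  if (is.data.frame(e)) {
    stopifnot(nrow(e) == 1L)
    e <- as.list(e)
  }
  if (n_points < 5) stop("n_points must be at least 5 (conic fit underdetermined)")
  theta <- e$minor_axis_angle
  if (is.na(theta)) theta <- 0 # circle: boundary does not depend on orientation
  phi <- deg2rad(theta + 90) # major-axis direction
  th <- deg2rad(theta)
  t <- seq(0, 2 * pi, length.out = n_points + 1L)[-(n_points + 1L)]
  x <- e$cx + e$semi_major * cos(t) * cos(phi) + e$semi_minor * sin(t) * cos(th)
  y <- e$cy + e$semi_major * cos(t) * sin(phi) + e$semi_minor * sin(t) * sin(th)
  pts <- cbind(x = x, y = y)
  if (noise_sd > 0) {
    pts <- pts + with_seed(seed, matrix(stats::rnorm(2 * n_points, sd = noise_sd),
                                        ncol = 2))
  }
  pts
}

#' Read a contour point list
#'
#' @param path CSV file with header `x,y`, one boundary point per row.
#' @return Two-column numeric matrix.
#' @export
read_contour <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("x", "y") %in% names(df))) stop("contour CSV must have columns x,y")
  cbind(x = as.numeric(df$x), y = as.numeric(df$y))
}
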