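#' Ground-truth pupil orbit model
#'
#' The pupil orbit model describes the eye as a pupil of radius `pupil_radius`
#' whose center travels on a sphere of radius `rotation_radius` about the
#' ocular rotational center point (ORCP). The gaze direction is given by two
#' angles: the rotation angle of the eye (RAE), the deviation of the gaze from
#' the camera axis, and the rotation direction angle (RDA), the direction of
#' that deviation in the image plane.
#'
#' @param orcp_x,orcp_y true rotational center, pixels.
#' @param rotation_radius orbit (rotation) radius of the pupil center, pixels,
#'   positive.
#' @param pupil_radius physical pupil radius, pixels, positive and smaller
#'   than `rotation_radius`.
#' @return An object of class `"hpom_model"`.
#' @examples
#' m <- hpom_model(250, 250, 250, 50)
#' project_pupil(m, rae = 30, rda = 90)
#' @export
hpom_model <- function(orcp_x, orcp_y, rotation_radius, pupil_radius) {
  stopifnot(
    is.finite(orcp_x), is.finite(orcp_y),
    rotation_radius > 0, pupil_radius > 0,
    pupil_radius < rotation_radius
  )
  structure(
    list(orcp_x = orcp_x, orcp_y = orcp_y,
         rotation_radius = rotation_radius, pupil_radius = pupil_radius),
    class = "hpom_model"
  )
}

#' @export
print.hpom_model <- function(x, ...) {
  cat(sprintf(
    "Pupil orbit model: ORCP (%g, %g), rotation radius %g px, pupil radius %g px\n",
    x$orcp_x, x$orcp_y, x$rotation_radius, x$pupil_radius
  ))
  invisible(x)
}

#' Orthographic projection of the pupil
#'
#' Projects the circular pupil onto the image plane for gaze angles
#' (RAE, RDA) under an orthographic camera. The projected pupil contour is an
#' ellipse with
#' center `ORCP + R * sin(RAE) * (cos RDA, sin RDA)`, semi-major axis equal to
#' the pupil radius `r`, semi-minor axis `r * cos(RAE)` (foreshortening along
#' the radial direction), and minor axis pointing along the RDA. Two
#' consequences drive the whole estimation method: the minor-axis line of
#' every projected pupil passes through the ORCP, and the distance of the
#' ellipse center from the ORCP is `R * sin(RAE)` — plotted against RAE the
#' centers trace a sine wave.
#'
#' At `rae = 0` the projection is an exact circle and the minor-axis direction
#' is undefined; the returned ellipse is flagged `degenerate` instead of being
#' given an arbitrary angle.
#'
#' @param model an [hpom_model].
#' @param rae rotation angle(s) of the eye, degrees in `[0, 90]`.
#' @param rda rotation direction angle(s), degrees in `[0, 360)`.
#' @return A [pupil_ellipses] object, one row per `(rae, rda)` pair.
#' @export
project_pupil <- function(model, rae, rda) {
  stopifnot(inherits(model, "hpom_model"), length(rae) == length(rda))
  if (any(rae < 0 | rae > 90)) stop("rae must lie in [0, 90] degrees")
  if (any(rda < 0 | rda >= 360)) stop("rda must lie in [0, 360) degrees")
  r <- model$pupil_radius
  s <- sin(deg2rad(rae))
  cx <- model$orcp_x + model$rotation_radius * s * cos(deg2rad(rda))
  cy <- model$orcp_y + model$rotation_radius * s * sin(deg2rad(rda))
  degen <- rae == 0
  pupil_ellipses(
    cx = cx, cy = cy,
    semi_major = rep_len(r, length(rae)),
    semi_minor = r * cos(deg2rad(rae)),
    minor_axis_angle = ifelse(degen, NA_real_, norm_angle180(rda)),
    label = "ideal", degenerate = degen
  )
}

#' Simulate ideal and noise pupil-ellipse datasets
#'
#' `sim_ideal_pupils()` draws gaze angles RAE ~ Uniform(`rae_range`),
#' RDA ~ Uniform[0, 360) and projects the pupil through [project_pupil()]; all
#' resulting minor-axis lines concur at the model ORCP. `sim_noise_pupils()`
#' draws unrelated ellipses: centers uniform over the image space, minor-axis
#' angles uniform over [0, 180), semi-axes uniform over `axis_range` (sorted
#' so the major axis is the longer). `sim_pupil_dataset()` concatenates both,
#' reproducing the benchmark design of 100 ideal plus 100 noise ellipses on a
#' 500 x 500 px space with the true ORCP at its center.
#'
#' @param model an [hpom_model]; the hidden truth behind the ideal ellipses.
#' @param n,n_ideal,n_noise number of ellipses to generate.
#' @param rae_range RAE sampling interval, degrees; the lower endpoint must be
#'   strictly positive (RAE = 0 projects a direction-degenerate circle) and
#'   the upper at most 90.
#' @param width,height extent of the image space, pixels.
#' @param axis_range semi-axis sampling interval for noise ellipses, pixels.
#' @param seed optional integer seed making generation reproducible; the
#'   caller's RNG stream is restored afterwards.
#' @return A [pupil_ellipses] object (`label` is `"ideal"` or `"noise"`).
#' @examples
#' d <- sim_pupil_dataset(seed = 1)
#' table(d$label)
#' @export
sim_ideal_pupils <- function(model, n = 100, rae_range = c(5, 85), seed = NULL) {
  stopifnot(inherits(model, "hpom_model"), n >= 1)
  if (length(rae_range) != 2 || rae_range[1] <= 0 || rae_range[2] > 90 ||
      rae_range[1] >= rae_range[2]) {
    stop("rae_range must satisfy 0 < rae_min < rae_max <= 90 ",
         "(rae_min = 0 would request direction-degenerate samples)")
  }
  with_seed(seed, {
    rae <- stats::runif(n, rae_range[1], rae_range[2])
    rda <- stats::runif(n, 0, 360)
    project_pupil(model, rae, rda)
  })
}

#' @rdname sim_ideal_pupils
#' @export
sim_noise_pupils <- function(n = 100, width = 500, height = 500,
                             axis_range = c(5, 60), seed = NULL) {
  stopifnot(n >= 0, width > 0, height > 0,
            length(axis_range) == 2, axis_range[1] > 0,
            axis_range[1] <= axis_range[2])
  if (n == 0) {
    return(pupil_ellipses(numeric(0), numeric(0), numeric(0), numeric(0),
                          numeric(0), label = character(0),
                          degenerate = logical(0)))
  }
  with_seed(seed, {
    cx <- stats::runif(n, 0, width)
    cy <- stats::runif(n, 0, height)
    ax1 <- stats::runif(n, axis_range[1], axis_range[2])
    ax2 <- stats::runif(n, axis_range[1], axis_range[2])
    ang <- stats::runif(n, 0, 180)
    pupil_ellipses(cx, cy, pmax(ax1, ax2), pmin(ax1, ax2), ang,
                   label = "noise")
  })
}

#' @rdname sim_ideal_pupils
#' @export
sim_pupil_dataset <- function(model = hpom_model(250, 250, 250, 50),
                              n_ideal = 100, n_noise = 100,
                              width = 500, height = 500,
                              rae_range = c(5, 85), axis_range = c(5, 60),
                              seed = NULL) {
  stopifnot(n_ideal + n_noise >= 2)
  with_seed(seed, {
    ideal <- if (n_ideal > 0) sim_ideal_pupils(model, n_ideal, rae_range) else NULL
    noise <- sim_noise_pupils(n_noise, width, height, axis_range)
    out <- rbind(as.data.frame(ideal), as.data.frame(noise))
    class(out) <- c("pupil_ellipses", "data.frame")
    rownames(out) <- NULL
    out
  })
}
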