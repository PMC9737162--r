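#' @export
print.hpom <- function(x, digits = max(4L, getOption("digits") - 3L), ...) {
  cat("Pupil orbit model fit (RANSAC minor-axis line intersection)\n")
  cat("Call: ", deparse(x$call), "\n", sep = "")
  co <- coef(x)
  cat(sprintf("  ORCP:   (%s, %s) px\n",
              format(co["orcp_x"], digits = digits),
              format(co["orcp_y"], digits = digits)))
  cat(sprintf("  Radius: %s px\n", format(co["radius"], digits = digits)))
  cat(sprintf("  Cost:   %d of %d ellipses in the consensus set (ES = %d, AAE = %g deg)\n",
              x$cost, nrow(x$data), x$es, x$aae))
  invisible(x)
}

#' @export
coef.hpom <- function(object, ...) object$coefficients

#' Angular residuals of a pupil orbit model fit
#'
#' @param object an [hpom] fit.
#' @param ... unused.
#' @return Angular residual (degrees, in `[0, 90]`) of each ellipse's
#'   minor-axis line with respect to the estimated rotational center; `NA`
#'   for direction-degenerate ellipses.
#' @export
residuals.hpom <- function(object, ...) object$residuals

#' Summarize a pupil orbit model fit
#'
#' @param object an [hpom] fit.
#' @param ... unused.
#' @return An object of class `"summary.hpom"`.
#' @export
summary.hpom <- function(object, ...) {
  r <- object$residuals
  lab <- object$data$label
  out <- list(
    call = object$call,
    coefficients = coef(object),
    cost = object$cost,
    n = nrow(object$data),
    es = object$es, aae = object$aae,
    iterations_used = object$iterations_used,
    pupil_radius = object$pupil_radius,
    inlier_labels = table(lab[object$inliers]),
    resid_quartiles = stats::quantile(r, na.rm = TRUE)
  )
  class(out) <- "summary.hpom"
  out
}

#' @export
print.summary.hpom <- function(x, digits = 4L, ...) {
  cat("Pupil orbit model fit\nCall: ", deparse(x$call), "\n\n", sep = "")
  print(round(x$coefficients, digits))
  cat(sprintf("\nConsensus set: %d / %d ellipses (ES = %d, AAE = %g deg, %d rounds)\n",
              x$cost, x$n, x$es, x$aae, x$iterations_used))
  if (length(x$inlier_labels)) {
    cat("  by label: ",
        paste(sprintf("%s = %d", names(x$inlier_labels), x$inlier_labels),
              collapse = ", "), "\n", sep = "")
  }
  cat(sprintf("Implied pupil radius: %s px\n",
              format(x$pupil_radius, digits = digits)))
  cat("Angular residuals (deg):\n")
  print(signif(x$resid_quartiles, 3))
  invisible(x)
}

#' Predict projected-pupil ellipses from a fitted orbit model
#'
#' Given gaze angles, predicts where and how the pupil would appear under the
#' fitted orbit: center at `ORCP + R sin(RAE) (cos RDA, sin RDA)`, semi-major
#' axis equal to the implied pupil radius, semi-minor axis foreshortened by
#' `cos(RAE)`, minor axis along the RDA.
#'
#' @param object an [hpom] fit.
#' @param newdata data frame with columns `rae` and `rda` (degrees).
#' @param ... unused.
#' @return A [pupil_ellipses] object, one row per gaze direction.
#' @export
predict.hpom <- function(object, newdata, ...) {
  if (missing(newdata) || !all(c("rae", "rda") %in% names(newdata))) {
    stop("newdata must be a data frame with columns rae and rda (degrees)")
  }
  m <- hpom_model(coef(object)[["orcp_x"]], coef(object)[["orcp_y"]],
                  coef(object)[["radius"]], object$pupil_radius)
  project_pupil(m, newdata$rae, newdata$rda)
}

#' Simulate pupil-ellipse datasets from a fitted orbit model
#'
#' Draws new ideal projected pupils from the fitted rotational center, orbit
#' radius and implied pupil radius, mirroring [sim_ideal_pupils()].
#'
#' @param object an [hpom] fit.
#' @param nsim number of datasets.
#' @param seed optional integer seed.
#' @param n ellipses per dataset.
#' @param rae_range RAE sampling interval, degrees.
#' @param ... unused.
#' @return A list of `nsim` [pupil_ellipses] objects.
#' @export
simulate.hpom <- function(object, nsim = 1, seed = NULL, n = 100,
                          rae_range = c(5, 85), ...) {
  m <- hpom_model(coef(object)[["orcp_x"]], coef(object)[["orcp_y"]],
                  coef(object)[["radius"]], object$pupil_radius)
  with_seed(seed, lapply(seq_len(nsim), function(i) {
    sim_ideal_pupils(m, n = n, rae_range = rae_range)
  }))
}

#' Plot a pupil orbit model fit
#'
#' Draws the ellipse centers (inliers filled, outliers open), the minor-axis
#' lines of the consensus set, and the estimated rotational center.
#'
#' @param x an [hpom] fit.
#' @param show_lines draw the inlier minor-axis lines.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.hpom <- function(x, show_lines = TRUE, ...) {
  d <- x$data
  inl <- seq_len(nrow(d)) %in% x$inliers
  graphics::plot(d$cx, d$cy, asp = 1,
                 pch = ifelse(inl, 19, 1),
                 col = ifelse(inl, "steelblue", "grey60"),
                 xlab = "x (px)", ylab = "y (px)", ...)
  if (show_lines && length(x$inliers)) {
    ln <- minor_axis_line(d[x$inliers, , drop = FALSE],
                          circularity_threshold = x$circularity_threshold)
    for (i in seq_len(nrow(ln))) {
      # a*x + b*y = c with unit normal; direction vector is (-b, a)
      graphics::abline(
        a = if (abs(ln$b[i]) > 1e-12) ln$c[i] / ln$b[i] else NA,
        b = if (abs(ln$b[i]) > 1e-12) -ln$a[i] / ln$b[i] else NA,
        col = grDevices::adjustcolor("steelblue", 0.2)
      )
      if (abs(ln$b[i]) <= 1e-12) graphics::abline(v = ln$c[i] / ln$a[i],
                                                  col = grDevices::adjustcolor("steelblue", 0.2))
    }
  }
  graphics::points(coef(x)[["orcp_x"]], coef(x)[["orcp_y"]],
                   pch = 3, cex = 2, lwd = 2, col = "firebrick")
  invisible(x)
}
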