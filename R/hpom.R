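#' Fit a human pupil orbit model by robust minor-axis line intersection
#'
#' Estimates the ocular rotational center point (ORCP) and the pupil orbit
#' radius from a set of projected-pupil ellipses. Every elliptically deformed
#' pupil's minor axis points at the rotational center, so each ellipse
#' contributes one straight line and the center is the common intersection of
#' all lines from the same eye. Because real sets are contaminated by
#' spurious detections, the intersection is estimated inside a RANSAC loop:
#'
#' 1. Each round draws `es` distinct usable ellipses (the model estimation
#'    sample), extracts their minor-axis lines and solves the stacked line
#'    system for a candidate center by SVD pseudo-inverse
#'    ([intersect_lines()]).
#' 2. The candidate's support is the set of ellipses in the full dataset
#'    whose [angular_residual()] is at most `aae` (the allowable angle error,
#'    degrees) plus a 1e-9 degree epsilon that makes `aae = 0` meaningful in
#'    floating point.
#' 3. The candidate is refit to a fixed point: the lines of all its inliers
#'    are re-intersected and the support re-evaluated at the refit point,
#'    repeated until the consensus set is self-consistent. The refined model
#'    depends only on that set, not on the sample that discovered it.
#' 4. The refined model with the largest support (the cost) wins; ties are
#'    broken by the smaller summed residual over its inliers, then by round
#'    order. Rounds whose sampled lines are mutually parallel
#'    (rank-deficient system), or whose candidate gathers fewer than two
#'    supporters, are skipped. The orbit radius of the winning model is the
#'    mean per-inlier estimate [estimate_orbit_radius()].
#'
#' Two usable ellipses suffice in the noise-free case. Ellipses flagged
#' direction-degenerate, or with axis ratio below `circularity_threshold`,
#' are excluded from sampling and can never be inliers. The fit is
#' deterministic given `seed`.
#'
#' @param data a [pupil_ellipses] object (or a data frame with the same
#'   columns), e.g. from [sim_pupil_dataset()] or [read_pupils()].
#' @param es model estimation sample: ellipses drawn per round, at least 2.
#' @param aae allowable angle error, degrees, non-negative: the angular
#'   inlier tolerance of the consensus test.
#' @param iterations number of RANSAC rounds. The loop exits early when a
#'   candidate's support includes every usable ellipse.
#' @param seed optional integer seed; the caller's RNG stream is restored.
#' @param circularity_threshold minimum `semi_major/semi_minor` ratio for an
#'   ellipse's minor-axis direction to be usable.
#' @return An object of class `"hpom"`: a list with elements
#'   \describe{
#'     \item{coefficients}{named vector `orcp_x`, `orcp_y`, `radius` (pixels).}
#'     \item{cost}{number of ellipses forming the final model (inlier count
#'       at the refined center).}
#'     \item{inliers}{integer indices (rows of `data`) of the final consensus
#'       set.}
#'     \item{residuals}{angular residual (degrees) of every ellipse at the
#'       final center; `NA` for degenerate ellipses.}
#'     \item{pupil_radius}{mean semi-major axis over the inliers — the
#'       implied physical pupil radius under orthographic projection.}
#'     \item{data, es, aae, iterations, iterations_used, seed,
#'       circularity_threshold, call}{inputs and bookkeeping.}
#'   }
#' @examples
#' d <- sim_pupil_dataset(seed = 7)
#' fit <- hpom(d, es = 7, aae = 0, seed = 42)
#' coef(fit)
#' @export
hpom <- function(data, es = 7, aae = 0, iterations = 1000, seed = NULL,
                 circularity_threshold = 1.001) {
  cl <- match.call()
  data <- as_pupil_ellipses(data)
  if (es < 2) stop("es must be at least 2 (two lines determine a point)")
  if (aae < 0) stop("aae must be non-negative")
  if (iterations < 1) stop("iterations must be at least 1")

  ratio <- ifelse(data$semi_minor > 0, data$semi_major / data$semi_minor, Inf)
  usable <- !data$degenerate & !is.na(data$minor_axis_angle) &
    ratio >= circularity_threshold
  idx_usable <- which(usable)
  n_usable <- length(idx_usable)
  if (n_usable < es) {
    stop("es (", es, ") exceeds the number of usable ellipses (", n_usable, ")")
  }

  # precomputed line coefficients and residual ingredients
  th <- deg2rad(data$minor_axis_angle)
  sth <- sin(th)
  cth <- cos(th)
  la <- sth
  lb <- -cth
  flip <- !is.na(la) & (la < 0 | (la == 0 & lb < 0))
  la[flip] <- -la[flip]
  lb[flip] <- -lb[flip]
  lc <- la * data$cx + lb * data$cy
  cx <- data$cx
  cy <- data$cy
  eps <- 1e-9
  to_deg <- 180 / pi

  # unsigned angle (degrees, [0, 90]) between each minor-axis direction and
  # the direction from the ellipse center to p; Inf for unusable ellipses
  resid_at <- function(p) {
    dx <- p[1] - cx
    dy <- p[2] - cy
    d <- atan2(abs(dx * sth - dy * cth), abs(dx * cth + dy * sth)) * to_deg
    d[dx * dx + dy * dy < 1e-18] <- 0
    d[!usable] <- Inf
    d
  }

  # closed-form least-squares intersection of the lines selected by `sel`
  # (singular values of the 2-column system computed exactly; rank cutoff as
  # in intersect_lines); NULL when the selected lines are mutually parallel
  lsq_point <- function(sel) {
    a <- la[sel]; b <- lb[sel]; cc <- lc[sel]
    g11 <- sum(a * a); g12 <- sum(a * b); g22 <- sum(b * b)
    disc <- sqrt((g11 - g22)^2 + 4 * g12 * g12)
    if ((g11 + g22 - disc) <= (g11 + g22 + disc) * 1e-24) return(NULL)
    r1 <- sum(a * cc); r2 <- sum(b * cc)
    det <- g11 * g22 - g12 * g12
    c((g22 * r1 - g12 * r2) / det, (g11 * r2 - g12 * r1) / det)
  }

  best_cnt <- -1L
  best_ssr <- Inf
  best_inl <- NULL
  best_pt <- NULL
  it_used <- 0L

  with_seed(seed, {
    for (it in seq_len(iterations)) {
      it_used <- it
      pick <- idx_usable[sample.int(n_usable, es)]
      pt0 <- lsq_point(pick)
      if (is.null(pt0)) next # all sampled lines parallel: round skipped
      inl <- resid_at(pt0) <= aae + eps
      if (sum(inl) < 2L) next # no consensus around this candidate
      # the model a candidate proposes is the fixed point of refitting: re-
      # intersect the lines of its inliers and re-evaluate support at the
      # refit point, repeating until the consensus set is self-consistent, so
      # candidates are compared by the model they would finally report
      pt <- pt0
      r <- NULL
      for (k in 1:25) {
        pt_new <- lsq_point(inl)
        if (is.null(pt_new)) break # consensus lines parallel: keep last point
        pt <- pt_new
        r <- resid_at(pt)
        inl_new <- r <= aae + eps
        if (identical(inl_new, inl)) break
        inl <- inl_new
        if (sum(inl) < 2L) break
      }
      if (is.null(r)) r <- resid_at(pt)
      inl <- r <= aae + eps
      cnt <- sum(inl)
      if (cnt < 2L) next
      ssr <- sum(r[inl])
      if (cnt > best_cnt || (cnt == best_cnt && ssr < best_ssr)) {
        best_cnt <- cnt; best_ssr <- ssr
        best_inl <- inl; best_pt <- pt
      }
      if (best_cnt == n_usable) break # every usable ellipse already supports it
    }
  })

  if (best_cnt < 2L) {
    stop("estimation failed: no candidate reached a consensus of at least ",
         "two ellipses (aae = ", aae, ")")
  }

  cost <- best_cnt
  inliers <- which(best_inl)
  radius <- estimate_orbit_radius(data[inliers, , drop = FALSE], best_pt)

  res <- resid_at(best_pt)
  res[!usable] <- NA_real_

  structure(list(
    coefficients = c(orcp_x = unname(best_pt[1]), orcp_y = unname(best_pt[2]),
                     radius = radius),
    cost = cost,
    inliers = inliers,
    residuals = res,
    pupil_radius = mean(data$semi_major[inliers]),
    data = data,
    es = es, aae = aae, iterations = iterations, iterations_used = it_used,
    seed = seed, circularity_threshold = circularity_threshold,
    call = cl
  ), class = "hpom")
}

#' Count the inliers of a candidate rotational center
#'
#' The consensus step of the RANSAC loop, exposed directly: which ellipses'
#' minor-axis lines pass within `aae` degrees (plus a 1e-9 degree epsilon) of
#' `point`. Direction-degenerate ellipses never count.
#'
#' @inheritParams hpom
#' @param point numeric `c(x, y)`, candidate center.
#' @return A list with elements `count` and `indices`.
#' @export
count_inliers <- function(data, point, aae, circularity_threshold = 1.001) {
  data <- as_pupil_ellipses(data)
  stopifnot(aae >= 0)
  if (nrow(data) == 0) return(list(count = 0L, indices = integer(0)))
  ratio <- ifelse(data$semi_minor > 0, data$semi_major / data$semi_minor, Inf)
  usable <- !data$degenerate & ratio >= circularity_threshold
  r <- angular_residual(data, point)
  inl <- usable & !is.na(r) & r <= aae + 1e-9
  list(count = sum(inl), indices = which(inl))
}
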