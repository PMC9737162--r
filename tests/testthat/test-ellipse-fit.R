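test_that("exact contours are interpolated by the fitted conic", {
  e <- pupil_ellipses(120, 80, 45, 20, 30)
  pts <- ellipse_contour_points(e, 64, noise_sd = 0)
  conic <- fit_conic(pts)
  expect_true(all(abs(pupilorbit:::conic_residual(conic, pts)) < 1e-9))
  expect_lt(conic[2]^2 - 4 * conic[1] * conic[3], 0)
  expect_equal(sum(conic^2), 1)
})

test_that("fit recovers simulator parameters on noise-free contours", {
  # parameterized round trip across positions, eccentricities and angles,
  # including the vertical-line and horizontal-line directions
  cases <- expand.grid(
    cx = c(-30, 250), cy = c(10, 400),
    a = c(50, 12), ratio = c(0.3, 0.85),
    ang = c(0, 30, 90, 120, 179.5)
  )
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    e <- pupil_ellipses(cs$cx, cs$cy, cs$a, cs$a * cs$ratio, cs$ang)
    fit <- fit_pupil_ellipse(ellipse_contour_points(e, 64, noise_sd = 0))
    expect_equal(fit$cx, cs$cx, tolerance = 1e-6)
    expect_equal(fit$cy, cs$cy, tolerance = 1e-6)
    expect_equal(fit$semi_major, cs$a, tolerance = 1e-6)
    expect_equal(fit$semi_minor, cs$a * cs$ratio, tolerance = 1e-6)
    dang <- abs((fit$minor_axis_angle - cs$ang) %% 180)
    expect_lt(min(dang, 180 - dang), 1e-6)
  }
})

test_that("recovered minor-axis angle of an ideal projection equals the generating RDA", {
  m <- bench_model()
  for (rda in c(12, 90, 201.5, 359)) {
    e <- project_pupil(m, rae = 40, rda = rda)
    fit <- fit_pupil_ellipse(ellipse_contour_points(e, 64, noise_sd = 0))
    dang <- abs((fit$minor_axis_angle - rda) %% 180)
    expect_lt(min(dang, 180 - dang), 1e-6)
  }
})

test_that("degenerate point sets are refused", {
  xs <- 1:5
  expect_error(fit_conic(cbind(xs, 2 * xs + 1)), "no ellipse fit|collinear")
  expect_error(fit_conic(cbind(1:4, c(2, 1, 5, 3))), "at least 5")
  expect_error(fit_conic(matrix(1, 6, 2)), "distinct|degenerate")
})

test_that("axis ordering is enforced and circles flagged direction-degenerate", {
  # conic of the circle (x-100)^2 + (y-100)^2 = 50^2
  co <- c(1, 0, 1, -200, -200, 100^2 + 100^2 - 2500)
  e <- conic_to_ellipse(co)
  expect_equal(e$cx, 100)
  expect_equal(e$cy, 100)
  expect_equal(e$semi_major, 50)
  expect_equal(e$semi_minor, 50)
  expect_true(e$degenerate)

  # global sign flip describes the same conic
  e2 <- conic_to_ellipse(-co)
  expect_equal(e2$semi_major, 50)

  expect_error(conic_to_ellipse(c(1, 0, -1, 0, 0, -1)), "not an ellipse")

  f <- fit_pupil_ellipse(ellipse_contour_points(pupil_ellipses(0, 0, 30, 18, 150), 32))
  expect_gte(f$semi_major, f$semi_minor)
})

test_that("noisy fits are no worse than a grid-search oracle around the truth", {
  e <- pupil_ellipses(100, 100, 50, 30, 40)
  pts <- ellipse_contour_points(e, 64, noise_sd = 0.5, seed = 31)
  conic <- fit_conic(pts)
  fit_ss <- sum(pupilorbit:::conic_residual(conic, pts)^2)

  # brute-force search over ellipse parameters near the truth, each candidate
  # scored by the same normalized algebraic residual
  grid <- expand.grid(cx = 100 + (-2:2) * 0.5, cy = 100 + (-2:2) * 0.5,
                      a = 50 + (-2:2) * 0.5, b = 30 + (-2:2) * 0.5,
                      ang = 40 + (-2:2))
  best_ss <- Inf
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    th <- g$ang * pi / 180
    # conic of the candidate ellipse: minor axis along th, major along th+90
    R <- matrix(c(cos(th + pi / 2), sin(th + pi / 2),
                  -sin(th + pi / 2), cos(th + pi / 2)), 2, 2)
    Q <- R %*% diag(c(1 / g$a^2, 1 / g$b^2)) %*% t(R)
    A <- Q[1, 1]; B <- 2 * Q[1, 2]; C <- Q[2, 2]
    D <- -2 * A * g$cx - B * g$cy
    E <- -B * g$cx - 2 * C * g$cy
    F <- A * g$cx^2 + B * g$cx * g$cy + C * g$cy^2 - 1
    co <- c(A, B, C, D, E, F)
    co <- co / sqrt(sum(co^2))
    best_ss <- min(best_ss, sum(pupilorbit:::conic_residual(co, pts)^2))
  }
  expect_lte(fit_ss, best_ss + 1e-12)
})
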