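test_that("orthographic projection matches closed-form trigonometry", {
  m <- bench_model()

  # full foreshortening at RAE = 90: a segment pointing along the RDA
  e <- project_pupil(m, rae = 90, rda = 0)
  expect_equal(e$cx, 500)
  expect_equal(e$cy, 250)
  expect_equal(e$semi_major, 50)
  expect_equal(e$semi_minor, 0, tolerance = 1e-12)
  expect_equal(e$minor_axis_angle, 0)

  # sin 30 = 1/2, cos 30 = sqrt(3)/2
  e <- project_pupil(m, rae = 30, rda = 90)
  expect_equal(e$cx, 250)
  expect_equal(e$cy, 375)
  expect_equal(e$semi_major, 50)
  expect_equal(e$semi_minor, 50 * sqrt(3) / 2)
  expect_equal(e$minor_axis_angle, 90)

  # RAE = 0 projects a circle at the center with no minor-axis direction
  e <- project_pupil(m, rae = 0, rda = 123)
  expect_true(e$degenerate)
  expect_equal(e$cx, 250)
  expect_equal(e$cy, 250)
  expect_equal(e$semi_major, e$semi_minor)
  expect_true(is.na(e$minor_axis_angle))

  expect_error(project_pupil(m, rae = 91, rda = 0), "rae")
  expect_error(project_pupil(m, rae = 30, rda = 360), "rda")
})

test_that("every ideal ellipse's minor-axis line passes through the ORCP and traces the sine wave", {
  for (seed in c(3, 17, 91)) {
    m <- bench_model()
    d <- sim_ideal_pupils(m, n = 50, seed = seed)
    ln <- minor_axis_line(d)
    for (i in seq_len(nrow(ln))) {
      expect_lt(abs(ln$a[i] * 250 + ln$b[i] * 250 - ln$c[i]), 1e-9)
    }
    # distance(center, ORCP) / R = sin(arccos(b / a))
    dist <- sqrt((d$cx - 250)^2 + (d$cy - 250)^2)
    expect_equal(dist / 250, sin(acos(d$semi_minor / d$semi_major)),
                 tolerance = 1e-9)
  }
})

test_that("ideal generation respects its sampling contract", {
  m <- bench_model()
  expect_error(sim_ideal_pupils(m, 10, rae_range = c(0, 85)), "degenerate")
  expect_equal(nrow(sim_ideal_pupils(m, 1, seed = 4)), 1L)

  d1 <- sim_ideal_pupils(m, 100, seed = 11)
  d2 <- sim_ideal_pupils(m, 100, seed = 11)
  expect_identical(d1, d2)

  # RAE implied by the foreshortening stays inside the sampling range
  rae <- acos(d1$semi_minor / d1$semi_major) * 180 / pi
  expect_true(all(rae >= 5 - 1e-9 & rae <= 85 + 1e-9))
})

test_that("noise generation produces valid, reproducible, adversarial ellipses", {
  d <- sim_noise_pupils(100, seed = 5)
  expect_equal(nrow(d), 100L)
  expect_true(all(d$semi_major >= d$semi_minor))
  expect_true(all(d$semi_minor >= 5 & d$semi_major <= 60))
  expect_true(all(d$cx >= 0 & d$cx <= 500 & d$cy >= 0 & d$cy <= 500))
  expect_true(all(d$minor_axis_angle >= 0 & d$minor_axis_angle < 180))
  expect_identical(d, sim_noise_pupils(100, seed = 5))
  expect_equal(nrow(sim_noise_pupils(0)), 0L)

  # fraction of noise lines passing within 5 degrees of the space center,
  # checked against an independent brute-force recount
  res <- angular_residual(d, c(250, 250))
  brute <- vapply(seq_len(nrow(d)), function(i) {
    dirang <- atan2(250 - d$cy[i], 250 - d$cx[i]) * 180 / pi
    delta <- abs((dirang - d$minor_axis_angle[i]) %% 180)
    min(delta, 180 - delta) <= 5
  }, logical(1))
  expect_identical(which(res <= 5), which(brute))
})

test_that("combined dataset generation is deterministic and correctly labelled", {
  d1 <- bench_dataset(seed = 21)
  d2 <- bench_dataset(seed = 21)
  expect_identical(d1, d2)
  expect_equal(as.vector(table(d1$label)), c(100L, 100L))
  expect_false(identical(d1, bench_dataset(seed = 22)))
})

test_that("contour sampling honours its geometry and degrees of freedom", {
  circ <- pupil_ellipses(10, -4, 50, 50, NA, degenerate = TRUE)
  pts <- ellipse_contour_points(circ, 32, noise_sd = 0)
  expect_equal(sqrt((pts[, 1] - 10)^2 + (pts[, 2] + 4)^2), rep(50, 32))

  expect_error(ellipse_contour_points(circ, 4), "at least 5")

  e <- pupil_ellipses(0, 0, 40, 20, 60)
  expect_identical(ellipse_contour_points(e, 16, 0.5, seed = 9),
                   ellipse_contour_points(e, 16, 0.5, seed = 9))
})
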