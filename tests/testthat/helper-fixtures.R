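# Shared fixtures: the standard benchmark geometry is a 500 x 500 px space
# with the true rotational center at its middle, orbit radius 250 px and
# pupil radius 50 px.

bench_model <- function() hpom_model(250, 250, 250, 50)

bench_dataset <- function(seed = 1, ...) {
  sim_pupil_dataset(model = bench_model(), seed = seed, ...)
}

# independent line construction used as an oracle: normal-form coefficients
# of the line through (x0, y0) at `ang` degrees, unnormalized sign
oracle_line <- function(x0, y0, ang) {
  a <- sin(ang * pi / 180)
  b <- -cos(ang * pi / 180)
  c(a = a, b = b, c = a * x0 + b * y0)
}

# perpendicular distance from point p to line (a, b, c) with unit normal
line_point_dist <- function(ln, p) {
  abs(ln["a"] * p[1] + ln["b"] * p[2] - ln["c"]) /
    sqrt(ln["a"]^2 + ln["b"]^2)
}
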