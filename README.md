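# pupilorbit

Estimation of the eye's ocular rotational center point (ORCP) and pupil
orbit radius from elliptically projected pupil contours, for eye-gaze
tracking pipelines and for simulation studies of such estimators.

## The idea

A camera viewing a rotating eye sees the circular pupil as an ellipse. Under
orthographic projection the geometry is tightly constrained: if the gaze
deviates from the camera axis by the rotation angle α in image-plane
direction φ, the projected ellipse has center `ORCP + R sin α (cos φ, sin φ)`,
axes `a = r` and `b = r cos α`, and its **minor axis points along φ — straight
at the rotational center**. Every observed ellipse therefore contributes one
line,

```
sin θ · x − cos θ · y = sin θ · x_c − cos θ · y_c ,
```

(θ the minor-axis angle, `(x_c, y_c)` the ellipse center), and the ORCP is
the common intersection of all such lines, solved as an overdetermined linear
system by SVD pseudo-inverse. Spurious detections are handled by RANSAC: each
round draws a small estimation sample (ES) of ellipses, proposes the
intersection of their lines, and scores it by its consensus — the number of
ellipses whose minor-axis direction points at the candidate to within the
allowable angle error (AAE, degrees). Candidates are refit on their consensus
set to a fixed point before comparison, which makes repeated runs converge to
the identical model. The orbit radius follows from the sine-wave relation
`d = R sin α` with `cos α = b/a`, averaged over inliers.

The package provides the estimator (`hpom()`, returning a classed fit with
`print`/`summary`/`coef`/`residuals`/`predict`/`simulate`/`plot` methods), an
orthographic pupil-projection simulator (`sim_pupil_dataset()`), a direct
least-squares ellipse fit from raw contours (`fit_pupil_ellipse()`), and a
repeated-trial harness (`hpom_trials()`, `hpom_es_sweep()`,
`hpom_aae_sweep()`). A thin command-line front end lives in
`inst/cli/pupilorbit.R`.

## Worked example

The benchmark setting: 100 ideal projected pupils from a ground truth with
the ORCP at the center of a 500 × 500 px space (orbit radius 250 px, pupil
radius 50 px) plus 100 random noise ellipses.

```r
library(pupilorbit)
d <- sim_pupil_dataset(seed = 1)
fit <- hpom(d, es = 7, aae = 0, iterations = 1000, seed = 42)
summary(fit)
#> Pupil orbit model fit
#> Call: hpom(data = d, es = 7, aae = 0, iterations = 1000, seed = 42)
#>
#> orcp_x orcp_y radius
#>    250    250    250
#>
#> Consensus set: 100 / 200 ellipses (ES = 7, AAE = 0 deg, 1000 rounds)
#>   by label: ideal = 100
#> Implied pupil radius: 50 px
#> Angular residuals (deg):
#>       0%      25%      50%      75%     100%
#> 0.00e+00 1.74e-14 9.20e-01 4.37e+01 8.89e+01
```

With zero tolerance only the hundred ideal ellipses can agree on a point,
and they agree exactly: the fit recovers the true center (250, 250) and
radius 250 with all 100 ideal ellipses — and none of the noise — in the
consensus set. Widening the tolerance trades accuracy for support:

```r
hpom(d, es = 7, aae = 5, iterations = 1000, seed = 42)
#>   ORCP:   (249.9, 250.3) px
#>   Radius: 255.1 px
#>   Cost:   105 of 200 ellipses in the consensus set (ES = 7, AAE = 5 deg)
```

Five noise ellipses whose lines shave past the center are now admitted,
dragging the estimate slightly off. Repeating the fit 200 times
(`hpom_trials(d, es = 7, aae = 0, repeats = 200)`) gives standard deviations
of exactly 0 across repeats for every ES up to 7 — the estimator's precision
at these settings is perfect even though its accuracy degrades with the AAE.

See the methods vignette (`vignettes/pupil-orbit-model.Rmd`) for the model,
the tuning parameters, and what the simulation does and does not demonstrate.

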