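#' Repeated-trial evaluation of the orbit-model estimator
#'
#' Runs [hpom()] `repeats` times on the same dataset with per-repeat seeds
#' derived from `base_seed`, and aggregates the estimates into the accuracy /
#' precision summary used by the simulation experiments: average and standard
#' deviation of the estimated center coordinates, of the orbit radius, the
#' average cost, and processing time. `distance_sd` is the standard deviation
#' of each repeat's Euclidean distance from the mean estimated center — a
#' precision measure. When `true_orcp` is supplied, the mean distance of the
#' estimates from the true center (`distance_true_avg`, an accuracy measure)
#' is reported as well.
#'
#' Repeats in which the estimator fails (no consensus set of at least two
#' ellipses) are recorded in `n_failures` and excluded from the aggregates.
#'
#' @inheritParams hpom
#' @param repeats number of repeated fits.
#' @param base_seed integer; per-repeat seeds are derived from it, so the
#'   whole experiment is reproducible.
#' @param true_orcp optional numeric `c(x, y)` ground truth.
#' @return An object of class `"hpom_trials"`: list with `summary` (one-row
#'   data frame) and `raw` (per-repeat records).
#' @examples
#' d <- sim_pupil_dataset(seed = 1)
#' tr <- hpom_trials(d, es = 7, aae = 0, repeats = 5, base_seed = 99)
#' tr$summary
#' @export
hpom_trials <- function(data, es = 7, aae = 0, repeats = 200,
                        iterations = 1000, base_seed = 1,
                        circularity_threshold = 1.001, true_orcp = NULL) {
  stopifnot(repeats >= 1)
  data <- as_pupil_ellipses(data)
  seeds <- derive_seeds(base_seed, repeats)
  raw <- data.frame(
    repeat_id = seq_len(repeats), seed = seeds,
    orcp_x = NA_real_, orcp_y = NA_real_, radius = NA_real_,
    cost = NA_integer_, time_ms = NA_real_, failed = FALSE
  )
  for (i in seq_len(repeats)) {
    t0 <- proc.time()[["elapsed"]]
    fit <- tryCatch(
      hpom(data, es = es, aae = aae, iterations = iterations,
           seed = seeds[i], circularity_threshold = circularity_threshold),
      error = function(e) NULL
    )
    raw$time_ms[i] <- (proc.time()[["elapsed"]] - t0) * 1000
    if (is.null(fit)) {
      raw$failed[i] <- TRUE
    } else {
      co <- coef(fit)
      raw$orcp_x[i] <- co[["orcp_x"]]
      raw$orcp_y[i] <- co[["orcp_y"]]
      raw$radius[i] <- co[["radius"]]
      raw$cost[i] <- fit$cost
    }
  }
  ok <- !raw$failed
  sd0 <- function(v) if (sum(!is.na(v)) < 2) 0 else stats::sd(v, na.rm = TRUE)
  mx <- mean(raw$orcp_x[ok]); my <- mean(raw$orcp_y[ok])
  dist_from_mean <- sqrt((raw$orcp_x[ok] - mx)^2 + (raw$orcp_y[ok] - my)^2)
  summ <- data.frame(
    es = es, aae = aae, n_repeats = repeats, n_failures = sum(!ok),
    orcp_x_avg = mx, orcp_x_sd = sd0(raw$orcp_x[ok]),
    orcp_y_avg = my, orcp_y_sd = sd0(raw$orcp_y[ok]),
    distance_sd = sd0(dist_from_mean),
    radius_avg = mean(raw$radius[ok]), radius_sd = sd0(raw$radius[ok]),
    cost_avg = mean(raw$cost[ok]),
    time_avg_ms = mean(raw$time_ms), time_sd_ms = sd0(raw$time_ms)
  )
  if (!is.null(true_orcp)) {
    summ$distance_true_avg <- mean(sqrt((raw$orcp_x[ok] - true_orcp[1])^2 +
                                          (raw$orcp_y[ok] - true_orcp[2])^2))
  }
  structure(list(summary = summ, raw = raw), class = "hpom_trials")
}

#' @export
print.hpom_trials <- function(x, ...) {
  cat(sprintf("Repeated orbit-model trials: %d repeats (ES = %d, AAE = %g deg, %d failures)\n",
              x$summary$n_repeats, x$summary$es, x$summary$aae,
              x$summary$n_failures))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

sweep_over <- function(data, grid, varying, fixed, repeats, iterations,
                       base_seed, circularity_threshold, true_orcp) {
  seeds <- derive_seeds(base_seed, length(grid))
  rows <- vector("list", length(grid))
  raws <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    args <- c(list(data = data, repeats = repeats, iterations = iterations,
                   base_seed = seeds[i],
                   circularity_threshold = circularity_threshold,
                   true_orcp = true_orcp),
              stats::setNames(list(grid[i]), varying), fixed)
    tr <- do.call(hpom_trials, args)
    rows[[i]] <- tr$summary
    raws[[i]] <- cbind(tr$raw,
                       stats::setNames(data.frame(grid[i]), varying),
                       row.names = NULL)
  }
  structure(list(summary = do.call(rbind, rows), raw = do.call(rbind, raws)),
            class = "hpom_sweep")
}

#' Sweep experiments over the estimation sample size or the angle tolerance
#'
#' `hpom_es_sweep()` fixes the allowable angle error and varies the number of
#' ellipses drawn per RANSAC round; `hpom_aae_sweep()` fixes the sample size
#' and varies the angle tolerance. Each grid point is evaluated with
#' [hpom_trials()] (200 repeats by default) and summarized as one row.
#'
#' @inheritParams hpom_trials
#' @param es_grid,aae_grid grid of values to sweep.
#' @param es,aae the fixed parameter of each sweep.
#' @return An object of class `"hpom_sweep"`: list with `summary` (one row
#'   per grid value) and `raw` (all per-repeat records).
#' @examples
#' d <- sim_pupil_dataset(seed = 1)
#' sw <- hpom_aae_sweep(d, aae_grid = c(0, 5), repeats = 3, base_seed = 2)
#' sw$summary
#' @export
hpom_es_sweep <- function(data, es_grid = c(2, 3, 4, 5, 7, 10, 14), aae = 5,
                          repeats = 200, iterations = 1000, base_seed = 1,
                          circularity_threshold = 1.001, true_orcp = NULL) {
  sweep_over(data, es_grid, "es", list(aae = aae), repeats, iterations,
             base_seed, circularity_threshold, true_orcp)
}

#' @rdname hpom_es_sweep
#' @export
hpom_aae_sweep <- function(data, aae_grid = 0:5, es = 7,
                           repeats = 200, iterations = 1000, base_seed = 1,
                           circularity_threshold = 1.001, true_orcp = NULL) {
  sweep_over(data, aae_grid, "aae", list(es = es), repeats, iterations,
             base_seed, circularity_threshold, true_orcp)
}

#' @export
print.hpom_sweep <- function(x, ...) {
  cat(sprintf("Orbit-model sweep: %d configurations x %d repeats\n",
              nrow(x$summary), x$summary$n_repeats[1]))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write a sweep's outputs to a directory
#'
#' Writes `summary.csv` (one row per configuration), `raw.csv` (per-repeat
#' records) and `config.json` (an echo of the sweep arguments, if supplied).
#'
#' @param x an `"hpom_sweep"` or `"hpom_trials"` object.
#' @param dir output directory, created if needed.
#' @param config optional named list echoed to `config.json`.
#' @return `dir`, invisibly.
#' @export
write_sweep <- function(x, dir, config = NULL) {
  stopifnot(inherits(x, c("hpom_sweep", "hpom_trials")))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(x$summary, file.path(dir, "summary.csv"), row.names = FALSE)
  utils::write.csv(x$raw, file.path(dir, "raw.csv"), row.names = FALSE)
  if (!is.null(config)) {
    jsonlite::write_json(config, file.path(dir, "config.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(dir)
}
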