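#' Monte Carlo simulation settings for run-length estimation
#'
#' @param m,n phase-I and phase-II sample sizes.
#' @param dist process family: standard normal, Student t with 5
#'   degrees of freedom, or gamma with shape 3 and scale 1.
#' @param delta location shift of the test subgroups in units of the
#'   family's population standard deviation; `0` is in control.
#' @param replications number of independent zero-state runs.
#' @param max_run_length cap on a single run; runs reaching the cap are
#'   counted at the cap and flagged as censored.
#' @param seed optional integer seed; the whole study is reproducible
#'   from it.
#' @return An object of class `"rl_config"`.
#' @export
rl_config <- function(m, n, dist = c("normal", "t5", "gamma31"),
                      delta = 0, replications = 10000,
                      max_run_length = 100000, seed = NULL) {
  dist <- match.arg(dist)
  stopifnot(m >= 2, n >= 1, replications >= 1, max_run_length >= 1,
            is.finite(delta))
  structure(
    list(m = as.integer(m), n = as.integer(n), dist = dist,
         delta = as.numeric(delta),
         replications = as.integer(replications),
         max_run_length = as.integer(max_run_length),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "rl_config"
  )
}

dist_code <- function(dist) {
  switch(dist, normal = 0L, t5 = 1L, gamma31 = 2L)
}

#' Simulate a single zero-state run length
#'
#' Draws one fresh in-control reference sample, then streams shifted
#' test subgroups, computing the rank-sum statistic against that same
#' fixed reference and updating the chart from its zero state, until
#' the first signal (or the run-length cap).
#'
#' @param spec a [chart_spec()].
#' @param config an [rl_config()]; its `replications` field is ignored.
#' @return A single integer run length with attribute `"censored"`.
#' @export
simulate_one_run <- function(spec, config) {
  res <- run_engine(spec, config, reps = 1L)
  structure(res$rl[1L], censored = res$censored[1L])
}

run_engine <- function(spec, config, reps = config$replications) {
  stopifnot(inherits(spec, "chart_spec"), inherits(config, "rl_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  k <- if (spec$scheme == "cusum") {
    sw <- w_moments(config$m, config$n)$sigma_w
    if (is.null(spec$k)) 0.5 * sw else spec$k
  } else 0
  simulate_run_lengths_cpp(
    scheme_code(spec),
    if (is.na(spec$l_outer)) 0 else spec$l_outer,
    if (is.na(spec$l_inner)) 0 else spec$l_inner,
    spec$L, k, config$m, config$n, dist_code(config$dist),
    config$delta, process_sigma(config$dist),
    as.integer(reps), config$max_run_length
  )
}

#' Zero-state run-length distribution of a chart
#'
#' Replicates [simulate_one_run()] and summarises the run-length
#' distribution: average run length (ARL), its standard deviation
#' (SDRL), Monte Carlo standard error of the ARL, and the 5th, 25th,
#' 50th, 75th and 95th percentiles. Censored runs (those reaching the
#' cap) are counted at the cap value, reported in `n_censored`, and
#' trigger a warning when they exceed 1% of the replications.
#'
#' @param spec a [chart_spec()].
#' @param config an [rl_config()].
#' @return An object of class `"run_length_summary"`; the raw (capped)
#'   run lengths are kept in its `run_lengths` field.
#' @examples
#' \donttest{
#' spec <- chart_spec("hwma", lambda = 0.05, L = 2.9567)
#' cfg <- rl_config(100, 5, "normal", delta = 0, replications = 1000,
#'                  seed = 1)
#' estimate_run_length(spec, cfg)
#' }
#' @export
estimate_run_length <- function(spec, config) {
  res <- run_engine(spec, config)
  rl <- as.numeric(res$rl)
  n_cens <- sum(res$censored)
  if (n_cens > 0.01 * length(rl))
    warning(sprintf("%d of %d runs (%.1f%%) hit the run-length cap; ",
                    n_cens, length(rl), 100 * n_cens / length(rl)),
            "summaries are computed on the capped sample",
            call. = FALSE)
  structure(
    list(arl = mean(rl), sdrl = sd(rl),
         mc_se = sd(rl) / sqrt(length(rl)),
         percentiles = quantile(rl, c(0.05, 0.25, 0.5, 0.75, 0.95),
                                type = 1, names = TRUE),
         n_censored = n_cens, replications = length(rl),
         run_lengths = as.integer(res$rl),
         spec = spec, config = config),
    class = "run_length_summary"
  )
}

#' @export
print.run_length_summary <- function(x, ...) {
  print(x$spec)
  cat(sprintf("  %s, (m, n) = (%d, %d), delta = %g, %d replications\n",
              x$config$dist, x$config$m, x$config$n, x$config$delta,
              x$replications))
  cat(sprintf("  ARL = %.2f (MC se %.2f), SDRL = %.2f\n",
              x$arl, x$mc_se, x$sdrl))
  cat("  percentiles:",
      paste(names(x$percentiles), x$percentiles, sep = " = ",
            collapse = ", "), "\n")
  if (x$n_censored > 0)
    cat(sprintf("  %d run(s) censored at the cap of %d\n",
                x$n_censored, x$config$max_run_length))
  invisible(x)
}

#' Run-length profile over a grid of location shifts
#'
#' Estimates the run-length distribution for each shift on the
#' left-open grid `(delta_min, delta_max]` with the given step and
#' averages the per-shift ARL and SDRL into the expected ARL (EARL) and
#' expected SDRL (ESDRL) overall performance measures.
#'
#' @param spec a [chart_spec()].
#' @param config an [rl_config()]; its `delta` field is replaced by
#'   each grid value in turn.
#' @param delta_min,delta_max grid endpoints (the grid excludes
#'   `delta_min` and includes `delta_max`).
#' @param step grid increment, default 0.1.
#' @return An object of class `"shift_grid_summary"` with fields
#'   `grid`, `summaries` (per-shift [estimate_run_length()] results),
#'   `arl`, `sdrl`, `earl`, `esdrl` and `Delta` (number of grid
#'   points).
#' @export
shift_profile <- function(spec, config, delta_min, delta_max,
                          step = 0.1) {
  stopifnot(delta_min < delta_max, step > 0)
  k <- seq_len(floor((delta_max - delta_min) / step + 1e-9))
  grid <- delta_min + k * step
  if (length(grid) == 0L)
    stop("empty shift grid", call. = FALSE)
  summaries <- lapply(seq_along(grid), function(i) {
    cfg <- config
    cfg$delta <- grid[i]
    cfg$seed <- if (is.null(config$seed)) NULL else config$seed + i
    estimate_run_length(spec, cfg)
  })
  arls <- vapply(summaries, `[[`, numeric(1), "arl")
  sdrls <- vapply(summaries, `[[`, numeric(1), "sdrl")
  structure(
    list(grid = grid, summaries = summaries, arl = arls, sdrl = sdrls,
         earl = mean(arls), esdrl = mean(sdrls), Delta = length(grid),
         spec = spec),
    class = "shift_grid_summary"
  )
}

#' @export
print.shift_grid_summary <- function(x, ...) {
  print(x$spec)
  tab <- data.frame(delta = x$grid, ARL = round(x$arl, 2),
                    SDRL = round(x$sdrl, 2))
  print(tab, row.names = FALSE)
  cat(sprintf("  EARL = %.2f, ESDRL = %.2f over %d shifts\n",
              x$earl, x$esdrl, x$Delta))
  invisible(x)
}
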