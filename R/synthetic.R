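#' Population standard deviation of a process family
#'
#' Shifts throughout the package are expressed in units of the
#' family's own standard deviation: 1 for the standard normal,
#' `sqrt(5/3)` for Student t with 5 degrees of freedom, and `sqrt(3)`
#' for the gamma distribution with shape 3 and scale 1. Families are
#' used on their natural scale; because the rank-sum statistic is
#' invariant to common monotone rescaling, in-control behaviour does
#' not depend on this choice.
#'
#' @param dist `"normal"`, `"t5"` or `"gamma31"`.
#' @return The population standard deviation.
#' @export
process_sigma <- function(dist = c("normal", "t5", "gamma31")) {
  switch(match.arg(dist), normal = 1, t5 = sqrt(5 / 3),
         gamma31 = sqrt(3))
}

draw_family <- function(k, dist) {
  switch(dist,
         normal = rnorm(k),
         t5 = rt(k, df = 5),
         gamma31 = rgamma(k, shape = 3, scale = 1))
}

#' Draw an in-control phase-I reference sample
#'
#' @param m sample size (>= 2).
#' @param dist process family, see [process_sigma()].
#' @return Numeric vector of `m` i.i.d. in-control draws.
#' @export
draw_reference <- function(m, dist = c("normal", "t5", "gamma31")) {
  dist <- match.arg(dist)
  stopifnot(m >= 2)
  draw_family(m, dist)
}

#' Draw a phase-II test subgroup with a location shift
#'
#' @param n subgroup size (>= 1).
#' @param dist process family.
#' @param delta location shift in units of the family's population
#'   standard deviation; `0` gives in-control draws.
#' @return Numeric vector of `n` draws from the shifted family.
#' @export
draw_test_subgroup <- function(n, dist = c("normal", "t5", "gamma31"),
                               delta = 0) {
  dist <- match.arg(dist)
  stopifnot(n >= 1, is.finite(delta))
  draw_family(n, dist) + delta * process_sigma(dist)
}

#' Generate a synthetic monitoring data set
#'
#' Emulates the shape of an industrial silica-monitoring application: a
#' long retrospective phase-I reference series and a stream of hourly
#' phase-II subgroups from a right-skewed process, with a location
#' shift switched on at a known changepoint. The raw industrial data
#' are not redistributable, so this generator stands in for them; only
#' the dimensions and skewness are emulated.
#'
#' @param m phase-I size (default 520, i.e. 104 subgroups of 5).
#' @param n_subgroups number of phase-II subgroups (default 78).
#' @param n subgroup size (default 5).
#' @param dist process family; default the right-skewed `"gamma31"`.
#' @param delta shift (in sigma units) applied from `changepoint` on.
#' @param changepoint first shifted subgroup index; `Inf` keeps the
#'   whole stream in control.
#' @param seed optional integer seed.
#' @return A list with `phase1` (numeric vector), `phase2` (matrix,
#'   one subgroup per row) and a `manifest` list recording the
#'   generator settings.
#' @examples
#' fx <- make_illustration_fixture(seed = 1)
#' dim(fx$phase2)  # 78 x 5
#' @export
make_illustration_fixture <- function(m = 520, n_subgroups = 78, n = 5,
                                      dist = "gamma31", delta = 1,
                                      changepoint = 40, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_subgroups >= 1, changepoint >= 1)
  phase1 <- draw_reference(m, dist)
  phase2 <- t(vapply(seq_len(n_subgroups), function(t) {
    d <- if (t >= changepoint) delta else 0
    draw_test_subgroup(n, dist, d)
  }, numeric(n)))
  rownames(phase2) <- NULL
  list(phase1 = phase1, phase2 = phase2,
       manifest = list(m = m, n_subgroups = n_subgroups, n = n,
                       dist = dist, delta = delta,
                       changepoint = changepoint, seed = seed))
}

#' Write a synthetic monitoring data set to disk
#'
#' Serialises a [make_illustration_fixture()] result as a single-column
#' phase-I CSV, a wide phase-II CSV (`subgroup, obs1..obsn`) and a JSON
#' manifest recording the generator settings.
#'
#' @param fixture result of [make_illustration_fixture()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_fixture <- function(fixture, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p1 <- file.path(dir, "phase1.csv")
  p2 <- file.path(dir, "phase2.csv")
  pm <- file.path(dir, "manifest.json")
  write.csv(data.frame(value = fixture$phase1), p1, row.names = FALSE)
  ph2 <- as.data.frame(fixture$phase2)
  names(ph2) <- paste0("obs", seq_len(ncol(ph2)))
  write.csv(cbind(subgroup = seq_len(nrow(ph2)), ph2), p2,
            row.names = FALSE)
  jsonlite::write_json(fixture$manifest, pm, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(c(phase1 = p1, phase2 = p2, manifest = pm))
}
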