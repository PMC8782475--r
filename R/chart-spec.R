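#' Specify a rank-sum control chart
#'
#' Bundles the scheme family, its smoothing parameter(s) and the
#' control-limit constant `L` into a `"chart_spec"` object used by
#' [apply_chart()], [control_limits()], [estimate_run_length()] and
#' [calibrate_limit()].
#'
#' Schemes:
#' * `"hwma"`: homogeneously weighted moving average of the rank-sum
#'   statistic; weight `lambda` on the current `W`, `1 - lambda` spread
#'   over the running mean of all previous `W`.
#' * `"dhwma"`: HWMA smoothing applied twice with the same `lambda`.
#' * `"hhwma"`: double smoothing with two parameters; `lambda2` drives
#'   the inner HWMA of `W`, `lambda1` the outer smoothing. With
#'   `lambda1 == lambda2` it reduces exactly to the DHWMA chart.
#' * `"ewma"`, `"dewma"`: geometric (double) exponentially weighted
#'   competitors.
#' * `"cusum"`: two-sided tabular CUSUM of `W - mu_W` with reference
#'   value `k` (defaults to `0.5 * sigma_W` at run time) and decision
#'   interval `h = L * sigma_W`.
#'
#' @param scheme one of `"hwma"`, `"dhwma"`, `"hhwma"`, `"ewma"`,
#'   `"dewma"`, `"cusum"`.
#' @param lambda smoothing parameter in (0, 1] for the single-parameter
#'   schemes.
#' @param lambda1,lambda2 outer and inner smoothing parameters in (0, 1]
#'   (HHWMA only).
#' @param L positive control-limit constant.
#' @param k CUSUM reference value in rank-sum units, or `NULL` for the
#'   default `0.5 * sigma_W`.
#' @return An object of class `"chart_spec"`.
#' @examples
#' chart_spec("hwma", lambda = 0.5, L = 2.9069)
#' chart_spec("hhwma", lambda1 = 0.75, lambda2 = 0.5, L = 2.1171)
#' @export
chart_spec <- function(scheme = c("hwma", "dhwma", "hhwma", "ewma",
                                  "dewma", "cusum"),
                       lambda = NULL, lambda1 = NULL, lambda2 = NULL,
                       L, k = NULL) {
  scheme <- match.arg(scheme)
  chk_lambda <- function(x, name) {
    if (length(x) != 1L || !is.finite(x) || x <= 0 || x > 1)
      stop(sprintf("'%s' must be a single value in (0, 1]", name),
           call. = FALSE)
    as.numeric(x)
  }
  if (length(L) != 1L || !is.finite(L) || L <= 0)
    stop("'L' must be a single positive number", call. = FALSE)

  if (scheme == "hhwma") {
    if (is.null(lambda1) || is.null(lambda2))
      stop("the HHWMA scheme needs both 'lambda1' and 'lambda2'",
           call. = FALSE)
    l_outer <- chk_lambda(lambda1, "lambda1")
    l_inner <- chk_lambda(lambda2, "lambda2")
  } else if (scheme == "cusum") {
    if (!is.null(k) && (length(k) != 1L || !is.finite(k) || k < 0))
      stop("'k' must be a single nonnegative number", call. = FALSE)
    l_outer <- l_inner <- NA_real_
  } else {
    if (is.null(lambda))
      stop(sprintf("the %s scheme needs 'lambda'", toupper(scheme)),
           call. = FALSE)
    l_outer <- chk_lambda(lambda, "lambda")
    l_inner <- if (scheme %in% c("dhwma", "dewma")) l_outer else NA_real_
  }
  if (!is.null(lambda2) && scheme != "hhwma")
    stop("'lambda2' is only meaningful for the HHWMA scheme",
         call. = FALSE)

  structure(
    list(scheme = scheme, l_outer = l_outer, l_inner = l_inner,
         L = as.numeric(L),
         k = if (scheme == "cusum" && !is.null(k)) as.numeric(k) else NULL),
    class = "chart_spec"
  )
}

#' @export
print.chart_spec <- function(x, ...) {
  lab <- switch(x$scheme,
    hwma  = sprintf("HWMA W chart (lambda = %g, L = %g)", x$l_outer, x$L),
    dhwma = sprintf("DHWMA W chart (lambda = %g, L = %g)", x$l_outer, x$L),
    hhwma = sprintf("HHWMA W chart (lambda1 = %g, lambda2 = %g, L = %g)",
                    x$l_outer, x$l_inner, x$L),
    ewma  = sprintf("EWMA W chart (lambda = %g, L = %g)", x$l_outer, x$L),
    dewma = sprintf("DEWMA W chart (lambda = %g, L = %g)", x$l_outer, x$L),
    cusum = sprintf("CUSUM W chart (L = %g, k = %s)", x$L,
                    if (is.null(x$k)) "0.5 sigma_W" else format(x$k))
  )
  cat(lab, "\n")
  invisible(x)
}

# integer code used by the compiled engine
scheme_code <- function(spec) {
  switch(spec$scheme,
         hwma = 0L, dhwma = 1L, hhwma = 1L, ewma = 2L, dewma = 3L,
         cusum = 4L)
}
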