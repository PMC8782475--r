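#' In-control variance multipliers of the charting statistics
#'
#' The plotted statistic of each memory-type scheme is a linear
#' combination of the rank-sum statistics observed so far, so its
#' in-control variance is `factor(t) * sigma_W^2` where the factor
#' depends only on `t` and the smoothing parameter(s) (treating the
#' `W_t` as uncorrelated with common variance `sigma_W^2`).
#'
#' For the HWMA chart the factor is `lambda^2` at `t = 1` and
#' `lambda^2 + (1 - lambda)^2 / (t - 1)` afterwards. The DHWMA and
#' HHWMA factors are piecewise expressions whose `t > 2` branch
#' involves partial harmonic sums; `dhwma_variance_factor()` is the
#' `lambda1 = lambda2` specialization of the HHWMA expression.
#'
#' @param t sampling time(s), positive integer(s); vectorized.
#' @param lambda,lambda1,lambda2 smoothing parameters in (0, 1].
#' @return Numeric vector of variance multipliers, same length as `t`.
#' @seealso [coefficient_oracle()] for an independent check by symbolic
#'   propagation of the chart recursions.
#' @examples
#' hwma_variance_factor(1:3, 0.5)
#' dhwma_variance_factor(2, 0.5)          # 0.3125
#' hhwma_variance_factor(1, 0.75, 0.5)    # (0.75 * 0.5)^2
#' @export
hwma_variance_factor <- function(t, lambda) {
  check_times(t)
  check_unit(lambda, "lambda")
  variance_factors_cpp(0L, lambda, lambda, max(t))[t]
}

#' @rdname hwma_variance_factor
#' @export
dhwma_variance_factor <- function(t, lambda) {
  check_unit(lambda, "lambda")
  hhwma_variance_factor(t, lambda, lambda)
}

#' @rdname hwma_variance_factor
#' @export
hhwma_variance_factor <- function(t, lambda1, lambda2) {
  check_times(t)
  check_unit(lambda1, "lambda1")
  check_unit(lambda2, "lambda2")
  variance_factors_cpp(1L, lambda1, lambda2, max(t))[t]
}

#' Variance multiplier of any supported scheme
#'
#' Dispatches on the scheme of a [chart_spec()]; the CUSUM chart has no
#' time-varying variance factor and is rejected.
#'
#' @param spec a [chart_spec()].
#' @param t sampling time(s), positive integer(s).
#' @return Numeric vector of multipliers of `sigma_W^2`.
#' @export
chart_variance_factor <- function(spec, t) {
  stopifnot(inherits(spec, "chart_spec"))
  check_times(t)
  if (spec$scheme == "cusum")
    stop("the CUSUM chart has no time-varying variance factor",
         call. = FALSE)
  variance_factors_cpp(scheme_code(spec), spec$l_outer, spec$l_inner,
                       max(t))[t]
}

check_times <- function(t) {
  if (length(t) < 1L || !all(is.finite(t)) || any(t < 1) ||
      any(t != floor(t)))
    stop("'t' must contain positive integers", call. = FALSE)
  invisible(t)
}

check_unit <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x <= 0 || x > 1)
    stop(sprintf("'%s' must be a single value in (0, 1]", name),
         call. = FALSE)
  invisible(x)
}

#' Chart statistics as explicit linear combinations of the rank sums
#'
#' Propagates the chart recursion symbolically to express the plotted
#' statistic at time `t` as `sum(c_s * W_s) + c0 * mu_W`. Serves as an
#' independent oracle for the closed-form variance factors: treating
#' the `W_s` as uncorrelated, the variance multiplier is `sum(c_s^2)`,
#' and unbiasedness requires `sum(c_s) + c0 == 1`.
#'
#' @param spec a [chart_spec()] for any scheme except CUSUM (which is
#'   not a linear filter of the `W_s`).
#' @param t a single positive integer sampling time.
#' @return `chart_weights()`: a list with `coefficients` (`c_1..c_t`)
#'   and `constant` (`c0`). `coefficient_oracle()`: the scalar
#'   `sum(c_s^2)`.
#' @examples
#' chart_weights(chart_spec("dhwma", lambda = 0.5, L = 2), 2)
#' coefficient_oracle(chart_spec("hwma", lambda = 0.25, L = 3), 10)
#' @export
chart_weights <- function(spec, t) {
  stopifnot(inherits(spec, "chart_spec"))
  if (length(t) != 1L) stop("'t' must be a single time", call. = FALSE)
  check_times(t)
  if (spec$scheme == "cusum")
    stop("the CUSUM statistic is not a linear combination of the W_s",
         call. = FALSE)

  # each statistic is held as c(coef over W_1..W_t, constant-in-mu_W)
  lin <- function(coef, const) list(coef = coef, const = const)
  pad <- function(x, len) c(x, rep(0, len - length(x)))

  if (spec$scheme == "hwma") {
    l <- spec$l_outer
    if (t == 1) return(list(coefficients = l, constant = 1 - l))
    return(list(coefficients = c(rep((1 - l) / (t - 1), t - 1), l),
                constant = 0))
  }

  if (spec$scheme %in% c("dhwma", "hhwma")) {
    l1 <- spec$l_outer
    l2 <- spec$l_inner
    hlist <- vector("list", t)
    for (s in seq_len(t)) {
      hlist[[s]] <- if (s == 1) lin(l2, 1 - l2)
      else lin(c(rep((1 - l2) / (s - 1), s - 1), l2), 0)
    }
    if (t == 1) {
      out_coef <- l1 * hlist[[1]]$coef
      out_const <- l1 * hlist[[1]]$const + (1 - l1)
    } else {
      hbar_coef <- rep(0, t)
      hbar_const <- 0
      for (s in seq_len(t - 1)) {
        hbar_coef <- hbar_coef + pad(hlist[[s]]$coef, t) / (t - 1)
        hbar_const <- hbar_const + hlist[[s]]$const / (t - 1)
      }
      out_coef <- l1 * pad(hlist[[t]]$coef, t) + (1 - l1) * hbar_coef
      out_const <- l1 * hlist[[t]]$const + (1 - l1) * hbar_const
    }
    return(list(coefficients = out_coef, constant = out_const))
  }

  # EWMA / DEWMA by direct recursion from the zero state
  l <- spec$l_outer
  z <- lin(numeric(0), 1)
  z2 <- lin(numeric(0), 1)
  for (s in seq_len(t)) {
    z <- lin(c((1 - l) * z$coef, l), (1 - l) * z$const)
    if (spec$scheme == "dewma")
      z2 <- lin(l * z$coef + (1 - l) * pad(z2$coef, s),
                l * z$const + (1 - l) * z2$const)
  }
  out <- if (spec$scheme == "dewma") z2 else z
  list(coefficients = out$coef, constant = out$const)
}

#' @rdname chart_weights
#' @export
coefficient_oracle <- function(spec, t) {
  sum(chart_weights(spec, t)$coefficients^2)
}
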