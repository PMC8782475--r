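#' Time-varying control limits of a rank-sum chart
#'
#' Limits are symmetric about the in-control mean `mu_W`:
#' `mu_W +/- L * sigma_W * sqrt(factor(t))` where the factor is the
#' scheme's in-control variance multiplier (see
#' [hwma_variance_factor()]). No truncation is applied at the attainable
#' range of the statistic. The CUSUM chart instead uses a constant
#' decision interval `h = L * sigma_W` and is rejected here.
#'
#' @param spec a [chart_spec()] (any scheme except CUSUM).
#' @param moments a [w_moments()] object.
#' @param t sampling time(s), positive integer(s); vectorized.
#' @return A data frame with columns `t`, `center`, `lcl`, `ucl`.
#' @examples
#' control_limits(chart_spec("hwma", lambda = 0.5, L = 2.9069),
#'                w_moments(520, 5), t = 1:2)
#' @export
control_limits <- function(spec, moments, t) {
  stopifnot(inherits(spec, "chart_spec"), inherits(moments, "w_moments"))
  half <- spec$L * moments$sigma_w * sqrt(chart_variance_factor(spec, t))
  data.frame(t = as.integer(t), center = moments$mu_w,
             lcl = moments$mu_w - half, ucl = moments$mu_w + half)
}

#' Out-of-control signal rule
#'
#' A chart signals when the plotted statistic falls strictly beyond a
#' control limit; a statistic exactly on a limit is in control.
#'
#' @param statistic numeric vector of plotted values.
#' @param lcl,ucl lower and upper limits (recycled against `statistic`).
#' @return Logical vector.
#' @export
signal <- function(statistic, lcl, ucl) {
  statistic > ucl | statistic < lcl
}

#' Run a chart over a sequence of rank-sum statistics
#'
#' Applies the scheme in `spec` to the ordered sequence of rank-sum
#' statistics `w` (one per subgroup), starting from the zero state: all
#' running means and EWMA levels at `mu_W`, CUSUM arms at zero.
#'
#' @param w numeric vector of rank-sum statistics `W_1, W_2, ...`.
#' @param spec a [chart_spec()].
#' @param moments a [w_moments()] object.
#' @return A data frame with one row per subgroup: `t`, `w`,
#'   `statistic`, `lcl`, `ucl`, `signal`. For the CUSUM chart the
#'   columns are `t`, `w`, `cusum_pos`, `cusum_neg`, `h`, `signal`.
#' @examples
#' mom <- w_moments(520, 5)
#' apply_chart(1800, chart_spec("hwma", lambda = 0.5, L = 2.9069), mom)
#' @export
apply_chart <- function(w, spec, moments) {
  stopifnot(inherits(spec, "chart_spec"), inherits(moments, "w_moments"))
  if (length(w) < 1L || !all(is.finite(w)))
    stop("'w' must be a nonempty finite numeric vector", call. = FALSE)
  nt <- length(w)
  mu <- moments$mu_w

  if (spec$scheme == "cusum") {
    k <- if (is.null(spec$k)) 0.5 * moments$sigma_w else spec$k
    h <- spec$L * moments$sigma_w
    cp <- cm <- numeric(nt)
    up <- lo <- 0
    for (t in seq_len(nt)) {
      d <- w[t] - mu
      up <- max(0, up + d - k)
      lo <- max(0, lo - d - k)
      cp[t] <- up
      cm[t] <- lo
    }
    return(data.frame(t = seq_len(nt), w = w, cusum_pos = cp,
                      cusum_neg = cm, h = h,
                      signal = cp > h | cm > h))
  }

  lim <- control_limits(spec, moments, seq_len(nt))
  stat <- numeric(nt)
  if (spec$scheme == "hwma") {
    wbar <- c(mu, cumsum(w) / seq_len(nt))[seq_len(nt)]
    stat <- spec$l_outer * w + (1 - spec$l_outer) * wbar
  } else if (spec$scheme %in% c("dhwma", "hhwma")) {
    l1 <- spec$l_outer
    l2 <- spec$l_inner
    wbar <- c(mu, cumsum(w) / seq_len(nt))[seq_len(nt)]
    h_inner <- l2 * w + (1 - l2) * wbar
    hbar <- c(mu, cumsum(h_inner) / seq_len(nt))[seq_len(nt)]
    stat <- l1 * h_inner + (1 - l1) * hbar
  } else { # ewma / dewma
    l <- spec$l_outer
    z <- z2 <- mu
    for (t in seq_len(nt)) {
      z <- l * w[t] + (1 - l) * z
      z2 <- l * z + (1 - l) * z2
      stat[t] <- if (spec$scheme == "dewma") z2 else z
    }
  }
  data.frame(t = seq_len(nt), w = w, statistic = stat,
             lcl = lim$lcl, ucl = lim$ucl,
             signal = signal(stat, lim$lcl, lim$ucl))
}
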