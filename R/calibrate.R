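#' Calibrate a control-limit constant to a nominal in-control ARL
#'
#' Finds the constant `L` whose attained in-control average run length
#' matches a nominal target (500 in the usual design) by bisection on
#' `L`. Common random numbers are used across limit evaluations -- the
#' same seed is replayed for every candidate `L`, which makes the
#' attained-ARL curve a monotone step function of `L` and bisection
#' reliable at moderate replication counts. A final confirmation run
#' with a fresh seed reports the attained ARL and its Monte Carlo
#' standard error.
#'
#' @param scheme,lambda,lambda1,lambda2,k chart family and parameters,
#'   as in [chart_spec()] (the limit constant is the unknown).
#' @param m,n phase-I and phase-II sample sizes.
#' @param dist process family, as in [rl_config()] (the in-control run
#'   length is distribution-free, so this mainly matters for checking).
#' @param target_arl0 nominal in-control ARL (> 1).
#' @param tolerance stop when the attained ARL is within this of the
#'   target; default 2.
#' @param replications Monte Carlo replications per evaluation.
#' @param bracket search interval for `L`; the attained ARL must
#'   straddle the target across it.
#' @param max_run_length run-length cap per replication.
#' @param seed integer seed (replayed across evaluations).
#' @return An object of class `"calibration_result"`: `limit_constant`,
#'   `attained_arl0`, `mc_standard_error`, `iterations`,
#'   `tolerance_met`, plus the final [chart_spec()].
#' @examples
#' \donttest{
#' calibrate_limit("hwma", lambda = 0.5, m = 100, n = 5,
#'                 target_arl0 = 500, replications = 2000, seed = 1)
#' }
#' @export
calibrate_limit <- function(scheme, lambda = NULL, lambda1 = NULL,
                            lambda2 = NULL, k = NULL, m, n,
                            dist = "normal", target_arl0 = 500,
                            tolerance = 2, replications = 20000,
                            bracket = c(0.5, 5),
                            max_run_length = 100000, seed = 1) {
  stopifnot(target_arl0 > 1, tolerance > 0,
            length(bracket) == 2L, bracket[1] < bracket[2])
  make_spec <- function(L)
    chart_spec(scheme, lambda = lambda, lambda1 = lambda1,
               lambda2 = lambda2, L = L, k = k)
  cfg <- rl_config(m, n, dist, delta = 0, replications = replications,
                   max_run_length = max_run_length, seed = seed)
  arl_at <- function(L) estimate_run_length(make_spec(L), cfg)$arl

  lo <- bracket[1]
  hi <- bracket[2]
  arl_lo <- suppressWarnings(arl_at(lo))
  arl_hi <- suppressWarnings(arl_at(hi))
  if (!(arl_lo < target_arl0 && arl_hi > target_arl0))
    stop(sprintf(paste0("bracket does not straddle the target: ",
                        "ARL0(%.4f) = %.1f, ARL0(%.4f) = %.1f, ",
                        "target %.1f"),
                 lo, arl_lo, hi, arl_hi, target_arl0), call. = FALSE)

  iter <- 0L
  mid <- (lo + hi) / 2
  arl_mid <- NA_real_
  while (hi - lo >= 1e-4) {
    iter <- iter + 1L
    mid <- (lo + hi) / 2
    arl_mid <- suppressWarnings(arl_at(mid))
    if (abs(arl_mid - target_arl0) <= tolerance) break
    if (arl_mid < target_arl0) lo <- mid else hi <- mid
  }

  cfg_conf <- cfg
  cfg_conf$seed <- seed + 1L
  conf <- suppressWarnings(estimate_run_length(make_spec(mid), cfg_conf))
  structure(
    list(limit_constant = mid, attained_arl0 = conf$arl,
         mc_standard_error = conf$mc_se, iterations = iter,
         tolerance_met = abs(conf$arl - target_arl0) <=
           tolerance + 3 * conf$mc_se,
         spec = make_spec(mid), target_arl0 = target_arl0),
    class = "calibration_result"
  )
}

#' @export
print.calibration_result <- function(x, ...) {
  print(x$spec)
  cat(sprintf(paste0("  calibrated L = %.4f after %d bisection steps\n",
                     "  attained ARL0 = %.2f (MC se %.2f), target %g, ",
                     "tolerance met: %s\n"),
              x$limit_constant, x$iterations, x$attained_arl0,
              x$mc_standard_error, x$target_arl0, x$tolerance_met))
  invisible(x)
}
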