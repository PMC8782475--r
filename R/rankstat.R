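#' Two-sample Wilcoxon rank-sum statistic of a test subgroup
#'
#' Ranks the combined sample of `m` reference (phase-I) values and `n`
#' test (phase-II) values in ascending order and returns the sum of the
#' ranks occupied by the test subgroup. Ties receive midranks (a warning
#' is emitted, since the chart moments assume a continuous process).
#'
#' Under identical continuous distributions the statistic has mean
#' `n(m+n+1)/2` and variance `mn(m+n+1)/12` regardless of the common
#' distribution, which is what makes charts built on it distribution-free.
#'
#' @param ref numeric vector, the phase-I reference sample (length >= 1).
#' @param test numeric vector, the phase-II test subgroup (length >= 1).
#' @return The rank sum `W`, a number between `n(n+1)/2` and
#'   `n(2m+n+1)/2`.
#' @examples
#' wilcoxon_rank_sum(c(1, 3), c(2, 4))  # ranks 2 and 4 -> 6
#' @export
wilcoxon_rank_sum <- function(ref, test) {
  if (length(ref) < 1L || length(test) < 1L)
    stop("'ref' and 'test' must both be nonempty", call. = FALSE)
  if (!all(is.finite(ref)) || !all(is.finite(test)))
    stop("'ref' and 'test' must contain only finite values", call. = FALSE)
  combined <- c(ref, test)
  if (anyDuplicated(combined))
    warning("ties present; midranks assigned but the in-control variance ",
            "formula assumes a continuous process", call. = FALSE)
  r <- rank(combined, ties.method = "average")
  sum(r[seq_along(test) + length(ref)])
}

#' In-control moments of the Wilcoxon rank-sum statistic
#'
#' @param m phase-I reference sample size (integer >= 1).
#' @param n phase-II subgroup size (integer >= 1).
#' @return An object of class `"w_moments"`: a list with `mu_w`
#'   (`n(m+n+1)/2`), `var_w` (`mn(m+n+1)/12`), `sigma_w`, `m`, `n` and
#'   `N = m + n`.
#' @examples
#' w_moments(520, 5)  # mu_w = 1315
#' @export
w_moments <- function(m, n) {
  if (length(m) != 1L || length(n) != 1L ||
      !is.finite(m) || !is.finite(n) ||
      m < 1 || n < 1 || m != floor(m) || n != floor(n))
    stop("'m' and 'n' must be positive integers", call. = FALSE)
  m <- as.integer(m)
  n <- as.integer(n)
  mu <- as.numeric(n) * (m + n + 1) / 2
  v <- as.numeric(m) * n * (m + n + 1) / 12
  structure(
    list(mu_w = mu, var_w = v, sigma_w = sqrt(v), m = m, n = n, N = m + n),
    class = "w_moments"
  )
}

#' @export
print.w_moments <- function(x, ...) {
  cat("In-control Wilcoxon rank-sum moments\n")
  cat(sprintf("  m = %d, n = %d (N = %d)\n", x$m, x$n, x$N))
  cat(sprintf("  mu_W = %g, var_W = %g (sigma_W = %g)\n",
              x$mu_w, x$var_w, x$sigma_w))
  invisible(x)
}
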