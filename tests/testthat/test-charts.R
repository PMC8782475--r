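mom520 <- w_moments(520, 5)

test_that("chart_spec validates its arguments", {
  expect_error(chart_spec("hwma", lambda = 0, L = 2), "in \\(0, 1\\]")
  expect_error(chart_spec("hwma", lambda = 0.5, L = -1), "positive")
  expect_error(chart_spec("hhwma", lambda1 = 0.5, L = 2), "lambda2")
  expect_error(chart_spec("hwma", lambda = 0.5, lambda2 = 0.2, L = 2),
               "HHWMA")
  expect_error(chart_spec("cusum", L = 3, k = -1), "nonnegative")
  expect_error(chart_spec("dhwma", L = 2), "lambda")
})

test_that("single-step updates reproduce the worked silica example", {
  w1 <- 1800 # first rank-sum statistic of the worked example
  h <- apply_chart(w1, chart_spec("hwma", lambda = 0.5, L = 2.9069),
                   mom520)
  expect_equal(h$statistic, 1557.5)
  dh <- apply_chart(w1, chart_spec("dhwma", lambda = 0.5, L = 2.0095),
                    mom520)
  expect_equal(dh$statistic, 1436.25)
  hh <- apply_chart(w1, chart_spec("hhwma", lambda1 = 0.75,
                                   lambda2 = 0.5, L = 2.1171), mom520)
  expect_equal(round_half_up(hh$statistic), 1496.88)
})

test_that("lambda = 1 collapses every smoothing scheme to the raw statistic", {
  set.seed(3)
  w <- sample(1000:1600, 20)
  for (scheme in c("hwma", "dhwma", "ewma", "dewma")) {
    tb <- apply_chart(w, chart_spec(scheme, lambda = 1, L = 3), mom520)
    expect_equal(tb$statistic, as.numeric(w), info = scheme)
  }
  tb <- apply_chart(w, chart_spec("hhwma", lambda1 = 1, lambda2 = 1,
                                  L = 3), mom520)
  expect_equal(tb$statistic, as.numeric(w))
})

test_that("a constant sequence at mu_W is a fixed point with no signal", {
  w <- rep(mom520$mu_w, 30)
  for (scheme in c("hwma", "dhwma", "ewma", "dewma")) {
    tb <- apply_chart(w, chart_spec(scheme, lambda = 0.3, L = 2), mom520)
    expect_equal(tb$statistic, w, info = scheme)
    expect_false(any(tb$signal), info = scheme)
  }
  tb <- apply_chart(w, chart_spec("hhwma", lambda1 = 0.3, lambda2 = 0.7,
                                  L = 2), mom520)
  expect_equal(tb$statistic, w)
  expect_false(any(tb$signal))
  cu <- apply_chart(w, chart_spec("cusum", L = 3, k = 0), mom520)
  expect_equal(cu$cusum_pos, rep(0, 30))
  expect_equal(cu$cusum_neg, rep(0, 30))
  expect_false(any(cu$signal))
})

test_that("variance factors evaluate the published piecewise forms", {
  expect_equal(hwma_variance_factor(1, 0.5), 0.25)
  expect_equal(hwma_variance_factor(2, 0.5), 0.5)
  expect_equal(dhwma_variance_factor(1, 0.5), 0.0625)
  expect_equal(dhwma_variance_factor(2, 0.5), 0.25 * (0.25 + 4 * 0.25))
  expect_equal(hhwma_variance_factor(1, 0.75, 0.5), 0.140625)
  expect_equal(hhwma_variance_factor(2, 0.5, 0.5),
               dhwma_variance_factor(2, 0.5))
  expect_error(hwma_variance_factor(0, 0.5), "positive integers")
})

test_that("variance factors match the coefficient-propagation oracle", {
  lam_grid <- c(0.05, 0.25, 0.5)
  for (l in lam_grid) {
    sh <- chart_spec("hwma", lambda = l, L = 2)
    sd2 <- chart_spec("dhwma", lambda = l, L = 2)
    fh <- hwma_variance_factor(1:50, l)
    fd <- dhwma_variance_factor(1:50, l)
    for (t in c(1:10, 25, 50)) {
      expect_lt(abs(fh[t] - coefficient_oracle(sh, t)) / fh[t], 1e-10)
      expect_lt(abs(fd[t] - coefficient_oracle(sd2, t)) / fd[t], 1e-10)
    }
  }
  for (l1 in c(0.1, 0.2)) for (l2 in lam_grid) {
    sp <- chart_spec("hhwma", lambda1 = l1, lambda2 = l2, L = 2)
    f <- hhwma_variance_factor(1:50, l1, l2)
    for (t in c(1:10, 37, 50))
      expect_lt(abs(f[t] - coefficient_oracle(sp, t)) / f[t], 1e-10)
  }
  for (scheme in c("ewma", "dewma")) {
    sp <- chart_spec(scheme, lambda = 0.3, L = 2)
    f <- chart_variance_factor(sp, 1:30)
    for (t in c(1, 2, 7, 30))
      expect_lt(abs(f[t] - coefficient_oracle(sp, t)) / f[t], 1e-10)
  }
})

test_that("chart weights are unbiased and match hand expansions", {
  # DHWMA at t = 2: c = (2 lambda (1 - lambda), lambda^2)
  wts <- chart_weights(chart_spec("dhwma", lambda = 0.5, L = 2), 2)
  expect_equal(wts$coefficients, c(0.5, 0.25))
  expect_equal(sum(wts$coefficients^2), 0.3125)
  wts1 <- chart_weights(chart_spec("hwma", lambda = 0.25, L = 2), 1)
  expect_equal(wts1$coefficients, 0.25)
  expect_equal(wts1$constant, 0.75)
  # DEWMA single-term double smoothing: multiplier lambda^4
  expect_equal(coefficient_oracle(chart_spec("dewma", lambda = 0.5,
                                             L = 2), 1), 0.0625)
  # unbiasedness at every t: coefficients plus constant sum to one
  set.seed(8)
  for (scheme in c("hwma", "dhwma", "ewma", "dewma")) {
    sp <- chart_spec(scheme, lambda = 0.35, L = 2)
    for (t in c(1, 2, 5, 13))
      with(chart_weights(sp, t),
           expect_equal(sum(coefficients) + constant, 1, info = scheme))
  }
  sp <- chart_spec("hhwma", lambda1 = 0.15, lambda2 = 0.6, L = 2)
  for (t in c(1, 3, 9))
    with(chart_weights(sp, t),
         expect_equal(sum(coefficients) + constant, 1))
})

test_that("control limits reproduce the worked-example surface at 2 dp", {
  h <- control_limits(chart_spec("hwma", lambda = 0.5, L = 2.9069),
                      mom520, 1:2)
  expect_equal(round_half_up(h$lcl), c(824.33, 621.09))
  expect_equal(round_half_up(h$ucl), c(1805.67, 2008.91))
  d <- control_limits(chart_spec("dhwma", lambda = 0.5, L = 2.0095),
                      mom520, 1)
  expect_equal(round_half_up(c(d$lcl, d$ucl)), c(1145.40, 1484.60))
  hh <- control_limits(chart_spec("hhwma", lambda1 = 0.75,
                                  lambda2 = 0.5, L = 2.1171), mom520, 1)
  expect_equal(round_half_up(c(hh$lcl, hh$ucl)), c(1046.98, 1583.02))
})

test_that("limits are symmetric and their width eventually tightens", {
  # the HWMA width is nonincreasing from t = 2; the double-smoothed
  # widths first widen while the harmonic variance terms build up
  # (that transient is part of the closed forms) and decay
  # monotonically once past it
  for (sp in list(chart_spec("hwma", lambda = 0.25, L = 2.9559),
                  chart_spec("dhwma", lambda = 0.05, L = 1.2959),
                  chart_spec("hhwma", lambda1 = 0.1, lambda2 = 0.5,
                             L = 3.11))) {
    lim <- control_limits(sp, mom520, 1:500)
    expect_equal(lim$ucl - lim$center, lim$center - lim$lcl)
    width <- lim$ucl - lim$lcl
    if (sp$scheme == "hwma") {
      expect_true(all(diff(width[-1]) <= 1e-9))
    } else {
      expect_true(all(diff(width[10:500]) <= 1e-9))
      expect_lt(width[500], width[3])
    }
  }
  # long-run factors approach the stable components
  expect_lt(hwma_variance_factor(5000, 0.25) - 0.0625, 2e-4)
  expect_lt(dhwma_variance_factor(5000, 0.25) - 0.25^4, 0.01)
})

test_that("HHWMA with equal parameters reproduces DHWMA bit for bit", {
  set.seed(12)
  w <- mom520$mu_w + round(rnorm(40, 0, mom520$sigma_w))
  for (l in c(0.05, 0.25, 0.5)) {
    dspec <- chart_spec("dhwma", lambda = l, L = 2.9995)
    hspec <- chart_spec("hhwma", lambda1 = l, lambda2 = l, L = 2.9995)
    expect_identical(dhwma_variance_factor(1:100, l),
                     hhwma_variance_factor(1:100, l, l))
    expect_identical(apply_chart(w, dspec, mom520),
                     apply_chart(w, hspec, mom520))
  }
})

test_that("double smoothing agrees with direct re-evaluation from history", {
  set.seed(5)
  w <- mom520$mu_w + rnorm(7, 0, mom520$sigma_w)
  tb <- apply_chart(w, chart_spec("dhwma", lambda = 0.3, L = 2), mom520)
  expect_equal(tb$statistic,
               direct_double_stat(w, 0.3, 0.3, mom520$mu_w))
  tb2 <- apply_chart(w, chart_spec("hhwma", lambda1 = 0.8,
                                   lambda2 = 0.2, L = 2), mom520)
  expect_equal(tb2$statistic,
               direct_double_stat(w, 0.8, 0.2, mom520$mu_w))
})

test_that("signal rule is strict at the limits", {
  expect_true(signal(1667.13, 964.42, 1665.58))
  expect_false(signal(1557.50, 824.33, 1805.67))
  expect_false(signal(1805.67, 824.33, 1805.67)) # exactly on the limit
  expect_true(signal(824.32, 824.33, 1805.67))
})

test_that("competitor charts behave at their degenerate settings", {
  set.seed(9)
  w <- mom520$mu_w + rnorm(15, 0, mom520$sigma_w)
  # EWMA with lambda = 1 is the Shewhart chart of W itself
  sh <- apply_chart(w, chart_spec("ewma", lambda = 1, L = 3), mom520)
  expect_equal(sh$statistic, w)
  expect_equal(sh$ucl, rep(mom520$mu_w + 3 * mom520$sigma_w, 15))
  # CUSUM with zero drift never accumulates at the centre
  cu <- apply_chart(rep(mom520$mu_w, 15), chart_spec("cusum", L = 3,
                                                     k = 0), mom520)
  expect_true(all(cu$cusum_pos == 0 & cu$cusum_neg == 0))
  # CUSUM accumulates (W - mu - k) on a sustained upward drift
  up <- apply_chart(rep(mom520$mu_w + 50, 4),
                    chart_spec("cusum", L = 3, k = 10), mom520)
  expect_equal(up$cusum_pos, cumsum(rep(40, 4)))
  expect_equal(up$cusum_neg, rep(0, 4))
})
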