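---
title: "Distribution-free HWMA charts on the Wilcoxon rank-sum statistic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distribution-free HWMA charts on the Wilcoxon rank-sum statistic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npwma)
```

## The monitoring problem

A process has been observed in control long enough to collect a
phase-I reference sample $X = \{x_1,\dots,x_m\}$. From then on,
subgroups $Y_t = \{y_{t1},\dots,y_{tn}\}$ of fixed size $n$ arrive
sequentially (hourly samples from a flotation circuit, daily assay
batches, and so on). The question at every $t$ is whether the location
of the process has shifted relative to the reference, *without*
assuming any distributional form — industrial measurements such as
silica concentration are routinely non-normal.

The two-sample Wilcoxon rank-sum statistic answers the distributional
part. Rank all $N = m + n$ observations of the combined sample
ascending and let $W_t$ be the sum of the ranks occupied by the
subgroup $Y_t$. Under the in-control hypothesis (subgroup and
reference share one continuous distribution),

$$\mu_W = \frac{n(m+n+1)}{2}, \qquad
  \sigma_W^2 = \frac{mn(m+n+1)}{12},$$

whatever that distribution is. Location shifts push $W_t$ up or down;
everything the charts below do is built on this one statistic.
`wilcoxon_rank_sum()` assigns midranks to ties (with a warning — the
variance above assumes a continuous process) and `w_moments()`
evaluates the moments exactly.

## The charting schemes

All schemes start from the zero state and plot a smoothed version of
$W_t$ against limits centred at $\mu_W$:

* **HWMA** (homogeneously weighted moving average):
  $H_t = \lambda W_t + (1-\lambda)\bar W_{t-1}$, where
  $\bar W_{t-1}$ is the arithmetic mean of all previous rank sums and
  $\bar W_0 = \mu_W$. The weight $1-\lambda$ is spread *evenly* over
  the whole history, unlike the EWMA's geometric decay.
* **DHWMA**: the same smoothing applied twice with one parameter,
  $DH_t = \lambda H_t + (1-\lambda)\bar H_{t-1}$ with
  $\bar H_0 = \mu_W$.
* **HHWMA**: the hybrid variant with an inner parameter $\lambda_2$
  (driving $H_t$) and an outer parameter $\lambda_1$. With
  $\lambda_1 = \lambda_2$ it *is* the DHWMA chart, and the package
  implements DHWMA as exactly that specialization, so the two agree
  bit for bit. (The double-smoothed statistic is symmetric in
  $(\lambda_1,\lambda_2)$: writing it as a linear filter of the
  $W_s$ shows every coefficient depends only on $\lambda_1\lambda_2$,
  $\lambda_1+\lambda_2-2\lambda_1\lambda_2$ and
  $(1-\lambda_1)(1-\lambda_2)$.)
* **EWMA, DEWMA, CUSUM**: the classical memory-type competitors on the
  same statistic, for benchmarking.

Treating the $W_s$ as uncorrelated with variance $\sigma_W^2$, each
smoothed statistic has in-control variance
$f(t)\,\sigma_W^2$ with a closed-form factor $f(t)$; for HWMA
$f(t) = \lambda^2 + (1-\lambda)^2/(t-1)$ for $t>1$, and for the
double schemes $f(t)$ involves partial harmonic sums (evaluated
incrementally in compiled code, $O(1)$ per step). Control limits are
the time-varying bands $\mu_W \pm L\,\sigma_W\sqrt{f(t)}$; the signal
rule is strict (`statistic > ucl | statistic < lcl`), so a value
exactly on a limit is in control. No truncation is applied where a
band exceeds the attainable range of the statistic at small $t$.

Two numerical safeguards back these formulas. First,
`chart_weights()` propagates every recursion symbolically into
$\text{statistic}_t = \sum_s c_s W_s + c_0\mu_W$ and serves as an
independent oracle: the closed-form factors match $\sum_s c_s^2$ to
$10^{-10}$ relative error for all tested $t$ and smoothing values, and
$\sum_s c_s + c_0 = 1$ (unbiasedness) at every $t$. Second, the EWMA
and DEWMA limit factors are *defined* through that propagation rather
than transcribed from the literature, which removes any ambiguity
about asymptotic-versus-exact variants: the limits are exact at every
$t$ by construction.

A consequence worth knowing: for the double-smoothed schemes with
small $\lambda$, the limit width is *not* monotone after $t=2$. The
$t=1,2$ variances are tiny ($\lambda^4$-order) and the harmonic terms
then build up before the $1/(t-1)^2$ envelope takes over, so the band
widens sharply around $t=3{-}5$ and only then tightens monotonically.
The tests assert symmetry always, monotone tightening from $t=2$ for
HWMA, and monotone tightening past the transient for the double
schemes.

## The run-length engine

Run-length behaviour has no tractable closed form for these
nonparametric schemes, so performance is estimated by zero-state
Monte Carlo (`estimate_run_length()`, compiled core):

1. draw one fresh in-control reference sample of size $m$ and keep it
   fixed for the whole replication;
2. stream subgroups of size $n$, shifted by $\delta\sigma_F$ where
   $\sigma_F$ is the population standard deviation of the process
   family ($1$, $\sqrt{5/3}$, $\sqrt3$ for the normal, $t_5$ and
   Gamma(3,1) families — families are used on their natural scale,
   and the rank statistic makes in-control behaviour invariant to
   that choice);
3. compute $W_t$ against the fixed reference, update the chart from
   the zero state, and record the first $t$ beyond the limits.

Keeping the reference fixed within a replication is deliberate: it is
how the charts are used in practice, and it induces serial dependence
among the $W_t$ (correlation $n/(N+1)$ between periods) that the
variance formulas ignore but the run length genuinely feels. The
run-length cap defaults to 100{,}000 ($200\times$ the nominal
in-control ARL of 500); capped runs enter the mean at the cap, are
counted in `n_censored`, and raise a warning above 1%. Percentiles and
the SDRL are computed on the same capped sample.

Randomness comes from R's seeded generator consumed sequentially
through the compiled loop — replications use disjoint stream segments,
so a single integer seed reproduces an entire study bit for bit, and
the first replication of a batch equals a single-run call with the
same seed (the property the zero-state tests exercise). Counter-based
per-replication streams were considered and rejected: R's generators
are not counter-based, and sequential segments already give
independence plus one-seed reproducibility.

`shift_profile()` evaluates a left-open grid
$(\delta_{\min},\delta_{\max}]$ in steps of 0.1 (by default) and
averages per-shift ARLs and SDRLs into the EARL and ESDRL overall
measures. `calibrate_limit()` finds the constant $L$ attaining a
nominal in-control ARL by bisection, replaying the same seed at every
candidate $L$ (common random numbers make attained ARL a monotone
step function of $L$), then confirms with a fresh seed. The default
tolerance is $|{\rm ARL}_0 - 500| \le 2$ at 20{,}000 replications; the
default bracket $[0.5, 5]$ covers every constant used in the package's
reference designs.

For a sanity anchor with an exactly known answer, the $\lambda = 1$
chart reduces to a Shewhart chart of $W$ itself. Its signal
probability $p$ follows from the exact null distribution of $W$
(enumerable for tiny $(m,n)$, `dwilcox` otherwise). Two facts are then
checked: the probability of a signal at $t=1$ equals $p$ exactly for
$(m,n)=(4,2)$, and the full run length is geometric with mean $1/p$
once the reference is large (at $(m,n)=(4,2)$ itself the run length is
*not* geometric — conditionally on an extreme reference draw the
signal probability can be arbitrarily small, and the tiny-reference
mean run length is heavy-tailed; the ample-reference design
$(m,n)=(2000,2)$ makes that conditioning negligible).

## Reference designs and what reproduces

The package ships the published silica-flotation case study as a
plain-text reference table (`inst/extdata/silica_published_reference.tsv`):
78 hourly subgroups of 5 monitored against $m = 520$ reference values,
with HWMA ($\lambda=0.5$, $L_H=2.9069$), DHWMA ($\lambda=0.5$,
$L_{DH}=2.0095$) and HHWMA ($\lambda_1=0.75$, $\lambda_2=0.5$,
$L_{HH}=2.1171$) columns. The raw assay data are not public; the
underlying rank-sum sequence is recovered from the HWMA column by
inverting the recursion ($W_t = 2H_t - \bar W_{t-1}$ at
$\lambda = 0.5$, snapped to the attainable half-integer grid).

Recomputing from that sequence, the package reproduces the HWMA
column in full — limits to the printed 2 decimals, statistics to the
table's own print noise ($\pm 0.13$), and the identical signalling
pattern with the first alarm on subgroup 14 — as well as the DHWMA
limit surface and the opening HHWMA limits. The double-smoothed
*statistic* columns of the reference table, however, are internally
inconsistent with the recursions stated alongside them: from the
second subgroup on they equal $\lambda_1 H_t + (1-\lambda_1)\mu_W$,
i.e. a running mean frozen at its initial value, and the HHWMA limit
column drifts from the closed-form variance from $t=3$ onward. The
package implements the recursions as defined (the frozen variant is
not a sensible estimator — it never updates its memory), and the
tests compare only the surfaces that are mutually consistent.

The same inconsistency shows up in the Monte Carlo reference values.
With the published constants at $(m,n) = (100,5)$, the engine
reproduces the HWMA designs well: attained in-control ARL within
Monte Carlo error of the reported 502.47 ($\lambda=0.05$, normal) and
499.37 ($t_5$; distribution-freeness), and the moderate-to-large-shift
ARLs of the $\lambda=0.5$ design to within a few percent. For the
DHWMA and HHWMA designs no implementation consistent with the stated
recursions — fixed or redrawn reference, exact-null i.i.d. rank sums,
and eight recursion variants were tried during development — matches
the reported in-control constants coherently (deviations run from
$-13\%$ to $+60\%$ in both directions across configurations), and the
small-shift expected-ARL summaries inherit the same gap. The
acceptance suite therefore asserts the published double-scheme
run-length values as stated and lets them fail visibly rather than
tuning toward them; the corresponding HWMA checks pass.

## The synthetic generator

`make_illustration_fixture()` emulates the case study's *shape*:
$m = 520$ reference values and 78 subgroups of width 5 from a
right-skewed family (Gamma(3,1) by default), with a location shift of
$\delta = 1$ population standard deviations switched on at subgroup
40 by default — a mid-stream shift of the size the reference designs
treat as moderate-to-large, chosen once as a realistic monitoring
scenario. What it does *not* emulate: autocorrelation, measurement
error, or any true flotation-process dynamics, so passing tests on
these fixtures demonstrate correctness of the chart arithmetic and
calibrated false-alarm behaviour, not validity on dependent real-world
streams. Fixtures serialize as single-column phase-I CSV, wide
phase-II CSV (`subgroup, obs1..obs5`; long format available) and a
JSON manifest carrying family, shift, changepoint and seed.

## Problem sizes and reporting conventions

The packaged studies use 10,000 replications for in-control ARLs
(Monte Carlo standard error about 10 run-length units at ARL 500) and
2,000 replications per shift for EARL grids, sizes at which every
stochastic tolerance in the test suite is several standard errors
wide. Reports round half-up to 2 decimals at output time only; all
internal arithmetic is double precision. Statistics, limits and signal
flags serialize as RFC-4180 CSV blocks per scheme; summaries and
calibration results as JSON. The thin command-line wrapper
(`inst/cli/npwma.R`) exposes `simulate`, `calibrate`, `chart` and
`fixture` subcommands over these functions and exits with status 2 on
usage errors.

## Known limitations

* Zero-state evaluation only; steady-state run lengths and
  fast-initial-response limits are out of scope.
* The variance factors (hence the limits) ignore the shared-reference
  correlation among rank sums; this is the standard design for these
  charts, but it means attained error rates depend on $m$ more than
  the formulas suggest when $m$ is small.
* Ties receive midranks without a variance correction; heavily
  discretized measurements deserve a dedicated tie-corrected design.
* The competitor CUSUM uses a user-supplied reference value
  ($k = 0.5\,\sigma_W$ by default) and a two-sided tabular form; no
  claim is made that this matches any particular published CUSUM
  tuning.
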