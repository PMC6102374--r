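---
title: "Methods: uncertainty quantification and sensitivity analysis in uqsa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: uncertainty quantification and sensitivity analysis in uqsa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A simulation model $Y = U(t, Q)$ maps $d$ uncertain parameters
$Q = (Q_1, \dots, Q_d)$, each described by a probability distribution, to an
output — typically a time series such as a membrane voltage trace, or a set
of spike trains. `uqsa` estimates how the parameter uncertainty propagates
into the output (mean $\mathbb{E}[Y]$, variance $\mathbb{V}[Y]$, and the
5th/95th percentiles forming a 90% prediction interval), and how much of the
output variance each parameter is responsible for (first-order Sobol index
$S_i = \mathbb{V}[\mathbb{E}[Y \mid Q_i]]/\mathbb{V}[Y]$ and total-order
index $S_{Ti}$, which adds all interaction terms involving $Q_i$). All
metrics are computed per output point and, for the Sobol indices, also as
time averages $\bar S_i$, $\bar S_{Ti}$ so that outputs of different
dimensionality can be compared.

The model is a black box: any function that accepts named parameter values
and returns `list(time, values, info)` can be analysed, and models whose raw
trace is a poor comparison target (e.g. spiking neurons, where spike timing
jitters) can instead be analysed through extracted *features* such as spike
rate, action-potential width, interspike-interval statistics, or pairwise
spike-train correlations.

## Estimators

### Polynomial chaos expansions (default)

The model is approximated by a surrogate
$\hat U(t, Q) = \sum_{n=0}^{N_p - 1} c_n(t)\,\phi_n(Q)$ in polynomials
orthonormal under the parameter distribution, truncated at total degree $p$
($N_p = \binom{d+p}{p}$). Univariate families come from the classical
three-term recurrences (Legendre for uniform marginals, Hermite for normal
ones) and from the discretized Stieltjes procedure for any other marginal
with a density on finite support; multivariate terms are tensor products.
The basis is normalised internally, so $\mathbb{E}[Y] \approx c_0$,
$\mathbb{V}[Y] \approx \sum_{n \ge 1} c_n^2$, and the Sobol indices are sums
of squared coefficients over the terms whose multi-index is non-zero only in
coordinate $i$ (first order) or non-zero in coordinate $i$ at all (total
order), divided by the variance. Percentiles have no closed form and are
read off $10^4$ surrogate evaluations at Hammersley points.

Coefficients are fitted two ways:

* **Point collocation** (default): the surrogate is regressed onto model
  evaluations at $N_s = 2(N_p + 1)$ nodes (the standard over-sampling rule),
  drawn deterministically by mapping a Hammersley set through the joint's
  inverse transformation. The regression is ridge-penalised (Tikhonov), with
  the penalty chosen by generalized cross-validation over the grid
  $\{0, 10^{-12}, \dots, 10^{-2}\}$ (scaled by the mean diagonal of the
  normal equations). The grid is scanned in ascending order and a larger
  penalty must improve the GCV score by a relative margin of $10^{-6}$ to be
  accepted; this tie-break matters because for noise-free polynomial data
  the residual identity used by GCV bottoms out at the cancellation noise
  floor, where the score would otherwise drift toward needless shrinkage.
  With that rule, polynomials of degree $\le p$ are reproduced exactly
  (tested to $10^{-8}$). Invalid model evaluations (failed runs, undefined
  features) are dropped from the regression, which is well-posed as long as
  at least $N_p$ valid rows remain.
* **Pseudo-spectral projection**: $c_n = \sum_k w_k\, Y(q_k)\, \phi_n(q_k)$
  over a Gaussian quadrature rule of order $p + 2$ by default — a full
  tensor rule up to four dimensions, a Smolyak combination of Gaussian rules
  above that. The paper this design follows uses nested Leja rules with a
  Smolyak grid; we use Gaussian nodes because their polynomial exactness is
  easy to verify in tests, at the cost of more nodes. Projection cannot drop
  bad rows, so any invalid evaluation is a hard error directing the user to
  point collocation.

### Quasi-Monte Carlo with Saltelli's scheme

With `method = "mc"`, a Saltelli design of $N(d+2)$ rows is built from two
$N$-row blocks $A$, $B$ and the $d$ hybrid blocks $AB_i$. Mean, variance
(with the $N-1$ divisor) and percentiles use the $A$ block only, since the
remaining rows are not mutually independent. First-order indices use the
Saltelli (2010) estimator
$S_i = \overline{f_B (f_{AB_i} - f_A)} / \hat V$ and total-order indices the
Jansen estimator $S_{Ti} = \overline{(f_A - f_{AB_i})^2} / (2 \hat V)$, with
$\hat V$ the sample variance over the pooled $A$ and $B$ blocks. Invalid
evaluations are replaced by the per-output mean of the valid ones (with a
warning carrying the count) — the standard workaround, which biases the
indices when many runs fail but keeps the estimator defined.

The underlying uniform points are a randomly shifted Halton sequence in $2d$
dimensions. The design decision in the specification this package follows
names a Sobol' sequence here; no installed package provides one, and rather
than embed direction-number tables we use the shifted Halton set, which is
deterministic given a seed, gives independent replicates across seeds
(Cranley–Patterson rotation), and passes the closed-form estimator checks at
$d = 11$ with absolute errors around $10^{-2}$ at $N = 4096$. For very high
dimensions unshifted Halton coordinates correlate; the random shift
mitigates but does not remove this, which is an accepted limitation.

### Dependent parameters: the Rosenblatt transformation

Chaos expansions assume independent coordinates. Dependent joints are
declared constructively — a marginal for the first coordinate plus, for each
later coordinate, a function returning its conditional distribution given
the earlier ones — which makes both directions of the Rosenblatt map exact
sequential (inverse) CDF applications rather than fitted approximations.
`quantify()` then builds the expansion on the independent unit-cube base
space (shifted Legendre in every coordinate) and evaluates the model at the
transformed nodes: the reformulated model has the same output distribution,
so all statistics carry over, and the index of base coordinate $i$ is the
sensitivity attributed to parameter $i$ of the construction. The bundled
dependent coffee-cup study checks the two invariants this must satisfy: the
statistics match the independent parameterisation, and the sensitivity to
the artificial factor $\alpha$ vanishes.

Boundary points of the hypercube are rejected rather than clamped (inverse
CDFs of unbounded marginals diverge there); both node generators use index
offsets that keep all points strictly interior, which is also why the
Hammersley first coordinate is $(i - 1/2)/n$ rather than $i/n$.

## The evaluation pipeline

`quantify()` shares one node set between the model and all features — only
the expansion coefficients differ per output. Each node is evaluated
independently (optionally across forked workers; results are gathered by
node index so scheduling never affects statistics). An evaluation is invalid
if the model raises, returns `NULL`, or a feature returns `NA` (e.g. spike
width without spikes); validity is tracked per output. More than 50% invalid
evaluations aborts the analysis with advice to narrow the distributions,
since no statistic is trustworthy at that point.

Irregular outputs (adaptive solvers) are interpolated onto a common grid:
the time axis of the valid evaluation with the most points, restricted to
the span covered by every evaluation so nothing is extrapolated; piecewise
cubic for five or more points, linear below. Models without a time axis must
already be regular.

`screen_single()` implements one-at-a-time screening: a 1-parameter analysis
per uncertain parameter with the others held at their declared fallback
values. It is a cheap pre-filter and deliberately blind to interactions.

## Bundled case-study models

* **Cooling coffee cup** $dT/dt = -\kappa (T - T_{env})$, $T(0) = 95$ °C,
  200 min on a 150-point grid, solved with `deSolve` at tolerances $10^{-10}$
  (closed-form error below $10^{-4}$ °C). Case-study distributions
  $\kappa \sim U(0.025, 0.075)$ 1/min, $T_{env} \sim U(15, 25)$ °C. The
  dependent variant uses $\alpha \hat\kappa$ in place of $\kappa$ with
  $\hat\kappa \mid \alpha \sim U(0.025, 0.075)/\alpha$, so the product always
  recovers the original $\kappa$ distribution; $\alpha \sim U(0.5, 1.5)$ was
  fixed once (any zero-free interval works, and the analysis outcome provably
  cannot depend on the choice — that independence is itself one of the
  checks).
* **Hodgkin-Huxley membrane** in the original 1952 convention (resting
  potential 0 mV), Table-2 parameter values, continuous 140 µA/cm²
  stimulus from $t = 0$, fixed-step RK4 at 0.01 ms (halving the step moves
  the trace by < 0.5 mV), reported on the 5–15 ms window every 0.05 ms so the
  initial-condition transient is excluded. The case study puts independent
  $\pm 10\%$ uniform distributions on all eleven parameters.
* **Recurrent LIF network**: 10,000 excitatory + 2,500 inhibitory neurons,
  fixed in-degree 1,000/250, $J = 0.1$ mV, inhibitory weight $-gJ$, delay
  $D$, external Poisson drive at $\eta$ times the threshold rate
  $\nu_{thr} = \theta / (J C_E \tau_m)$; $\tau_m = 20$ ms, $\theta = 20$ mV,
  reset 10 mV, refractory 2 ms, dt = 0.1 ms (canonical constants of the
  cited network model, which the source paper does not restate). 1,000 ms
  simulated; the first 20 excitatory units are recorded after a 100 ms
  warm-up (which 20 is not specified anywhere; the first 20 is the
  deterministic choice). Within $\eta \in [1.5, 3.5]$, $D \in [1.5, 3]$ ms,
  the network is synchronous-regular for $g \in [1, 3]$ and
  asynchronous-irregular for $g \in [5, 8]$.

A full UQ of the network (32 collocation nodes × minutes per simulation) is
not a desk-scale computation; the test suite instead verifies the
state-contrast properties that the published analysis rests on (pairwise
binned correlation far higher in SR than AI; interval CV near 1 in AI) on
single simulations per state.

## Features

`find_spikes()` defines a spike as a contiguous super-threshold excursion
(default threshold −30 mV for physiological traces; pass a positive value
for the historical 0 mV-resting convention) and cuts a ±5 ms window around
each peak — both configurable, neither stated in the source material. The
seven spiking features follow the Druckmann et al. definitions; choices the
literature leaves protocol-dependent are: the accommodation index discards
the first interspike interval when five or more are available (else none),
the afterhyperpolarisation depth is the global minimum between consecutive
peaks, and the spike width is the chord at the voltage midway between the
threshold-crossing (onset) voltage and the peak voltage, linearly
interpolated.

The thirteen network features operate on recorded spike trains; binning for
the correlation/covariance features uses the worked-example rule (a spike at
$s$ marks bin $\mathrm{round}(s/dt)$, ties rounding up). Defaults that the
source material leaves open: Victor-Purpura shift cost $q = 1/5$ per ms, van
Rossum $\tau = 10$ ms, instantaneous-rate window 10 ms, 1 ms bins — all
arguments of `network_feature_set()`.

## Error metric and the method-comparison experiment

`relative_error()` implements the time-averaged absolute relative error
$\varepsilon_X = \frac{1}{T}\int |X - X_{est}|/|X|\,dt$ used to compare
estimators, with the first 5 ms excluded for the membrane-model experiment.
`convergence_experiment()` tabulates this error for the mean, the variance
and the first-order Sobol indices over grids of polynomial orders and sample
counts, against a converged reference (a high-order expansion by default,
order 6; sampling-based errors are averaged over re-runs since the design is
randomised). For the Sobol indices the error is computed per parameter and
averaged over parameters; this is the reading under which the published
method-comparison numbers are reproducible, because with a sampling-based
reference the relative error of a negligible parameter's index is driven by
the reference's own noise floor (the ratio of two near-zero quantities), and
that regime is exactly what the very large printed quasi-Monte Carlo errors
reflect. The alternative reading — averaging the index curves over
parameters first — collapses those ratios and yields errors orders of
magnitude smaller for both methods.

Problem sizes used by the acceptance computations, chosen once: the
11-parameter membrane model at order 4 (2,732 evaluations) and order 5
(8,738) as the expansion side; the Sobol reference from a blockwise
Saltelli run at $N = 10^5$ (1.3 million evaluations, the reference size the
published experiment states), evaluated block-by-block so peak memory stays
within a desktop budget; and quasi-Monte Carlo error points at
$N = 5{,}000$ (65,000 evaluations) averaged over 3 re-runs (the published
experiment averages 50; 3 keeps the run inside its time budget at the cost
of a noisier point estimate).

## Numerical choices and degenerate inputs

* `dist_uniform_pm(0, f)` with $f > 0$ is an error, not a silent point mass:
  a relative interval around zero has zero width regardless of $f$ and
  almost always indicates a transcription mistake.
* Outputs whose variance sits at the regression noise floor (below
  $10^{-13}$ of the squared output scale) get flagged-missing Sobol indices;
  time averages are taken over the remaining points.
* Percentiles interpolate linearly between order statistics (R type 7),
  fixed for reproducibility.
* Multi-indices are graded lexicographic, so persisted coefficient layouts
  are stable.
* HDF5 has no missing-value marker; persisted arrays with missing entries
  carry a companion 0/1 mask dataset.

## What the tests do and do not show

The oracle tests pin the estimators to closed forms on polynomial models,
where chaos expansions are exact by construction; real neuroscience models
are only approximately polynomial in their parameters, and the case-study
checks (order 4 versus order 5 agreement within 1%, expansion-versus-
sampling cross-checks) probe that gap for the bundled models only. Smooth,
monotone parameter dependence — as in the cooling law and, within ±10%
ranges, the membrane model — is the regime where the default order-4
expansion is trustworthy; strongly bifurcating responses (a parameter range
that straddles a spiking/non-spiking boundary) violate the smoothness
assumption, show up as slow convergence in the order-4/order-5 comparison,
and are better analysed through features that remain smooth. The synthetic
network generator emulates the published network's architecture and states
but is not the NEST implementation: spike-for-spike output differs, so only
distributional and qualitative properties (state contrasts, interval
statistics) are asserted about it.

## Known limitations

* Pseudo-spectral projection above four dimensions uses a non-nested sparse
  Gaussian grid; node counts grow quickly with order, and point collocation
  is the practical choice there (it is also the default).
* The Halton-based Saltelli design loses uniformity quality in high
  dimensions relative to a Sobol' sequence; beyond a few dozen parameters
  the estimators will need larger $N$.
* Feature outputs of varying length across evaluations are marked invalid
  rather than interpolated; only the raw model output is auto-interpolated.
* One feature evaluation failure invalidates that node for that feature
  only, but an imputation-heavy Saltelli analysis (> 50% failures) aborts.
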