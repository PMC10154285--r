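---
title: "Inferring autoregulation from single-cell dispersion: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring autoregulation from single-cell dispersion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fanoreg)
```

## The scientific problem

Whether a gene regulates its own expression (autoregulation) is hard to
establish experimentally.  `fanoreg` implements a dispersion-based
inference: from single-cell, non-interventional, one-time expression
count data — one measurement per cell, many cells, no perturbation — the
variance-to-mean ratio (VMR, or Fano factor) of a gene's stationary
expression level carries a signature of self-regulation, provided the
gene's position in a known gene regulatory network (GRN) licenses the
corresponding bound.

Two exact results drive the method.  Both are statements about
continuous-time Markov chain (CTMC) models of expression and involve no
diffusion or linear-noise approximation; the package's solvers are
correspondingly exact up to state-space truncation.

**Autonomous single gene.**  If the count $X$ of a gene is itself
Markovian (autonomous expression), with synthesis rate $f_n \ge 0$ for
the transition $n-1 \to n$ and per-molecule degradation rate $g_n > 0$
(total death rate $g_n n$), define the relative growth rate
$h_n = f_n/g_n$.  The stationary law follows the product-form recursion
$P_n = P_{n-1} h_n / n$.  Constant $h$ means no autoregulation and gives
a Poisson law (VMR = 1).  If $h_n$ is non-decreasing, VMR $\ge 1$ with
equality iff $h$ is constant, and symmetrically for non-increasing
$h_n$.  Contrapositively: VMR > 1 implies $h_{n+1} > h_n$ somewhere
(positive autoregulation), VMR < 1 implies negative autoregulation.

**Non-autonomous, acyclic, unregulated degradation.**  For a gene
embedded in a multi-gene one-step chain (only unit changes of one
species per transition), if the gene is not in a feedback loop, its
per-molecule degradation rate is a global constant, and it has no
autoregulation (its $h$ does not depend on its own count) and does not
regulate its interior factors, then its marginal VMR is $\ge 1$.  So a
significantly sub-Poissonian gene outside any directed cycle either has
autoregulation or breaks one of the model assumptions (most notably the
one-step structure).

The second route does not require autonomy — bursting via an on/off
gene state is fine — which makes it the more reliable of the two.  The
decision procedure ([`call_gene()`], [`infer_autoregulation()`])
therefore prefers it whenever VMR < 1.

## What can go wrong, and how the package represents it

Three model classes in the package mark the boundaries of the theory:

* the *telegraph model* (`telegraph_model()`): two-state bursting gives
  VMR > 1 with no autoregulation, so super-Poissonian dispersion alone
  proves nothing unless autonomy is asserted;
* the *multi-step cycle* (`multistep_cycle_model()`): a gene walking
  through $k$ sequential states and emitting one mRNA per cycle has a
  nearly deterministic production clock when $k$ is large; with $k =
  100$ stages at rate 100 and degradation 0.01 the count concentrates
  near 100 with VMR near 0.5 — sub-Poissonian with no autoregulation,
  because the effective production event is not one-step.  As the cycle
  becomes deterministic the VMR approaches roughly $(1 + 1/k)/2$-like
  behaviour; the package exposes $k$ and the stage rate rather than
  hard-coding the folklore value;
* the *indicator-gated pair* (`example2_network()`): two genes freezing
  each other's synthesis *and degradation* off a gate state.  Both
  marginal VMRs equal $2e/(4e-1) \approx 0.5506$, showing the acyclic
  bound genuinely needs unregulated degradation.  The stationary law on
  the class reachable from $(2,2)$ has the closed form
  $P(n_1, 2) \propto 1/n_1!$, $P(2, n_2) \propto 1/n_2!$ (the shared
  state counted once), which the test suite uses as an independent
  oracle for the sparse solver.

## Statistical machinery

For a Poisson gene the sample VMR (unbiased variance over mean) of $n$
cells asymptotically follows $\Gamma[(n-1)/2,\, 2/(n-1)]$, whose mean is
exactly 1.  `vmr_test()` flags a gene only when its sample VMR falls
strictly outside the equal-tailed interval; boundary ties resolve to
"not significant", and the flag feeds the decision logic.  Choices worth
recording:

* *Variance estimator*: unbiased ($n-1$) — the Gamma null's mean then
  matches the estimator's null expectation exactly.  The source theory
  does not fix the denominator; this is the convention that makes the
  null exact in expectation.
* *Sidedness*: two-sided by default (the autonomous bound can break in
  both directions); one-sided variants are exposed for targeted
  sub-Poissonian screens.
* *Small samples*: the null is asymptotic; `n < 30` warns.
* *Multiple testing*: none by default.  Calls are reported per gene at
  level $\alpha$; a Benjamini–Hochberg option exists but is off, and
  the number of genes tested is recorded in the report parameters so
  panel-wide error rates can be judged.
* *Heterogeneity*: `mixture_vmr()` implements the exact mixture-moment
  identity — if every component has VMR $\ge 1$, the mixture does too —
  so cell-type mixing cannot fake a sub-Poissonian signal.
  `decompose_vmr()` splits the pooled VMR into intrinsic and extrinsic
  components using population (divide-by-$n$) moments, the convention
  under which the decomposition is an identity; this intentionally
  differs from the unbiased estimator used in testing.

## The decision logic

For each gene: status in the GRN (`grn_status()`), then

1. absent from the GRN, or inside a directed cycle of length $\ge 2$:
   *undetermined* (neither bound applies; cycle membership is computed
   via strongly connected components);
2. self-loop in the input GRN: *declared* — the edge list already
   asserts autoregulation, and the gene is excluded from inference
   rather than double-counted;
3. VMR significantly below 1: *autoregulation* via the acyclic bound,
   caveated with its assumptions (one-step model, unregulated
   degradation; the direction is "negative" only if expression is
   additionally autonomous);
4. VMR significantly above 1, no ancestors, and autonomy explicitly
   asserted by the user: *positive autoregulation* via the autonomous
   bound.  Autonomy is rarely verifiable and frequently violated in real
   cells, so this route is opt-in (`autonomous =` argument) and always
   caveated;
5. otherwise *undetermined*.  The method never asserts the *absence* of
   autoregulation.

Lowering $\alpha$ can only move calls toward *undetermined* (the null
interval widens), a monotonicity property the suite checks.

## Exact solvers and their numerics

* `stationary_birth_death()` runs the product-form recursion in log
  space with adaptive truncation: states are added until the relative
  unnormalised mass increment falls below `tail_tol` (default
  $10^{-12}$) in the decaying regime $h_{n+1}/(n+1) < 1$, with a hard
  cap (default $10^5$ states) and a geometric tail bound reported on
  every distribution.  Divergent models ($h_n/n$ not decaying) raise a
  truncation error rather than returning a silently wrong law.
* `stationary_network()` enumerates a truncated box (capped at $10^6$
  joint states), tabulates all $2m$ one-step propensities, restricts to
  the closed communicating class reachable from `init` (strongly
  connected components of the reachable set; several reachable closed
  classes is an error asking the user to disambiguate), and solves
  $\pi Q = 0$ with one balance row replaced by normalisation via a
  sparse direct solve.  Stationary mass on "leaky" boundary states above
  $10^{-6}$ raises a truncation error.  Rate functions follow the
  destination-indexed convention of the single-gene model: the
  propensity of $n \to n + e_i$ is $f_i(n + e_i)$.
* States with $f_n = g_n = 0$ get $h_n = 0$ with a warning; the support
  simply ends there.  Numerical property suites use
  $\varepsilon = 10^{-8}$, appropriate for double-precision solves at
  these sizes.

## Simulation

All four simulators (`simulate_birth_death()`, `simulate_network()`,
`simulate_telegraph()`, `simulate_multistep_cycle()`) are exact
direct-method Gillespie kernels in C++ drawing from R's RNG, so a seed
fixes the output bit-for-bit.  Defaults:

* *burn-in*: 20 relaxation times ($20/\min g$) — the theory assumes
  stationarity but prescribes no equilibration rule; the suite checks
  that doubling the burn-in moves the sampled VMR by less than two
  Monte-Carlo standard errors;
* *sampling*: endpoint-per-cell (independent trajectories), matching
  the one-measurement-per-cell data type; thinned within-trajectory
  sampling is available with an autocorrelation warning;
* *safety cap*: $10^6$ molecules, so divergent models fail loudly;
* no tau-leaping or other accelerations — the claims being tested are
  exact-distribution claims.

## The synthetic benchmark

`generate_benchmark()` produces ground-truth-labelled data with no
download: Poisson genes ($h = 8$), linear autoregulation genes
($f_n = k + b(n-1)$, $g_n = c$, stationary VMR exactly $1 + b/(c-b)$ —
the defaults $b = \pm 1.5, -3$ with $c = 3$ give VMRs 2 and 0.5),
telegraph genes (slow switching, VMR $\approx 9.3$), regulatory cascades
(parent → child, child super-Poissonian by the acyclic bound), and the
indicator-gated pair sitting in a 2-cycle.  Truth labels record the
*rate-level* ground truth (what $h_n$ does), not detectability at a
given sample size.  The default landscape deliberately leaves most genes
undetermined, mirroring real panels where only a minority of genes is
callable.

What the generator does **not** emulate: library-size variation,
technical dropout, measurement error, cell-cell dependence, or
non-stationarity.  A green round-trip therefore establishes that the
pipeline is correct *under the model's own assumptions* — it does not
validate the method against the failure modes listed above, which real
data exhibit.

Benchmark sample sizes for the end-to-end checks follow the validation
setup: 5000 cells gives power $\ge 0.9$ for linear negative
autoregulation of relative strength $|b|/c \ge 0.5$, while type-I error
on truly Poisson genes tracks $\alpha$; bursting genes must never be
called through the sub-Poissonian route.

## Evaluation

`random_classifier_comparison()` provides the hypergeometric baseline
for contextualising real-data calls: against a reference with $K$
positives among $N$ genes, a random picker of $n$ genes is strictly
worse than an observed overlap $k$ with probability $P(X < k)$ and
strictly better with $P(X > k)$, $X \sim \mathrm{Hypergeom}(N, K, n)$;
ties are reported separately since "worse/better" is defined strictly.
For a 39-gene reference panel with 17 positives, 5 calls and 3 hits this
gives 62.55% and 10.17%.

## Known limitations

* Reanalysis of the original four experimental data sets is out of
  scope; the CLI ingests user matrices (TSV/MatrixMarket) and GRNs, but
  indirect measurements must be converted to molecule counts first —
  normalised expression destroys the VMR's meaning, and the package
  warns on non-integer input rather than silently proceeding.
* Genes absent from the supplied GRN are *undetermined*: without the
  network we cannot rule out feedback loops.
* For sub-Poissonian calls in non-autonomous settings the direction
  (positive vs negative) of autoregulation is not identified.
* The two conjectured generalisations (dropping the degradation
  restriction; cyclic GRNs) are explored numerically by the test suite's
  counterexample models but are not used for inference.
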