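---
title: "Estimating tissue composition from aggregate attribute measurements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating tissue composition from aggregate attribute measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellcomp)
```

## The problem

Heterogeneous cancer tissue is a mixture of subpopulations (cell lines),
and tracking the subpopulation ratio over time matters both for
understanding progression and for therapy strategies that deliberately
maintain a drug-sensitive majority. Imaging every cell in a mixture and
classifying it is accurate but expensive: it needs high-resolution
imaging plus segmentation. An *aggregate* measurement -- the per-channel
total fluorescence of the whole well, say -- is cheap, but it collapses
thousands of cells into one vector.

cellcomp estimates the number of cells $N_i$ of each candidate cell line
$C_1, \dots, C_n$ in a mixture from exactly that: one aggregate vector
$E_{sum} \in \mathbb{R}^m$ of per-attribute totals, plus per-cell-line
attribute profiles that were measured once, cell by cell, on pure
cultures. The set of candidate lines may safely include lines that are
absent from a given mixture; their estimates come out near zero.

## Model

**Profiling (one-time, high cost).** For each line $i$ and attribute
$j$, the profile is the sample mean and Bessel-corrected sample SD over
$p$ individually measured cells:
$$\hat\mu_{ij} = \tfrac1p \sum_{k=1}^{p} e_{ijk}, \qquad
  \hat\sigma_{ij} = \Big(\tfrac{1}{p-1}\sum_k (e_{ijk}-\hat\mu_{ij})^2\Big)^{1/2}.$$
`estimate_profile()` computes these; `write_profile()` /
`read_profile()` persist them as a long-format CSV so the database is
diffable. The attribute order of the profile is authoritative: the
aggregate measurement must be taken under the same experimental setup,
since any drift in $\mu, \sigma$ between profiling and mixture
measurement propagates directly into the count estimates (see
*Limitations*).

**Aggregate likelihood.** Cells are assumed not to influence each
other's attribute values, so the mixture total for attribute $j$ is a
sum of $N_i$ i.i.d. contributions per line. For counts large enough for
the central limit theorem,
$$E_{sumj} \mid N \;\sim\;
  \mathcal{N}\!\Big(\sum_i N_i \mu_{ij},\; \sum_i N_i \sigma_{ij}^2\Big),$$
independently across attributes. This is why the method is agnostic to
the per-cell attribute distribution: only means and variances enter.
`aggregate_log_likelihood()` evaluates the product over attributes in
log space -- with $m$ attributes and thousands of cells the raw
densities underflow doubles.

**Prior and posterior.** Each count has an independent uniform prior on
$[0, M]$ with $M$ arbitrarily large (default $10^6$). The full
conditional of $N_i$ is known only up to its normalizing integral, which
is exactly the situation Metropolis sampling is built for; the constant
$1/M$ cancels in the acceptance ratio, so the algorithm is independent
of $M$ (this is asserted exactly, not approximately, in the tests).

**Sampling.** `run_chain()` runs Metropolis-within-Gibbs: each sweep
visits components $1..n$ in order; component $i$ gets a symmetric
uniform proposal on $(N_i - \delta_i, N_i + \delta_i)$, accepted with
probability $\min(r, 1)$ where $r$ is the posterior ratio. Counts are
treated as continuous (the posterior integrals are over a continuous
$N_i$, and the density estimation downstream assumes continuous
samples).

**Density estimation and MAP.** Marginal posteriors are estimated from
the retained samples by a Gaussian-kernel KDE,
$$\hat f(x) = \frac{1}{kh}\sum_{j=1}^{k} \phi\!\Big(\frac{x - N_{ij}}{h}\Big),
  \qquad h = 1.06\, s\, k^{-1/5},$$
the plug-in bandwidth obtained from the squared-error-optimal rule by
substituting a Gaussian reference density. The reported $\hat N_i$ is
the grid arg-max of $\hat f$ (the marginal MAP), and
$\hat\pi = \hat N / \sum_i \hat N_i$ is the composition. Accuracy is
scored by the root square error
$e = \lVert \pi - \hat\pi \rVert_2$, which -- unlike a root *mean*
square error -- does not shrink automatically as $n$ grows, because
$\pi$ is constrained to the simplex.

## Tunable parameters

* **`delta` (cells)** -- proposal half-width. Too small: slow mixing,
  highly correlated samples; too large: near-total rejection. The
  default `"auto"` adapts each $\delta_i$ during burn-in only (doubling
  above 50% acceptance over 50-sweep windows, halving below 30%) and
  freezes it for the retained phase, so the retained chain is a valid
  fixed-kernel Metropolis chain. On the 10-line reference design this
  lands per-component acceptance in roughly 0.3--0.6.
* **`n_burnin` = 5000, `n_samples` = 10000, `thin` = 1** -- sized so the
  10-line design runs in well under a minute while the KDE has enough
  samples for a stable mode. For low-dimensional problems with strong
  autocorrelation, thinning (e.g. `thin = 10`) measurably tightens the
  MAP.
* **`prior_config(upper_bound = 1e6)`** -- $M$; value is immaterial as
  long as it exceeds any plausible count (it cancels in $r$).
* **`eps_n` = $10^{-3}$ cells** -- positivity floor. The Gaussian
  likelihood is undefined at the all-zero counts vector (zero variance),
  so the sampler confines counts to $[\epsilon_N, M]$; proposals outside
  are rejected via $r = 0$ rather than reflected, which preserves the
  symmetric-proposal requirement without Jacobian corrections.
* **Variance floor** -- if an attribute has zero variance in every line
  (degenerate profile), its model variance is floored at
  $10^{-12} E_{sumj}^2$ with a warning instead of producing a hard
  constraint; real variance is never floored.
* **KDE grid** -- 2048 equally spaced points on
  $[\max(0, \min - 3h), \max + 3h]$; covers the effective kernel
  support, and the resolution is reported so "within one grid cell"
  statements are meaningful. There is no boundary correction at 0, so
  the trapezoid mass of a density hugging the origin can dip a few
  percent below 1.

## Design choices

* **Marginal MAP, not joint.** The reported $\hat N$ is the vector of
  per-component marginal posterior modes; the joint mode is not
  computed. For the near-Gaussian posteriors this model produces they
  coincide in practice, and marginal densities are what one inspects
  per cell line.
* **Initialization.** Nonnegative least squares on the mean equations
  ($E_{sum} \approx \hat\mu^{\mathsf T} N$, clipped to the support)
  starts the chain near the posterior mass and shortens burn-in; the
  fallback is a flat start at $\sum_j E_{sumj} / \sum_{ij}\hat\mu_{ij}$.
* **Systematic sweep.** Components are updated in fixed order $1..n$;
  the full conditionals do not prescribe a scan order and a fixed sweep
  keeps runs reproducible.
* **Cyclic rotation direction.** In the simulation designs, row $i+1$
  of the mean matrix is row $i$ shifted left by one. Either direction
  is the same design up to relabeling; one is fixed for
  reproducibility.
* **Separate RNG streams.** `run_simulation()` derives independent
  seeds for profiling data, aggregate data and the sampler from the
  master seed, so tests can vary one source of randomness while holding
  the others.

## What the synthetic generator emulates -- and what it does not

`sim_config()` defaults reproduce the reference validation design: 10
cell lines x 10 attributes, cyclic mean matrix with first row
$[100, 200, \dots, 1000]$ (every line contributes to every attribute,
with distinct profiles), constant coefficient of variation
$\sigma_{ij} = \mathrm{CV} \cdot \mu_{ij}$ with CV = 1, and $p = 2000$
profiling cells per line. The aggregate observation is generated
honestly: $N_i$ per-cell Gaussian draws per line, summed per attribute.
Per-cell draws can go negative at CV = 1 and are used untruncated --
the estimator consumes only means and variances. The similarity
parameter $k \in [0,1)$ compresses the first row to
$[1000k, \dots, 1000]$ (equally spaced), making profiles more alike;
the CV sweep scales all SDs. Both sweeps show the expected monotone
degradation of $e$.

The generator does **not** emulate: profile drift between the profiling
phase and the mixture measurement (the dominant real-world failure
mode), non-Gaussian per-cell attributes, correlated attributes within a
cell, cell--cell interaction effects, or instrument background. Passing
tests therefore demonstrate correctness of the inference machinery
under the model's own assumptions, not robustness to violations of
them.

**A note on attainable accuracy.** With CV = 1 and ~500 cells per line,
a single aggregate draw carries limited information per component: the
marginal posterior SD on the 10-line equal mixture is ~60 cells (12%),
as a Laplace approximation of the exact likelihood confirms. The
composition-level error $e$ is nonetheless small (typically 0.02--0.05)
because component errors are strongly negatively correlated and
normalization cancels much of them. Per-component accuracy much tighter
than the posterior SD on a *single* mixture cannot be expected from any
estimator under these conditions; lines that are truly absent are
suppressed to near zero, but with a noisy aggregate they can absorb up
to ~10% of the largest component on unlucky draws.

## Numerical choices

* All likelihood arithmetic in log space; the sweep updates the
  per-attribute mean and variance vectors incrementally ($O(m)$ per
  component update) and recomputes them from scratch every 500 sweeps
  to cap accumulation of floating-point drift.
* The KDE is the exact kernel sum (chunked to bound memory), not a
  binned/FFT approximation.
* MAP grid ties break toward the smallest grid value; degenerate
  (all-equal) sample vectors return the common value with a warning
  instead of erroring, since a boundary-pinned component can produce
  them.
* `plugin_bandwidth()` refuses zero-variance samples (the rule would
  give $h = 0$); callers may substitute a floor.

## Problem sizes used by the test suite

Acceptance-level checks run the full defaults (5000 burn-in + 10000
retained sweeps, 2048-point KDE grid). Multi-run property tests --
similarity and CV sweeps, absent-line suppression, scale consistency,
the 10-replicate recovery check -- use 1000 + 2000 sweeps and a
1024-point grid so the whole suite stays in the minutes range; at these
sizes the sampler noise is small relative to the aggregate-observation
noise that dominates all of these properties.

## Limitations

* The CLT approximation degrades for lines with very few cells; the
  positivity floor $\epsilon_N$ is a numerical device, not a
  small-count correction.
* No convergence diagnostics beyond per-component acceptance rates are
  computed (no $\hat R$, no effective sample size); the test suite
  validates the chain against exhaustive grid posteriors on small
  problems instead.
* Interval summaries are empirical chain quantiles, provided as a
  convenience and labelled as such -- they are not density-based
  credible intervals.
* Profile drift between profiling and mixture measurement biases counts
  in proportion to the drift; the package diagnoses nothing here, it
  assumes the experimental design holds the attribute parameters fixed.
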