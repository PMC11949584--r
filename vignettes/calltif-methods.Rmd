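---
title: "Causal discovery from slowly sampled time series: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal discovery from slowly sampled time series: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calltif)
```

## The problem

Functional MRI samples brain activity slowly (a repetition time, TR, of
0.7–1.2 s) while the neural interactions of interest unfold over tens to
hundreds of milliseconds. Two consequences dominate causal structure
learning from such data. First, much of the causal signal collapses into
*contemporaneous* (lag-0) dependence: an influence faster than one TR looks
instantaneous. Second, cortical connectivity is rich in feedback: methods
that assume an acyclic contemporaneous structure discard exactly the
reciprocal (2-cycle) edges that tract tracing says are the most common.

`calltif` implements a constraint-based algorithm built for this regime. It
tests every lagged-source/contemporaneous-target pair with a partial
correlation conditioned on a *complete* set of lagged variables, keeps
cycles, orients lag-0 dependence with lagged evidence plus an explicit
reciprocity prior, and controls the per-edge type-I error across lags.

## The algorithm

Let $X_1(t), \dots, X_N(t)$ be the node series and $\tau_{\max}$ the
maximum lag. For every ordered pair $(i, j)$ and lag
$\tau \in \{0, \dots, \tau_{\max}\}$ the momentary conditional independence
(MCI) statistic is the sample partial correlation
$\rho\!\left(X_i(t-\tau),\, X_j(t) \mid Z\right)$ with

* $Z = \{X_k(t-s): s = 1..\tau_{\max}\} \setminus \{X_i(t-\tau)\}$ for
  $\tau \ge 1$ (the tested regressor is excluded from its own conditioning
  set; the target's own lags remain in $Z$), and
* $Z = \{X_k(t-s): s = 1..\tau_{\max}\}$ for $\tau = 0$ — conditioning sets
  contain lagged variables only, never contemporaneous ones.

The p-value is the two-sided t-test of $\rho = 0$ using
$t = \rho\sqrt{\mathrm{dof}/(1-\rho^2)}$ with
$\mathrm{dof} = n - |Z| - 2$. A lagged hit is directed
$X_i(t-\tau) \to X_j(t)$; a lag-0 hit is an undirected mark. There is no
PC-style parent-set search: with a complete conditioning set that step is
provably redundant and skipping it removes the main computational
bottleneck.

**Orientation.** Each lag-0 mark $\{i, j\}$ becomes: a reciprocal pair
$i \leftrightarrows j$ when no lagged edge connects the pair in either
direction (the reciprocity prior); the single lagged direction when lagged
edges run one way only; both directions when lagged edges run both ways.

**Summary graph.** The node-level digraph takes an OR across lags: edge
$i \to j$ iff some $\tau \ge 0$ contributed it. Lagged self-loops
($i \to i$, $\tau \ge 1$) pass straight through — damped autocorrelation
makes them part of the expected structure. Edge strength is the minimum
p-value over contributing lags; when a reciprocal lag-0 pair contributes,
the symmetric lag-0 p-value is shared by both directions (an
interpretation; the source description does not fix this detail).

## Correction for multiple comparisons across lags

The OR-collapse makes each summary edge the disjunction of
$\tau_{\max} + 1$ tests, so a per-edge type-I bound $\alpha$ requires a
smaller per-test level. Under a uniform prior on each per-lag null and
non-negative dependence of the nulls across lags, the per-edge error is
bounded by $\alpha_{\mathrm{level}} (\tau_{\max}+1) 2^{\tau_{\max}}$, so

$$\alpha_{\mathrm{level}} = \frac{\alpha}{(\tau_{\max}+1)\,2^{\tau_{\max}}}.$$

Only the resulting formula is implemented (`corrected_alpha()`); the prior
argument lives here and in the documentation, not in code. At
$\alpha = 0.01$, $\tau_{\max} = 3$ the per-test level is
$0.01/32 = 0.0003125$. This is *not* a family-wise correction across edges:
it bounds the error of each single edge decision. This bound is
conservative; on synthetic data with a known truth the threshold can
instead be set manually (`alpha_level`), which is also how the original
analysis tuned it on benchmarks.

```{r}
corrected_alpha(0.01, 3)
```

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `tau_max` | 3 | lags | suits TR ≈ 0.7 s; use 2 at TR = 1.2 s (slower sampling needs fewer lags) |
| `alpha_overall` | 0.01 | — | per-edge type-I bound fed to the correction |
| `alpha_level` | derived | — | manual override for ground-truth calibration |
| `standardize` | TRUE | — | z-score design columns; numerical conditioning only (tests are affine-invariant per column) |

## Numerical choices

* **Thresholding is strict** (`p < alpha_level`); a p-value exactly at the
  threshold is excluded.
* **Lagged tests via the precision matrix.** For each target the inverse
  covariance of (all lagged variables, target) yields every
  $\tau \ge 1$ partial correlation in one inversion. The test suite checks
  this route to within $10^{-8}$ against an independent ordinary
  least-squares coefficient t-test, and the lag-0 route against the
  residual-correlation test.
* **Rank deficiency** in a conditioning set drops redundant columns with a
  warning and adjusts the degrees of freedom; a singular joint covariance
  in the batched route falls back to explicit per-test residualisation.
* **Sessions never share lags.** The lagged design is built per session
  and stacked, so no design row mixes scans. Design columns are
  standardized globally after stacking: per-session z-scoring cannot give
  the stacked columns exactly unit variance (the pooled variance of
  per-block-unit-variance data is $\sum_k (n_k - 1)/(N-1)$), and the tests
  are invariant to the distinction anyway, so the globally exact convention
  was chosen.
* **Missing data fail fast**; the pipelines assume complete series.

## The synthetic-data generator

The generator emulates the simulated benchmark family used to validate
this class of algorithms: a signed ground-truth digraph $A$
($A_{ij} \ne 0 \Leftrightarrow i \to j$, negative self-decay on the
diagonal) drives linear neural dynamics
$\mathrm{d}z/\mathrm{d}t = \sigma A^{\mathsf T} z + C u$ (the transpose
reconciles the edge convention with the state-space convention) with
independent Poisson impulse inputs ($C = I$), passed through the nonlinear
Balloon–Windkessel hemodynamic model and sampled at the TR. Euler
integration at $dt = 10$ ms is deliberate: inputs are impulsive, the step
is small relative to all time constants, and the target is reproducible
desk-scale benchmarks, not hemodynamic fidelity.

Stated-world defaults, chosen once: hemodynamic constants follow the
standard DCM-lineage values ($\kappa = 0.65\,\mathrm{s}^{-1}$,
$\gamma = 0.41\,\mathrm{s}^{-1}$, $\tau = 0.98$ s, $\alpha = 0.32$,
$\rho = 0.34$, $V_0 = 0.02$, $k_1 = 7\rho$, $k_2 = 2$,
$k_3 = 2\rho - 0.2$); dynamics use $\sigma = 1$, Poisson rate 0.5
events/s/node, unit impulse amplitude, no measurement noise. The
continuous system is checked for stability (all eigenvalues of
$\sigma A$ in the left half-plane) at construction, and random graphs are
rejection-sampled until stable. These dynamics values are documented
stand-ins — the original benchmark's exact input statistics live in its
own source publication — and the `simulate` CLI manifest labels them as
such.

What a green recovery test establishes: that on stable, moderately dense
5-node systems with these hemodynamics the full pipeline recovers
adjacency far above density-matched chance. What it does not establish:
performance under measurement noise, subject variability, non-neural
physiological confounds, scanner drift, or at the 100+-node scale of real
parcellations; none of these are emulated.

A simpler VAR generator (`simulate_var()`) provides closed-form-checkable
fixtures: planted coefficients yield known lagged correlations
(Yule–Walker), and off-diagonal innovation covariance plants ground-truth
contemporaneous dependence.

## Evaluation metrics

Structure recovery is scored as binary classification: the *directed*
protocol over all $n^2$ ordered pairs including self-loops, and the
*adjacency* protocol over the $\binom{n}{2}$ unordered pairs after
collapsing both graphs to undirected. Per node,
$\mathrm{degree}_i = (\sum_j G_{ij} + \sum_j G_{ji})/N$ and
$\mathrm{flow}_i = (\sum_j G_{ij} - \sum_j G_{ji})/N$ (out minus in; net
source vs net sink; flows sum to zero by construction). Subnetwork
aggregation counts ordered cross-membership node pairs with an edge,
normalized by $|a||b|$ ($a \ne b$) or $|a|(|a|-1)$ (within — self-loops
excluded; the normalization for the diagonal case was genuinely open and
the pair-count reading was chosen and is tested). Functional graphs
threshold pairwise Pearson correlation at $p < \alpha$, uncorrected, as
literally specified. Per-lag contribution reports the percentage of
summary edges owed to exactly one lag.

## Known limitations

* Linear-Gaussian tests only; no rank or kernel CI tests.
* Lag-0 conditioning contains lagged variables only, so sub-TR chains and
  common drivers can leave spurious contemporaneous edges; the reciprocity
  prior then orients them both ways. This is a property of the method, and
  the structure-recovery margin in the acceptance suite is measured with
  it in place.
* The cross-lag correction is conservative (its prior terms are bounds),
  so corrected mode trades recall for per-edge error control.
* The simulator is a stated world, not a calibrated digital twin (see
  above).
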