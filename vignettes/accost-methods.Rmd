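---
title: "Methods: differential Hi-C contacts with distance-specific size factors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential Hi-C contacts with distance-specific size factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(accost)
```

## Model

Hi-C contact counts between bins $i$ and $j$ in replicate $k$ of condition
$\rho(k) \in \{A, B\}$ are modeled as negative binomial with

$$\mu_{ij}^k = \beta_i^k \beta_j^k \, s_{|i-j|}^k \, q_{ij}^{\rho(k)},
\qquad
(\sigma_{ij}^k)^2 = \mu_{ij}^k +
 \left(\beta_i^k \beta_j^k s_{|i-j|}^k\right)^2 v^{\rho(k)}(q_{ij}^{\rho(k)}).$$

The mean factorizes into locus-specific biases $\beta$, *distance-specific
size factors* $s_d$, and a normalized contact intensity $q$; the variance is
shot noise plus a smooth raw-variance function $v$ of the normalized
intensity. The distance-indexed size factors are the heart of the method:
they generalize the scalar library-size factors of count-based differential
expression so that the entire distance-decay profile of each experiment —
not just its depth — is absorbed into the normalization. Everything is
intra-chromosomal; all quantities are indexed by the bin distance
$d = |i-j|$, which is undefined across chromosomes, so chromosomes are
processed independently.

## Estimators

**Biases.** `estimate_ice_biases()` runs iterative proportional fitting until
the bias-corrected matrix has equal row sums over valid bins (relative
deviation below `tol`, default `1e-5`, at most `max_iter = 300` sweeps).
Bins with zero marginals, plus the lowest `low_count_fraction` (default 2%)
of marginals, are flagged invalid rather than silently set to 1; every pair
touching an invalid bin is reported untestable downstream with reason
`"filtered_bin"`. Biases are rescaled to unit geometric mean over valid
bins, so the $\beta/s$ factorization is identifiable and all depth and
scale information lives in $s$.

**Size factors.** For each distance $d$,
$\hat s_d = \mathrm{median}_{|i-j|=d}\; C_{ij}/(\hat\beta_i \hat\beta_j)$,
taken over *all* pairs at that distance whose bins are valid, counting pairs
with no stored entry as zeros. Including the structural zeros matters:
restricting to observed entries would inflate $\hat s_d$ at sparse long-range
distances. The consequence is that a distance where more than half the valid
pairs are empty gets $\hat s_d = 0$ and its pairs are reported untestable
(`"zero_size_factor"`) rather than tested against a fabricated scale. A
direct corollary — used as a correctness check in the test suite — is that
the per-distance median of the normalized counts
$\hat q_{ij} = C_{ij}/(\hat\beta_i\hat\beta_j\hat s_d)$ equals 1 (to
floating precision) wherever $\hat s_d > 0$.

**Raw variance.** With as little as one replicate per condition, the
variance cannot come from replicates; it is borrowed from same-distance
neighborhoods. For each pair, $N(i,j)$ is the set of all *other* valid pairs
at the same distance on the chromosome; the neighborhood mean $\hat t$ and
sample variance $\hat w$ (divisor $m_A |N| - 1$) are computed over the
condition's replicates, pairs absent from a replicate's sparsity pattern
contributing $\hat q = 0$ (absence is an observed zero, not missing data).
Subtracting the expected shot-noise term

$$\hat z_{ij} = \frac{\hat q^A_{ij}}{m_A |N(i,j)|}
 \sum_{k \in M(A)} \sum_{(u,v) \in N(i,j)}
 \frac{1}{\hat\beta_u^k \hat\beta_v^k \hat s_{|u-v|}^k}$$

gives $E[\hat w - \hat z] = v(q)$ under the model, assuming the
normalization factors are exact. `fit_variance_function()` then regresses
$\log(\hat w - \hat z)$ on a polynomial in $\log \hat q$ (default degree 2)
over the pairs with positive $\hat w - \hat z$; nonpositive values are rare
and excluded from the regression only — the pairs themselves are still
tested, with their variance taken from the fitted curve.

Two choices here were genuinely open. First, the regression space: we fit
the *logarithm* of $\hat w - \hat z$ rather than the raw difference. Raw
variances span several orders of magnitude across distances, and a
linear-response fit lets the largest values dominate the least squares; on
simulated negative-binomial data with a known quadratic raw variance the
log-response fit recovers the planted coefficient more accurately than the
linear-response alternative, so the log–log fit is the default. Second,
evaluation outside the observed range of $\log \hat q$ clamps to the
boundary value: a quadratic in log space explodes when extrapolated, and a
flat extension is the conservative choice. By convention $v(0) = 0$ — a
pair with zero expected intensity has no raw variance.

**Degenerate inputs.** If fewer than `degree + 2` positive raw-variance
points survive (tiny matrices, or data with essentially no overdispersion),
the pipeline warns and falls back to the pure shot-noise limit $v \equiv 0$
rather than failing: the Poisson limit is the correct boundary of the model.

## The test

Under the null $q^A_{ij} = q^B_{ij}$, the pooled normalized count
$\hat q^0_{ij}$ (mean over all $m$ replicates) yields per-condition null
moments

$$\hat\mu^A = \sum_{k \in M(A)} \hat\beta_i^k \hat\beta_j^k \hat s_d^k\,
 \hat q^0, \qquad
(\hat\sigma^A)^2 = \hat\mu^A + \sum_{k \in M(A)}
 (\hat\beta_i^k \hat\beta_j^k \hat s_d^k)^2\, \hat v^A(\hat q^0),$$

and the pooled counts are approximated by negative binomials matched to
those moments ($\hat\sigma^2 \ge \hat\mu$ holds by construction since
$\hat v \ge 0$; the pipeline asserts it). The p-value conditions on the
total $C = C^A + C^B$ and sums the probabilities of all splits no more
likely than the observed one, ties included, so $p > 0$ always and the test
is conservative rather than anti-conservative at ties. Enumeration is exact
($O(C)$ per pair, totals in the thousands are cheap) and carried out in log
space with a sorted log-sum-exp, which makes p-values bit-identical under
exchange of the condition labels. Tie comparison uses a relative tolerance
of $10^{-7}$ on the probability scale — the same convention as
`stats::binom.test` — so analytically exact ties are not lost to floating
point. When the variance does not exceed the mean (relative tolerance
$10^{-8}$) the Poisson branch is used for numerical stability; a zero mean
is a point mass at zero, and a pair where both null means are zero but
counts were observed is reported with $p = 1$ and flagged. Pairs with pooled
total below `min_count` (default 1, i.e. all-zero pairs) are untestable
(`"low_count"`) and excluded from the Benjamini–Hochberg denominator, as is
the matrix diagonal by default (self-ligation artifacts; set
`include_diagonal = TRUE` to keep it).

## The simulator

`simulate_null_experiment()` reproduces the null-calibration design used
throughout the tests: two conditions whose generation means decay as a
power law of distance, $\mathrm{mean}(d) = \max(a\, d^{-\gamma},
\mathrm{floor})$, anchored at neighboring-bin means $a$ of 1000 (condition
A) and 1500 (condition B) by default, exponent $\gamma = 1$, floor
$10^{-2}$, 500 bins, one replicate per condition, independent Poisson
counts, no position-specific biases. The power law is the canonical form of
the Hi-C distance effect; the anchors are the stated study conditions and
the exponent and floor are fixed defaults, chosen once. Poisson rather than
negative-binomial sampling makes the null *harder* for this method (no
overdispersion to absorb misfit). Under this design the two experiments
differ only in their distance decay, so any detection is a false positive.
An optional `spike_spec()` multiplies selected generation means in one
condition before sampling, for power studies; `dist = "nb"` draws negative
binomial counts with variance $\mu + \phi\mu^2$, which corresponds exactly
to the model with $\beta \equiv 1$, $s_d = \mathrm{mean}(d)$ and
$v(q) = \phi q^2$ — this is how the variance-recovery tests plant a known
$v$. A master seed deterministically derives per-matrix child seeds; the
whole experiment set is a pure function of its parameters and the seed.

What the simulator does *not* emulate: position-specific biases are off by
default (available via `biases =`), and there is no domain/compartment/loop
structure — the true intensity at a distance is constant across positions.
Passing null-calibration tests on these data therefore demonstrates
distance-effect handling, not robustness to structured biological variation.

## Known limitations

Three properties surfaced by the simulations are worth stating plainly,
because they are properties of the estimators as defined, not of this
implementation (the test suite demonstrates each one):

* **Discreteness at low counts.** An exact conditional test with ties
  included has an atom at $p = 1$ equal to the probability of the modal
  split. With power-law decay most long-range pairs have small pooled
  totals, so genome-wide p-value distributions on sparse data are markedly
  super-uniform (valid but conservative): $P(p \le \alpha) \le \alpha$
  holds at every level — the pipeline tests assert this — but a
  Kolmogorov–Smirnov statistic against the uniform remains large no matter
  how many pairs are tested. Significant calls at long range are also
  asymmetric in fold change when the two libraries differ in scale, because
  the rarer tail of the split distribution reaches smaller p-values.
* **Balancing edge effects.** ICE equalizes row sums; on a matrix whose
  true means depend only on distance, end-of-chromosome bins have smaller
  marginals and receive genuinely non-uniform biases. The normalized counts
  at a fixed distance then vary systematically with position, which the
  neighborhood variance $\hat w$ absorbs into $\hat v$, inflating the null
  variance (and making the test more conservative) precisely when the data
  carry no locus biases at all. In the per-pair null mean this cancels —
  $\hat\beta$ enters both $\hat\mu$ and $\hat q^0$ — but in the variance it
  does not.
* **Errors in variables at small $\hat q$.** The regression covariate is
  the pair's own noisy $\hat q$, and $\hat z \propto \hat q$: conditioned
  on a small observed $\hat q$, $\hat w - \hat z$ is biased upward, so the
  fitted $v$ rises toward the low-$q$ edge of the fit domain. At deeply
  sparse pairs this can push the moment-matched negative binomial below
  size 1 (a log-convex pmf), where the even split of a total is no longer
  its mode — so even two literally identical replicates labeled A and B can
  receive $p < 1$ at a handful of low-count pairs. At moderate counts the
  even split is modal and such contrasts give $p = 1$ everywhere.

## Problem sizes

The test suite exercises hand-checkable fixtures (up to $8 \times 8$)
against brute-force oracles, module-level simulations at 60–300 bins, and
the full 500-bin calibration scenario; these sizes give stable Monte-Carlo
estimates for every property asserted while keeping the default test run
fast. A 500-bin, two-replicate end-to-end analysis runs in roughly ten
seconds on one core; memory grows as dense $n \times n$ doubles per
replicate, comfortable for per-chromosome matrices up to a few thousand
bins at typical resolutions.
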