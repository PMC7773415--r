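---
title: "Autogenerating polynomial models of muscle kinematics: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Autogenerating polynomial models of muscle kinematics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Musculoskeletal simulations need the musculotendon length $L(x)$ and the
moment arm $M_i(x)$ about every actuated degree of freedom (DOF) as functions
of the joint posture $x = (x_1, \dots, x_d)^T$ (radians). Computing these from
a full geometric model (muscle paths wrapping over bones and other tissues) is
far too slow for real-time use, so surrogate models are fitted to values
sampled on a posture grid. `musclepoly` builds such surrogates as sparse
multivariate polynomials whose *structure* — the set of terms present — is
selected automatically, instead of being chosen by hand per muscle.

## Model form and K-notation

A model is

$$ f(x) = a + \sum_{p=1}^{\rho} \; \sum_{i_1 \le i_2 \le \dots \le i_p}
   K_{i_1 i_2 \dots i_p} \prod_{j=1}^{p} x_{i_j}, $$

an intercept plus monomials identified by the sorted multiset of variable
indices: $x_1^2 x_2$ is the term `K112`. Sorting makes the key canonical, so a
structure is literally a set of keys, e.g. `(a, K1, K122, K1111)`. The maximum
power is $\rho = 5$ for length and $\rho = 4$ for moment arms, so that the
derivative of the length polynomial stays inside the moment-arm space.
Coefficients are in millimetres; the full $d$-variable space of power $\rho$
has $\binom{d+\rho}{\rho}$ terms (462 at $d = 6$, $\rho = 5$).

## Term selection under AICc

Fitting a fixed structure is linear least squares. Structure search is forward
stepwise: starting from the zero model, each function (the length and every
moment arm, fitted independently) evaluates all single-term expansions and
accepts the one with the smallest corrected Akaike Information Criterion,

$$ \mathrm{AICc} = 2k + 2N\ln\sigma + \frac{2k(k+1)}{N-k-1}, $$

where $k$ counts coefficients (intercept included), $N$ is the number of grid
points and $\sigma$ is the RMS residual of *normalized* data: lengths are
divided by the length range over the fitting grid and each moment arm by its
maximum magnitude, so the same trade-off scale applies to every function. A
function freezes when its best candidate no longer lowers its accepted AICc;
the search ends when all functions are frozen. Ties between candidates are
broken toward the lowest-degree, lexicographically smallest term, which makes
the search deterministic and biased toward simple structures.

Two deliberate refinements:

* **Perfect-fit sentinel.** $\sigma = 0$ maps to $-\infty$, so an exact fit
  wins any comparison and stops further growth. Numerically, $\sigma$ below
  $10^{-9}$ of the RMS of the target is snapped to zero; near-perfect fits
  recompute the residual from the raw design matrix because the precomputed
  normal-equation form cancels catastrophically there.
* **Backward cleanup.** A greedy forward step can pick a proxy term that later
  additions make exactly redundant (its coefficient becomes zero). After the
  forward phase freezes, terms whose removal does not worsen AICc are removed.
  This is AICc-consistent — $k$ drops while $\sigma$ is unchanged — and it is
  what makes structure recovery exact on noiseless data.

## The differential constraint

With moment arms defined as partial derivatives of length,
$M_i = \partial L / \partial x_i$ (the sign convention is adopted exactly as
stated; no minus sign), independent fits of $L$ and $\{M_i\}$ are mutually
inconsistent. The constraint step restores consistency at the structure level:

1. integrate each moment-arm structure over its own DOF (term-wise
   antiderivative plus a free constant);
2. union those antiderivative structures into the length structure;
3. re-derive every moment-arm structure as the analytic derivative of the new
   length structure;
4. refit all coefficient sets independently by least squares on the original
   data.

In `constrained` mode this runs every iteration (and interleaved with the
backward cleanup until a fixed point), so the returned model always satisfies
$\mathrm{structure}(M_i) = \mathrm{structure}(\partial L/\partial x_i)$.
Coefficients of $L$ and $M_i$ are *not* shared — each function keeps its own
least-squares solution; the constraint couples structures, not values. Whether
the final refit should instead estimate length and moment-arm coefficients
jointly is an open modelling question; the independent refit was chosen
because it keeps every fit a plain linear problem and treats the measured
moment arms as first-class data.

## Grids and the synthetic geometry oracle

Fitting uses a uniform 9-point grid per DOF including both range-of-motion
endpoints ($9^d$ postures per muscle); validation uses the 8-point grid of
midpoints between adjacent fitting nodes, strictly interior to the ROM.

The package replaces the upstream geometric model with a synthetic oracle:
each muscle is a random sparse polynomial length function (degree $\le 5$)
whose moment arms are its analytic derivatives, so the ground truth satisfies
the differential constraint by construction. Defaults emulate gross muscle
anatomy: intercepts of 120–350 mm, coefficient magnitudes of 4–20 mm halved
per extra degree (smooth paths are dominated by low-order posture
dependence). An optional sinusoidal perturbation (amplitude in mm) makes the
geometry non-polynomial to exercise the approximation regime rather than
exact recovery.

What the oracle does *not* emulate: wrapping-surface discontinuities, via
points, measurement noise structure, or correlations between muscles. Passing
tests therefore demonstrate correctness of the selection machinery and its
statistical behaviour, not fidelity to any particular anatomical dataset.

### The 33-muscle arm fixture

The packaged fixture mirrors an 18-DOF forearm/hand model with 33
musculotendon actuators in seven functional categories (wrist supinators,
pronators, wrist extensors and flexors, finger flexors and extensors, thumb
muscles). The DOF-count distribution across muscles — (5, 7, 7, 12, 1, 1)
muscles spanning 1 to 6 DOFs — is the unique integer solution that makes the
combined fitting grids total 674,937 postures, the test grids 348,136, and
the 10-set perturbation design 3,481,360 length and 19,450,000 moment-arm
samples, matching the dimensions of the reference arm model this fixture
stands in for. Named-muscle DOF assignments follow standard anatomy (e.g.
ECU spans the two wrist DOFs; FPL, the most complex, spans six). Fixture term
counts grow at about 7 per DOF. All fixture files are explicitly synthetic.

## Validation metrics

* Normalized RMS error, in percent of the per-quantity normalizer.
* Chebyshev outlier screen: errors above
  $\mathrm{MEE} = \bar\varepsilon + \sigma/\alpha$ are flagged. With
  $\alpha = 0.1$ the threshold sits 10 standard deviations out, i.e. outside
  99% of any distribution by Chebyshev's inequality — appropriate because
  approximation-error populations are heavy-tailed, not normal.
* Complexity regression: selected term count against DOF count, linear and
  free two-parameter exponential fits, with residual outliers removed by
  Tukey's rule (above median + 1.5 IQR for either fit) before the final fit.
  A relative complexity (terms as a share of the full parameter space) is
  also provided.

## Muscle invariants and structural statistics

The similarity index between two structures is the shared-term fraction
$\mathrm{SI} = 100\, N_C / (N_{ANC} + N_{BNC} + N_C)$. For analyses that must
ignore *which* DOFs a muscle actuates, each length polynomial maps to an
18-dimensional unit vector: absolute coefficients summed by the power
signature of each term (the multiset of per-variable exponents; 18 distinct
signatures exist up to power 5, the integer partitions of 1..5).

Two orderings of those 18 axes are in circulation: a degree-sorted table
ordering and the ordering under which the worked example
$L = C_1 x_1 x_2^2 + C_2 x_1^2 x_2 + C_3 x_1^3 + C_4 x_1 + C_5 x_2 + C_6$
loads exactly $v_9$, $v_{12}$ and $v_{16}$. They conflict; `musclepoly`
follows the latter as the default (`invariant_axes("invariant")`) because the
worked example pins it down, and exposes the table ordering as an explicit
alternative rather than reconciling the two silently.

Invariant vectors are compared by Euclidean distance, clustered with
average-linkage hierarchical clustering, and projected on principal
components. Two hypothesis tests are built on muscle pairs:

* *Shared DOF*: per DOF, pairs both actuating it versus pairs with exactly
  one actuating muscle. Pairs are selected once per DOF, so a pair can
  legitimately recur at another shared DOF — the counting rule is therefore
  per-DOF, not global, and phalangeal MCP/PIP/DIP joints are pooled across
  fingers 2–5 (kept distinct from each other and from the thumb). The exact
  de-duplication rule is under-specified in general; the incidence table is
  an explicit argument so alternative poolings can be supplied.
* *Shared function*: restricted to pairs sharing a DOF, split by functional
  category within each (DOF, category) cell; cells with fewer than two
  members are skipped with a message.

The difference population subtracts from each "with" pair distance every
"without" pair distance that shares exactly one muscle with it. Group
normality is screened with an in-package D'Agostino K-squared test (no
installed package provides it; the implementation follows the standard
skewness and kurtosis transforms and is cross-checked against an independent
implementation in the tests). Group separation uses a one-tailed
Mann-Whitney U test and the median of the difference population a one-sided
sign test (robust to asymmetry), both at $\alpha = 0.01$.

## Hill-type force model and noise propagation

Isometric force is
$F = u\,F_{max}\,F_a(L) + 0.1\,F_{max}\,F_P(L)$ with
$F_a = 2.5\,L_{norm} - 1.25\,L_{norm}^2$ and an exponential passive term that
engages above the slack length $L_{pass} = 0.9\,L_{max}$; torque about each
DOF is moment arm times force. Activation defaults to $u = 1$.

The perturbation experiment draws, for every posture of the test grid, 10
noisy samples of length and moment arms. "Centered on the reference posture"
is read as noise added to the reference kinematic *values* (not the angles):
the noise is expressed in percent of ROM and the moment-arm channel carries a
10× multiplier, which only makes sense on the value scale. Length samples are
clamped into the physiological length range (muscle excursion is bounded);
moment-arm noise is not clamped (moment arms are not). The moment-arm noise
SD is scaled per DOF by that DOF's maximum moment-arm magnitude — a
muscle-global maximum was the alternative; per-DOF was chosen so that a weak
DOF is not swamped by noise calibrated to a strong one. Errors are normalized
to the range of the corresponding reference force or torque for that muscle
and pooled; reported per level as mean and IQR. Levels default to 0.1, 1, 10
and 20% of ROM.

## Degenerate inputs and numerical choices

* Constant-length muscles: the length range is zero, so the normalizer falls
  back to the length magnitude; the fit correctly returns an intercept-only
  structure.
* Identically zero moment arms: the zero model is already exact; the function
  freezes with an empty structure (a zero polynomial).
* Rank-deficient designs (possible on degenerate grids) fall back to the
  minimum-norm solution with a warning.
* Candidate fits run on precomputed Gram matrices with unit-RMS column
  scaling, so each candidate costs one small dense solve; the design matrix
  is built in blocks for large grids.
* Integration that would exceed power 5 drops the offending term with a
  warning; with moment arms capped at power 4 this cannot trigger in normal
  operation.

## Problem sizes used by the tests

The test-suite fits use 9-point grids at $d \le 4$ (up to 6,561 postures) and
fixture subsets of a few muscles for the clustering, scaling and perturbation
properties; these sizes were chosen as the smallest that exercise every code
path with comfortable statistical margins. The acceptance script's quantities
are all desk-scale (combinatorial counts and closed-form evaluations) and run
in seconds.

## Known limitations

* Polynomial bases only; periodic or sigmoidal kinematics would be better
  served by trigonometric or exponential terms, which are out of scope.
* One term is added per function per iteration; simultaneous multi-term
  addition is not implemented.
* The synthetic fixture reproduces the *dimensions* of the reference arm
  model, not its muscle geometry, so published error tables, dendrogram
  orderings and test statistics that depend on that geometry are not
  reproduced — the corresponding behaviour is validated by construction-based
  properties instead.
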