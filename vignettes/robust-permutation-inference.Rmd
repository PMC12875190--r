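---
title: "Robust paired-permutation inference for linear models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust paired-permutation inference for linear models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpalmrt)
```

## The testing problem

Biological assays routinely produce responses whose noise is heavy-tailed or
strongly skewed — cell-type proportions, abundances, concentrations.  For
the partial-correlation model

$$Y = X\beta + Z\theta + \varepsilon,$$

with a covariate of interest $X$ ($n \times d$, usually $d = 1$) and control
covariates $Z$ ($n \times p$, including an intercept), the classical F-test
of $H_0\colon \beta = 0$ leans on normality and can wildly over-reject at
small nominal levels when the noise is Cauchy-like or log-normal.  rpalmrt
implements a paired-permutation framework whose only distributional
assumption is that the entries of $\varepsilon$ are *exchangeable*, plus
linearity in $Z$; no moments of $\varepsilon$ need exist.

The construction: draw permutations $\pi_1,\dots,\pi_B$ i.i.d. uniformly
from the symmetric group (with replacement — the exchangeability argument
needs i.i.d. draws, so there is no de-duplication and the identity may occur
by chance).  For each $\pi$, fit the two augmented models

$$Y \sim X + Z + Z_\pi \qquad\text{and}\qquad Y \sim X_\pi + Z + Z_\pi,$$

where $A_\pi$ permutes rows.  The permuted control block $Z_\pi$ gives the
permuted covariate $X_\pi$ the same "help" the original $X$ gets, making the
comparison fair.  A model-fitting algorithm $\mathcal{M}$ produces a summary
of each fit and an evaluation function $\omega$ (smaller = better) scores
it; with $\omega^{\mathrm{Orig}}_b$ and $\omega^{\mathrm{Perm}}_b$ the two
scores at $\pi_b$,

$$\text{p-value} \;=\; \frac{1 + \#\{b\colon \omega^{\mathrm{Orig}}_b \ge
\omega^{\mathrm{Perm}}_b\}}{1 + B}.$$

Ties count toward the numerator (exact floating-point equality, no
tolerance — the conservative direction), and the p-value can never drop
below $1/(B+1)$.

Provided $\mathcal{M}$ satisfies two explicitly checkable conditions —
*shift invariance* (its output is unchanged when $Y$ is shifted by any
vector in the span of $[Z, Z_\pi]$) and *row symmetry* (unchanged under a
joint permutation of the rows of $(Y, X, [Z, Z_\pi])$) — the test has
finite-sample type I error at most $2\alpha$ when run at level $\alpha$,
for every $\theta$ and every exchangeable error law.  In simulations the
nominal $\alpha$ itself is respected by all shipped fitters, with
considerable slack.  `verify_fitter()` ships the two condition checks as a
public utility (random shifts $\gamma$ and permutations $\sigma$, 20 draws,
absolute tolerance $10^{-6}$) so custom fitters can be certified before
their p-values are trusted.

## Fitters: separating fitting from evaluation

The framework deliberately decouples *how the model is fitted* from *how a
fit is judged*.  Shipped fitters produce a `fit_summary`: a frozen scale
estimate plus the residuals stored as order statistics (sorting is the
concrete device that makes row symmetry hold mechanically).

**OLS** (`palmrt_fitter("ols")`) — projection residuals.  Rank-deficient
designs fall back to the pseudo-inverse, so residuals depend only on the
design's column span; this is what makes shift invariance exact.

**Huber with preliminary-regression scale** (`palmrt_fitter("huber")`) —
the workhorse for heavy tails.  M-estimation needs a scale, and estimating
it per-model would make the two members of a permutation pair incomparable
(they would optimise different losses).  Instead:

1. a *preliminary* robust regression of $Y$ on $[Z, Z_\pi]$ alone —
   initialised at OLS, with a fixed number (two) of MAD re-estimation
   stages, each followed by a fully converged fixed-scale Huber fit;
2. the scale $\hat s$ is frozen as the MAD of the final preliminary
   residuals;
3. a fixed-scale Huber fit of $Y$ on $[X, Z, Z_\pi]$ (and on
   $[X_\pi, Z, Z_\pi]$) with that shared $\hat s$.

Because $\hat s$ depends only on $(Y, [Z, Z_\pi])$, it is identical for the
original and permuted fits of a pair, and it is valid under $H_0$.  Under
the alternative it *over*-estimates the scale, pushing more residuals into
the quadratic core of the loss — which helps rather than hurts power.  A
zero MAD (the response is essentially inside the control span) aborts with
a `rpalmrt_degenerate_scale` error rather than substituting a floor: a
silent floor would silently change every score.

**Quantile** (`palmrt_fitter("quantile", q = )`) — check-loss residuals via
the deterministic Barrodale–Roberts simplex (`quantreg::rq.fit.br`); its
fixed pivoting convention resolves non-unique minimisers reproducibly and
shift-invariantly.

**Evaluators.**  `"l2"` ($\sum r_i^2$), `"l1"` ($\sum|r_i|$) and `"huber"`
($\sum\rho_\delta(r_i/\hat s)$, the scaled Huber norm, requiring a
scale-aware fitter).  The paper-style method names compose the two:
OLS-L2 is the classical augmented-pair test, Huber-Huber is the robust
default.  A key empirical finding reproduced by the study harness below:
moving from L2 to Huber *evaluation* recovers much of the robustness
benefit even when the model is still fitted by OLS (for OLS fitters the
evaluation scale is the MAD of the preliminary OLS residuals of
$Y \sim Z + Z_\pi$, shared by the pair — our reading of an
under-specified detail, flagged here).

### Tuning constants

| constant | default | meaning |
|---|---|---|
| `delta` | 1.345 | Huber corner, in units of the (normal-consistent) scale; 95% efficiency at the normal |
| `mad_constant` | 1.4826 | MAD consistency factor for the normal; set 1 for the raw MAD (`delta` is calibrated for the consistent scale, so the default matches standard robust-regression practice) |
| `max_iter` | 100 | cap on the IRLS phase of each fixed-scale fit; hitting it is recorded, not an error — the Newton polish below still lands on the minimiser |
| `tol` | 1e-9 | IRLS stopping tolerance, measured on the residual vector |

The numerical design of the Huber machinery is where most of the care in
this package went, because the validity argument leans on *exact*
invariances that floating point happily destroys.  Four choices matter.

*Residual-based stopping.*  IRLS convergence is declared on the relative
change of the residual vector, not the raw coefficients: the residuals
are the shift-invariant image of the coefficient step, so shifted and
unshifted runs of the same problem stop at the same iteration.  A
coefficient-normalised rule measurably breaks certification at $10^{-6}$.

*A fixed number of scale stages.*  The folklore scheme — alternate
"re-estimate the MAD, refit" until it settles — has a fixed-point equation
$s = \mathrm{MAD}(r(s))$ that can possess several solutions; the
alternation can cycle between them or converge arbitrarily slowly, and a
convergence-triggered exit then makes the output chaotically sensitive to
round-off (mathematically equivalent replays of one problem were observed
to disagree by whole percent).  The preliminary fit therefore performs a
fixed number of stages (two MAD updates, each followed by a fully
converged fixed-scale fit): a composition of finitely many numerically
stable maps, exactly equivariant step by step.

*A Newton polish.*  The fixed-scale Huber objective is convex and
piecewise quadratic, but plain IRLS can stall $10^{-4}$ away from the
minimiser in nearly flat valleys, at a spot that depends on row order.
Every fixed-scale fit therefore ends with a few semismooth-Newton steps
with an exact line search, guarded so that round-off-level "descent"
directions are never chased (doing so can walk the iterate off the
residual manifold entirely).

*Full-rank reduction.*  The augmented controls $[Z, Z_\pi]$ always contain
an exactly duplicated intercept column.  A Cholesky factorisation of the
resulting near-singular normal equations can numerically "succeed" while
returning huge null-direction coefficients whose cancellation pollutes the
residuals at the $10^{-3}$ level; all designs are therefore reduced to a
pivoted full-column-rank basis before solving — the fits depend on the
design only through its span, which the reduction preserves.

With all four in place the certification suite measures worst
shift-invariance and row-symmetry discrepancies near $10^{-7}$ over
thousands of random instances, against a tolerance of $10^{-6}$.

## DispersionPALMRT

For a binary case/control covariate the same machinery tests a *dispersion*
difference: per permutation, quantile regressions of $Y$ on
$[X, Z, Z_\pi]$ at $q_{\mathrm{low}} = 0.10$ and $q_{\mathrm{high}} = 0.90$
give each subject a fitted conditional 80% inter-quantile spread
$\hat y^{(0.9)}_i - \hat y^{(0.1)}_i$, and

$$\omega = -\log\frac{\text{mean spread among cases}}
{\text{mean spread among controls}},$$

computed once grouping by $X$ and once by $X_\pi$ (four quantile fits per
permutation).  Conventions we fixed where the source formula is ambiguous:
the per-subject spread is written so group means are positive (the raw
residual difference has negative sign); subjects are paired by index across
the two quantile fits (the group summaries are means, so pairing order
statistics instead would give identical results); and the test is
one-sided for *increased* case dispersion, as the sign of $\omega$
dictates — a two-sided variant ($-|\log\text{ratio}|$) sits behind
`two_sided = TRUE`.

One caveat inherited from linear programming: when $nq$ is an integer the
check-loss optimum can be non-unique, and although every optimal vertex has
the same loss, the solver's vertex choice depends on row order.  On such
knife-edge instances the grouped spreads can differ in the third decimal
under a joint row permutation; the paired comparison is unaffected except
on exact ties.  In simulations the test is strongly conservative (empirical
size well below $\alpha/2$ at $n = 100$), consistent with its design.

## Confidence intervals by test inversion

`invert_ci()` retains every candidate $\beta^\star$ for which the test on
$Y - X\beta^\star$ fails to reject at level $\alpha$; coverage is
guaranteed at least $100(1 - 2\alpha)\%$.  One permutation set is reused at
every grid point, making the p-value profile stable in $\beta^\star$ and
the interval reproducible.  The default grid is 401 equally spaced points
across the OLS estimate $\pm 10$ standard errors (user-overridable).
Because the acceptance region need not be an interval, the reported
endpoints are the convex hull of the retained grid points and the full
p-value profile is returned so disconnected regions can be detected.  An
all-rejected grid returns an empty-interval flag with the profile, not an
error.

## Classical baselines

`partial_f_test()` is the nested-model F-test ($(d, n-d-p)$ degrees of
freedom).  `koenker_bp_test()` regresses squared OLS residuals on auxiliary
regressors and refers Koenker's studentized $nR^2$ to $\chi^2$.  The
auxiliary set defaults to $X$ plus an intercept — the dispersion model
places heteroskedasticity in $X$ — with `aux = "xz"` available.  Both
guard exact-degenerate inputs (residual sums at projection round-off,
constant squared residuals) by returning the no-evidence p-value 1; these
guards only engage below $\sim 10^{-10}$ relative variation.

## The simulation harness and what it does (not) show

`gen_design()` draws $[X, Z]$ i.i.d. Cauchy(0,1) apart from the intercept —
deliberately brutal leverage; normal, $t_3$ and balanced $\pm 1$ designs
are available.  `gen_errors()` covers normal, $t_3$, Cauchy, log-normal
(`exp` of a standard normal) and the multinomial+normal outlier model:
$n-1$ standard normals with one uniformly chosen entry at
$N(\pm 10^4, 1)$, the sign a fair coin per replicate.  Location responses
use $\theta = 0$ without loss of generality — the package proves its own
shift invariance, and a nonzero-$\theta$ smoke test guards regressions.
Dispersion responses follow $Y_i = Z_i^\top\theta + (1 + \beta X_i)\varepsilon_i$
with a balanced binary allocation ($n_1 = n/2$, our recorded default where
the source is silent).

`calibrate_beta()` finds the effect size at which the partial F-test
attains a target power, by bisection with common random numbers: one set
of replicates is drawn once, and since the F statistic depends on the data
only through $\|(I-P_Z)\varepsilon\|^2$, $\langle (I-P_Z)\varepsilon,
(I-P_Z)X\rangle$ and $\|(I-P_Z)X\|^2$, the power at any $\beta$ is a
closed-form function of three precomputed sums per replicate — each
bisection step is essentially free.  Default: 2000 replicates per
evaluation, power tolerance 0.02.

`run_study()` executes scenario grids with per-replicate seeds derived from
one master seed, so results are reproducible and independent of worker
scheduling; replicate failures are tolerated up to 1% and counted.

The package's own test suite runs a scaled-down study — 500 replicates and
$B = 199$ per cell at $n = 100$, $p = 6$ (the headline conditions use 1000
replicates and $B = 999$) — chosen to keep Monte-Carlo standard errors
($\approx 0.01$ for a size of 0.05) well inside the margins being tested.
What passing shows: finite-sample size control under all five error laws,
strong conservatism of the dispersion test, calibration fidelity, and the
robust-evaluation power ordering under Cauchy noise.  What it does not
show: behaviour under *non-exchangeable* noise (correlated errors,
unmodelled heteroskedasticity under the location null) — the theory's one
real assumption — nor performance on real mixtures like cohort data, where
exchangeability must be argued scientifically, not verified numerically.

## Known limitations

- $Z$ must be of modest dimension; there is no high-dimensional control
  support, no multivariate response, and no built-in multiplicity
  correction across responses.
- The p-value floor $1/(B+1)$ caps attainable significance; choose $B$
  accordingly.
- The guarantee is $2\alpha$; the observed size is typically below
  $\alpha$, i.e. the test (and especially the dispersion variant) is
  conservative and could in principle be recalibrated.
- Quantile-fit vertex non-uniqueness at integer $nq$ (above) perturbs exact
  row symmetry on a measure-zero-in-practice set of instances.
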