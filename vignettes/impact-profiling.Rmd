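---
title: "Need and impact profiling: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Need and impact profiling: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollmatch)
```

## The two questions

Targeting a nutrition intervention raises two distinct questions.  *Who
lacks child dietary diversity?* is a question about **need**: it asks which
observable household profiles concentrate the children whose 24-hour diet
spans too few food groups.  *Who would benefit most from restoring
diversity?* is a question about **impact**: even among equally needy
groups, the effect of fixing the diet on a downstream outcome such as
stunting can differ sharply with agro-ecological and socio-economic
context.  `pollmatch` answers the first question with a fully
non-parametric polling engine and the second by attaching a matching-based
treatment-effect estimate to every enumerated profile.  Throughout,
"treated" means *having inadequate diet diversity* (`diet_class = 1`), so
an estimated positive effect on stunting is the harm that an intervention
restoring diversity could remove.

## Polling: profiles, coverage and the two errors

A *profile* fixes a subset of integer-coded covariates at specific values
(for example: rural, mother not working, poorest wealth quintile).  For a
profile $x$ and the relevant group $g$ (the inadequately-fed children),
with observation masses $w_s$:

* **coverage** $= m_{gx} / \sum_x m_{gx}$ — the share of the group's total
  mass captured by the profile;
* **exclusion error** $\lambda = 1 - \text{coverage}$ — needy mass the
  profile misses;
* **inclusion error** $\mu = 1 - m_{gx} / \sum_g m_{gx}$ — profile mass
  that is not needy;
* **indicator** $\psi = \lambda^\alpha \mu^{1-\alpha}$, a weighted
  geometric mean with $\alpha \in [0,1]$ weighting exclusion against
  inclusion.  We take $0^0 = 1$, so a perfect profile scores $\psi = 0$
  even at the boundary values of $\alpha$.

The engine enumerates *every* value assignment of *every* $k$-subset of the
candidate covariates (252 variable subsets for 10 candidates with
$k = 5$), tabulating masses per subset so that universes of tens of
thousands of profiles remain fast.  The winning profile per $\alpha$
minimizes $\psi$; exact ties are all reported, with the lexicographically
smallest profile key as the deterministic primary pick.  Zero-mass
profiles have an undefined inclusion error and are excluded from ranking
but kept in the metrics table.

## From need to impact

Let $ATT(x)$ be the average treatment effect on the treated within profile
$x$, $\Pr[\text{treated} \mid x]$ the treated mass share inside the
profile, and $\Pr[x]$ the profile's population mass share.  The expected
population-level gain from treating profile $x$ is

$$\text{impact}(x) = ATT(x) \times \Pr[\text{treated} \mid x] \times \Pr[x],$$

and $ATE(x) = ATT(x)\Pr[\text{treated} \mid x]$.  Impact coverage divides
a profile's impact by the total across the profile universe.  Because
profiles overlap — one household can satisfy many profiles — the plain sum
double-counts; the overlap-adjusted denominator divides each household's
weight by the number of universe profiles containing it, which reduces
exactly to the plain sum when profiles are pairwise disjoint (asserted in
the test suite).  The impact exclusion error is
$\lambda_{\text{impact}} = 1 - \text{impact coverage}$ and the inclusion
error is $\mu_{\text{impact}} = 1 - \Pr[\text{treated} \mid x]$; winners
again minimize $\lambda^\alpha\mu^{1-\alpha}$.  When profile impacts have
mixed signs the coverage of some profiles leaves $[0,1]$; such profiles
cannot enter a geometric mean of errors and are excluded from the ranking
(in practice the ranking is run on profiles with significantly positive
effects, where the issue does not arise).

## The matching stage

The propensity score is a maximum-likelihood probit of the treatment
indicator on category indicators of the screened covariates, fitted once
on the full sample; profile-level effects always reuse these global
scores, so subgroup estimates differ only through sample composition, not
through model refits.  Marginal effects are evaluated at the regressor
means (discrete 0/1 changes for indicators) with delta-method standard
errors.

Treated records outside the comparison group's score range are dropped as
off-support; the trimming is symmetric (both tails) because the rule is
stated once and applies identically at either end.  For on-support treated
$i$ the counterfactual is the Epanechnikov-kernel-weighted mean of
comparison outcomes within bandwidth $h$, with comparison observation
masses entering multiplicatively, and the ATT is the mass-weighted mean of
$y_i - \hat y_i^0$.  Treated records with an empty kernel window are
dropped and counted, not rescued by a nearest neighbour, because support
is the estimand's boundary, not a nuisance.

**Bandwidth.** The source methodology does not state $h$; we default to
0.06, the long-standing convention of widely used kernel-matching
implementations, and expose it everywhere (a sensitivity sweep over
$\{0.02, 0.06, 0.1\}$ is a one-liner over `kernel_att`).

**Standard error.** Derived from the stated assumption set — independent
observations, fixed matching weights, homoscedastic outcomes within the
treated and within the comparison group, variance unrelated to the score.
The estimator is linear in outcomes with fixed weights: treated enter with
normalized masses $a_i$ and comparisons with aggregated weights
$\omega_j = \sum_i a_i K_{ij} w_j / \sum_{j'} K_{ij'} w_{j'}$, so
$\widehat{\mathrm{Var}} = s_T^2 \sum_i a_i^2 + s_C^2 \sum_j \omega_j^2$
with within-group sample variances.  It is exact under those assumptions
and ignores, by design, the estimation of the score itself.

**Numerics.** Kernel sums are computed either by dense evaluation of all
treated–comparison pairs (exact) or by an $O(n\log n)$ route that expands
the quadratic kernel into prefix sums over score-sorted comparisons, with
aggregated weights recovered through difference arrays.  The two routes
agree to $10^{-10}$ in the test suite; the fast route is selected
automatically only when the pair count is large and the bandwidth is not
tiny relative to the score spread, where its floating-point cancellation
is provably negligible.  The local effect-by-score curve uses
locally weighted smoothing with robustness iterations disabled: the
per-treated differences are bimodal (a binary outcome minus a smooth
counterfactual), and robustness reweighting would chase the majority mode
rather than the conditional mean.

## Guarding against subgroup fishing

Estimating effects in thousands of subgroups invites false discoveries.
Three diagnostics are built in.  First, the distribution of profile ATTs
across minimum-treated-size thresholds (`att_distribution_by_min_n`):
under a global null it must center on zero at every threshold, and a
genuine positive effect shows as right skew plus a shrinking share of
negative estimates as the threshold rises.  Second, the significance
convention is one-sided $t \ge 1.645$ with at least 100 treated
observations per profile (both configurable).  Third, `fdr_tradeoff`
estimates the false discovery rate per (minimum $n$, $t$) cell by a
permutation null — treatment labels permuted, the propensity model refit,
all profile effects recomputed — dividing expected null discoveries by
observed ones; a Benjamini–Hochberg variant is offered as a flag.  The
permutation estimator was chosen because it respects the dependence
between overlapping profiles, which an analytic per-test correction does
not.

## Interview-timing correction

Fieldwork spans months, so measured diet diversity drifts with the
interview date.  Residualizing the binary adequacy indicator on the day
index and re-thresholding the residual at its mean is algebraically inert
(for fitted probabilities inside $(0,1)$ it returns the input indicator),
and residualizing the underlying 0–7 score fails differently: a material
share of children sits exactly at the adequacy cutoff of 3 groups, where
arbitrarily small fitted shifts flip the classification.  The
day-regression method therefore cancels the *fitted* linear trend by a
minimal deterministic reclassification: per interview day, the rounded
fitted excess $n_d(\hat p_d - \bar p)$ of adequate records (from a linear
probability fit) is reclassified, flipping the records nearest the cutoff
by CDDS score first.  When adequacy is day-independent the fitted quota is
asymptotically zero and the correction is inert; under a linear trend the
adjusted indicator has zero linear day trend in expectation.  The default
remains `none`, so the core pipeline never silently depends on this
approximation.

## The synthetic survey generator

No public deposit of the motivating survey exists, so the generator
emulates its structure with known truth: ten integer-coded covariates
(child age band, sibling presence, mother's work and education, wealth
quintile, urban/rural, land use, growing-period length, farming system,
slope) drawn from fixed marginals; probit treatment assignment with
education, wealth and urban gradients *lowering* the probability of
inadequate diversity; an additive-risk stunting model (baseline
probability plus per-covariate shifts plus a planted $\tau_x$ for treated
members of each effect profile).  The additive-risk form was chosen
because the method's ATT is a difference in stunting proportions, so a
probability-scale $\tau$ is the quantity the pipeline should recover
without link-function translation.  Item recall flags are generated
consistently with the assigned diet class (inadequate children receive
0–3 food groups, adequate ones 4–7), so rescoring through the CDDS
builder round-trips exactly.

Default scale mirrors the study setting as *approximations, not targets*:
1613 households aged 6–25 months, treated share near 0.7, stunting base
near 0.2; with these defaults the fitted scores also leave about 1–2% of
treated households off support at the upper end.  What the generator does
**not** emulate: spatial clustering and survey design effects, covariate
dependence (draws are independent unless configured), measurement error
in recall, and selection on unobservables — so passing tests demonstrate
correct mechanics and calibration under selection-on-observables, not
robustness to hidden confounding.  The same caution applies to real data:
profile effects are systematic associations, causal only insofar as the
observables close the back door.

## Problem sizes and other fixed choices

The test suite and acceptance script run at deliberately chosen sizes:
constant-effect recovery uses 200 replicates of $n = 5000$; planted
profile effects use $n = 20000$ with 50 replicates for rank-correlation
checks; null calibration pools 500 disjoint profile tests across 25
replicates of $n = 6000$.  These sizes make Monte-Carlo bands tight
enough to detect the failure modes that matter (a bandwidth-induced bias,
a mis-derived variance) while keeping a full run in minutes on one core.
Probit fitting uses `glm` with tolerance $10^{-8}$ and up to 100
iterations; complete separation in the univariate screen falls back to a
ridge-penalized probit ($\lambda = 10^{-2}$, flagged in the output)
rather than reporting a degenerate zero p-value.  Ties in every argmin are
broken lexicographically by profile key and reported.  All stochastic
routines take explicit seeds (default 20151104).

## A worked miniature

```{r}
tab <- toy_fixture()
polling_metrics(profile("area", 1L), tab)
s <- rep(0.5, nrow(tab))
im <- impact_analysis(tab, c("area", "educ"), 1L, s)
im <- impact_coverage(im[im$profile_key %in% c("area=0", "area=1"), ], tab)
im[, c("profile_key", "att", "pr_x", "pr_treated_given_x",
       "impact", "impact_coverage")]
```

Every number above reproduces a hand computation shipped with the package
(`inst/extdata/toy_expected.json`); the acceptance suite holds them to
$10^{-12}$.

## Known limitations

* Selection on observables is assumed, never tested; the package reports
  associations whose causal reading is the analyst's responsibility.
* The analytic SE ignores propensity-estimation noise and between-profile
  dependence; bootstrap variants are out of scope.
* The exhaustive enumeration is exponential in $k$; it is the intended
  design (the method is non-parametric by construction) but practical
  only for the categorical, ten-variable scale it was built for.
* Impact coverage is interpretable only over universes of same-signed
  impacts; mixed-sign universes are flagged, not resolved.
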