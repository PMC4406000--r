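---
title: "Models and methods in twinpgg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in twinpgg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(twinpgg)
```

twinpgg analyses strategy-method public goods game data from twin samples
in three stages: decision scoring, Bayesian ACE variance decomposition,
and Monte Carlo simulation of the payoffs the registered strategies would
earn. This vignette documents the models, the numerical choices, and the
limits of what the synthetic validation shows.

## The game and the strategy method

A four-member group plays a linear public goods game: each member holds an
endowment $E$ (default 20 points) and contributes $c_i \in \{0, \dots, E\}$;
payoffs are

$$\pi_i = E - c_i + \frac{m}{n}\sum_j c_j,$$

with multiplier $m$ and group size $n$. `game_config()` enforces
$1 < m < n$, the social-dilemma condition under which the marginal
per-capita return $m/n$ is below 1, so own contribution is always
individually costly (`round_payoffs()` satisfies this dominance property,
and total payoffs obey the conservation identity
$\sum_i \pi_i = nE + (m-1)\sum_i c_i$ exactly). The two experimental
designs the defaults mirror used $m = 1.6$ (on-site group experiment) and
$m = 2$ (web experiment).

Under the strategy method each individual registers an unconditional
contribution (`uc`) and a complete conditional schedule: their
contribution at every integer level $k$ of the other members' average
contribution. Two schedule dialects are supported, one covering levels
1–20 (`"study1"`; no level-0 decision was elicited in the on-site design)
and one covering 0–20 (`"study2"`). The dialect is carried by the `c0`
column: rather than padding the missing level, lookups below the elicited
domain clamp to level 1. Where a continuous others' average must be mapped
to a schedule level, it is rounded **half-up** by default
(`floor(x + 0.5)`). Averages of three integers have fractional parts in
$\{0, 1/3, 2/3\}$, so the tie-break matters only for two-member averages;
banker's rounding is available via `rounding = "half_even"`.

## Decision scores and trend regressions

Composite band scores average the conditional schedule over preset level
ranges: LC/MLC/MHC/HC (five levels each, dialect `"study1"`) and
LC2/MC2/HC2 (seven levels each, dialect `"study2"`). `band_spec()`
verifies that bands are disjoint and jointly cover the domain.
`summarize_population()` reports per-level means and **sample** SDs
($n-1$ denominator; at the sample sizes involved the distinction from the
population convention is below printed precision, and for a single profile
the SD is reported as `NA` rather than 0). `trend_regression()` regresses
the 20 or 21 per-level summary values — not individual-level data — on
the level; its standardized slope equals the Pearson correlation, and
$R^2$ its square.

## The Bayesian ACE model

For a score $Y_{ij}$ of twin $i$ in family $j$,

$$Y_{ij} = \mu + A1_j + A2_{ij} + C_j + E_{ij},$$

with half-additive components $A1, A2$ of equal variance
$\sigma^2_A/2$. MZ co-twins share both halves, DZ co-twins share only
$A1$, so the additive covariance in MZ pairs is twice that in DZ pairs;
$C$ is shared within a family and $E$ (which includes measurement error)
is individual-specific. Marginally a pair is bivariate normal with common
variance $v = \sigma^2_A + \sigma^2_C + \sigma^2_E$ and covariance
$\sigma^2_A + \sigma^2_C$ (MZ) or $\sigma^2_A/2 + \sigma^2_C$ (DZ).

**Priors.** The non-informative default places uniform priors on the
variance components — $U(0, 50)$ on each half-additive component variance
(inducing $U(0, 100)$ on $\sigma^2_A$), $U(0, 100)$ on $\sigma^2_C$ and
$\sigma^2_E$ — and $N(0, 100)$ (variance 100) on $\mu$. Whether such
bounds are meant on the variance or the SD scale is a genuine ambiguity in
this literature; both interpretations are implemented
(`prior_scale = "variance"` is the default, `"sd"` squares the bounds).
The informative variant (`posterior_to_priors()`) replaces each uniform by
a normal centred at a previous posterior mean with the posterior variance,
truncated at zero for variances and floored at $10^{-6}$ to guard
degenerate posteriors — this is how an analysis of one sample is chained
into the next.

**Sampler.** Because the latent effects integrate out analytically,
`fit_ace()` samples only $(\sigma^2_A, \sigma^2_C, \sigma^2_E, \mu)$:
component-wise random-walk Metropolis for the three variances on the exact
marginal likelihood (written in sufficient statistics, so each evaluation
is $O(1)$) and a conjugate Gibbs draw for $\mu$. Proposal scales adapt
toward a ~35% acceptance rate during burn-in only, leaving the retained
chains valid MCMC. Chains start from overdispersed points inside the prior
support; burn-in is discarded before thinning, giving
$\mathrm{chains} \times (\mathrm{iterations} - \mathrm{burnin}) / \mathrm{thin}$
retained draws. Standardized shares $a^2, c^2, e^2$ are computed per draw
(they sum to 1 by construction) and summarised by posterior means and 95%
central credible intervals.

**Diagnostics.** `gelman_rubin()` implements the potential scale
reduction factor $\sqrt{\hat V / W}$ with
$\hat V = \frac{n-1}{n} W + B/n$; identical chains give
$\sqrt{(n-1)/n} < 1$. A fit with any statistic $\ge 1.1$ is returned with
a warning and `converged = FALSE`, never silently. With a single zygosity
class the A/C decomposition is unidentified and `fit_ace()` refuses to
run. Default MCMC settings are 3 chains × 100,000 iterations (burn-in
10,000, thin 100); the reduced settings used throughout the test suite
(3 × 5,000–10,000, thin 5–10, burn-in 1,000) give posterior means whose
Monte Carlo error is well below the data-level uncertainty at the sample
sizes involved.

**Intraclass correlations.** The default ICC estimator is the
double-entry Pearson correlation (each pair entered in both orders),
with a one-way ANOVA estimator as an alternative; intervals are bootstrap
percentile intervals over pairs (the interval machinery for printed twin
ICCs is not standardised across the literature, so a distribution-free
choice seemed safest).

## Payoff simulations

`simulate_one_shot()` samples groups of four distinct individuals
(uniformly, independently across groups; co-twins may co-occur). One
member is the conditional responder — implemented as the last position of
the uniformly ordered tuple, which is equivalent to a random role draw —
and responds to the rounded mean unconditional contribution of the other
three. Role-wise payoff means, Monte Carlo standard errors, and role
counts are accumulated per individual; the total estimated payoff is the
sum of the two role means. `exhaustive_one_shot()` enumerates all
4-subsets × 4 role assignments (guarded to $N \le 12$) and serves as the
exact oracle the simulator is tested against.

`simulate_iterated()` plays round 1 with the unconditional decisions;
from round 2 on **all four** members are conditional responders to the
other three members' previous-round average (memory-1 play; the one-shot
role asymmetry has no analogue once play repeats). Every round grants a
fresh endowment; the reported quantity is mean payoff per round, averaged
over group memberships. Default group counts are 250,000 (one-shot) and
100,000 (iterated) — where the source descriptions disagree between
10,000 and 100,000 iterated groups, the larger value is the default and
`n_groups` is configurable.

`payoff_curves()` reuses a single simulation to horizon $T$ and, for each
round $k$, correlates each decision score with the cumulative mean payoff
per round through $k$ — Spearman (mid-ranks, because score distributions
are tie-heavy) and partial Spearman controlling for the other scores
(residualised ranks; the inverse-correlation-matrix form is used only as a
test oracle). Degenerate correlations are flagged as `NA` with a warning.

## The synthetic twin-population generator

Real strategy-method samples show a discrete strategy-type mixture, and
the generator reproduces it. Three independent latent traits, each built
from the exact half-additive construction the ACE model assumes (so
co-twin correlations are $a^2 + c^2$ for MZ and $a^2/2 + c^2$ for DZ by
construction), drive an individual's profile:

* **liability** (standard-normal) with two thresholds assigns the types:
  above $\Phi^{-1}(1 - 0.248)$ strict free riders (all-zero schedule,
  `uc = 0`); below $\Phi^{-1}(0.436)$ near-perfect conditional
  cooperators; intermediates otherwise. The two prevalences are the
  observed fractions of free riders (24.8%) and conditional cooperators
  (43.6%) in web-based strategy-method data.
* **baseline** and **slope** map linearly onto the schedule within type:
  conditional cooperators centre on pure matching (baseline 0 ± 0.5,
  slope 1 ± 0.1 points per level), intermediates on a flat-ish weak
  response (baseline 3 ± 2.5, slope 0.25 ± 0.2) — consistent with a
  per-level mean near 1 point at level 0 rising to ~10 at level 20 and
  with the substantial fraction of flat responders seen in on-site data.

Non-free-riders register $c_k = \mathrm{clip}(\mathrm{round}(b + s\,k +
\varepsilon_k), 0, E)$ with i.i.d. registration noise
$\varepsilon_k \sim N(0, 2^2)$; the unconditional decision is generated
analogously at a reference level of 10 (the mid-scale contribution an
undecided participant might expect). Rounding and clipping happen after
noise addition; the attenuation of twin correlations they cause is
accepted and covered by test tolerances. Default trait shares
($a^2 \approx 0.2$–0.25, $c^2 = 0.1$) echo the modest heritabilities
reported for one-shot economic-game behaviour.

**What passing tests show — and don't.** The generator reproduces the
marginal facts that matter downstream (rising per-level means and SDs,
the free-rider point mass, the sign flip of the payoff–cooperativeness
correlation between short and long horizons) and its latent structure
matches the fitted model exactly, which is what makes parameter-recovery
loops meaningful. It does not emulate age/sex structure, schedule shapes
beyond piecewise-linear (e.g. hump-shaped responders exist only in the
hand-built fixtures), cross-trait correlation (configurable in principle,
independent by default), or selection into participation — so green
recovery tests validate the machinery, not the behaviour of any
particular human sample.

## Problem sizes and design choices in the test suite

Unit tests run at small scale (hundreds of pairs, thousands of groups).
The acceptance-level checks use: 200,000 groups for the
oracle-equivalence comparison (3 Monte Carlo SEs); 500 + 500 pairs with
3 × 10,000 / thin 10 / burn-in 1,000 MCMC for share recovery (±0.08, all
G–R < 1.1, Falconer's $2(r_{MZ} - r_{DZ})$ within ±0.1); 100,000 groups
and 100 rounds for the sign-flip curve; and, for the U-shaped profile of
payoff heritability across the iteration ladder $\{2, 20, 100\}$, five
replicates of 300 + 300 pairs with 150,000 groups each. The last pattern
is intrinsically delicate — the heritability recovery between 20 and 100
iterations is a few hundredths — so the group count is chosen to keep
per-individual Monte Carlo payoff noise (which inflates $E$ precisely at
long horizons) from drowning it, and the check is a majority over
replicates rather than a point assertion.

A note on one deliberate red flag: the trend-regression statistics for
the levels-1–20 reference table cannot be recovered exactly from its
printed (rounded) per-level values — recomputation gives a standardized
slope of 0.988 for the means (published: 0.986) and 0.928 for the SDs
(published: 0.921), implying the published regressions used unrounded
summaries. The corresponding checks assert the published values anyway
and fail by those margins; the levels-0–20 table reproduces its published
statistics to ±0.0005.

## Pipeline reproducibility

`run_study()` derives every stage's RNG seed deterministically from the
single run seed (fixed documented offsets), so reruns are numerically
identical, stages can be reproduced in isolation, and the manifest
(written alongside the delimited output tables) records seed, versions,
per-stage wall time, and completeness. Any stage failure aborts with the
stage name; degenerate statistics (homogeneous populations) are flagged
`NA` rather than fatal.

## Known limitations

* Memory-1 conditional play only; no longer memories, no strategy
  updating or evolutionary dynamics.
* No ADE, sex-limitation, or multivariate twin models; zygosity is taken
  as given.
* The ICC credible intervals are bootstrap percentile intervals, not the
  (unspecified) interval construction used in the printed tables this
  package's layouts mirror.
* Monte Carlo payoffs treat the population itself as fixed; uncertainty
  from sampling the participants is outside the model.
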