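# twinpgg

Behaviour-genetic analysis of public goods game strategies — and of the
payoffs those strategies earn — in classical twin designs.

## The problem

In a four-player public goods game each member receives an endowment of
*E* points and contributes *c<sub>i</sub>* ∈ [0, *E*]; the aggregate
contribution is multiplied by *m* and split equally, so member *i* earns

> π<sub>i</sub> = E − c<sub>i</sub> + m · Σ<sub>j</sub> c<sub>j</sub> / n.

With 1 < *m* < *n* contributing is individually costly but collectively
beneficial — a social dilemma. Under the **strategy method**, each
participant registers an *unconditional* contribution (UC) plus a full
*conditional* schedule C<sub>0</sub>…C<sub>20</sub>: the contribution they
would make at every possible average contribution of the other members.
Most people are *conditional cooperators* (contribution rises with
others'), a sizeable minority are *free riders* (all-zero schedules).

When the participants are monozygotic (MZ) and dizygotic (DZ) twins,
within-pair resemblance separates the variance of any decision score into
additive-genetic (A), shared-environment (C), and non-shared (E)
components — the **ACE model**. For individual *i* in family *j*,

> Y<sub>ij</sub> = μ + A1<sub>j</sub> + A2<sub>ij</sub> + C<sub>j</sub> + E<sub>ij</sub>,

where the two half-additive components have equal variance, MZ co-twins
share both halves and DZ co-twins share one, so cov(MZ) = σ²<sub>A</sub> +
σ²<sub>C</sub> and cov(DZ) = σ²<sub>A</sub>/2 + σ²<sub>C</sub>. The model
is fitted by MCMC (Metropolis-within-Gibbs on the exact marginal pair
likelihood) with uniform priors on the variance components, a normal prior
on μ, Gelman–Rubin convergence diagnostics, and optional informative-prior
chaining from a previous posterior.

Because a strategy is not yet a payoff, the package also simulates what
registered strategies *earn*: Monte Carlo one-shot games (three
unconditional members plus one conditional responder) and iterated games
in which every member plays a memory-1 conditional response to the others'
previous-round average, for any number of rounds. Rank correlations and
ACE fits on the simulated payoffs show how the fitness consequences of
cooperativeness — and their heritability — change with the shadow of the
future.

A synthetic twin-population generator with known latent ACE structure
(baseline contribution, conditionality slope, and a strategy-type
liability that assigns free riders, near-perfect conditional cooperators,
and weakly conditional intermediates) makes the whole pipeline testable
end to end against ground truth.

## Worked example

```r
library(twinpgg)

cfg <- synthetic_config(
  n_mz = 300, n_dz = 300,
  shares = list(baseline = c(0.4, 0.2, 0.4), slope = c(0.4, 0.2, 0.4),
                liability = c(0.4, 0.2, 0.4)),
  seed = 42)
pop <- generate_twin_population(cfg)

trend_regressions(summarize_population(pop$profiles))
#>   statistic slope intercept standardized_slope r_squared
#> 1 mean      0.508      1.18              0.999     0.999
#> 2 sd        0.334      1.61              0.994     0.988

scores <- compute_scores(pop$profiles, band_spec("study2"))
intraclass_correlation(pair_scores(scores, HC2), R = 1000, seed = 1)
#>   zygosity n_pairs   icc conf.low conf.high
#> 1 DZ           300 0.313    0.202     0.414
#> 2 MZ           300 0.470    0.373     0.562

fit <- fit_ace(pair_scores(scores, HC2),
               ace_model_spec(iterations = 10000, burnin = 1000, thin = 10),
               seed = 1)
fit
#> <ace_fit> 300 MZ + 300 DZ pairs, 2700 retained draws (3 chains)
#>   a2 = 0.297 [0.071, 0.492]
#>   c2 = 0.169 [0.015, 0.354]
#>   e2 = 0.533 [0.456, 0.621]
#>   max Gelman-Rubin: 1.0003

sim <- simulate_one_shot(pop$profiles, game_config(), n_groups = 50000, seed = 2)
spearman_rho(scores$uc, sim$mean_uncond)
#> [1] -0.969
```

Reading the output: per-level mean contributions rise almost perfectly
linearly with others' level (standardized slope 0.999), and so does their
spread — the signature of a mixed conditional-cooperator / free-rider
population. The MZ intraclass correlation for the high-contribution band
score exceeds the DZ correlation (0.47 vs 0.31), and the ACE fit turns
that gap into a posterior heritability of about 0.30 with a 95% credible
interval [0.07, 0.49] (the generating latent value was 0.4; integer
rounding, clipping, and the type mixture attenuate it). In the one-shot
game, contributing is costly: the Spearman correlation between the
unconditional decision and the unconditional-role payoff is −0.97.
Run `payoff_curves()` to watch that correlation flip sign as the number
of iterations grows, and `run_study()` to produce the full report bundle
(decision summaries, ICC and ACE tables per score, one-shot and iterated
simulations, correlation curves) in one call.

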