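---
title: "Pathways of compensatory substitution: model, rates, and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathways of compensatory substitution: model, rates, and simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Two biallelic loci interact epistatically: the ancestral haplotype `AB`
and the doubly derived haplotype `ab` have fitness 1, while the two
single-mutant intermediates `aB` and `Ab` are deleterious with fitness
`1 - s` under haploid (genic) selection. Mutation is symmetric and
reversible at rate `mu` per locus per copy per generation, so either fit
haplotype is two mutational steps from the other, and every path between
them passes through a fitness valley. A population of `N` diploids
(`2N` haploid copies) crossing from fixed `AB` to fixed `ab` performs a
*compensatory substitution*.

Two qualitatively different pathways exist when selection is weak to
moderate:

* **Type 1** — a deleterious intermediate drifts to fixation first, and
  the compensating mutation then sweeps from that fixed intermediate.
* **Type 2** — the two loci are simultaneously polymorphic and the
  double mutant fixes without the intermediate ever being the last fixed
  state.

The package parameterises everything by the population-scaled quantities
of the study grid: `theta = 4 N mu` per locus (0.001–1), `Ns` (0–3),
`2 N rho` (0 or 5), and `2N = 200` copies. `make_parameters()` converts
scaled values to primitives; all derived quantities (`theta`, `Ns`, `t =
s/(1-s)`) are recomputed from primitives, never stored independently.

## The fixed-state substitution chain

Novel fixation events (the population becoming monomorphic for a
haplotype different from the last fixed one) define a four-state
continuous-time chain over `(AB, aB, Ab, ab)`. Its rates are:

* `r1 = 2 N mu (1 - e^{2s}) / (1 - e^{4Ns})` — from a fit state into
  either deleterious state: the origination rate `2 N mu` of new single
  mutants times the diffusion fixation probability of a deleterious copy.
* `r2 = 2 N mu (1 - e^{-2t}) / (1 - e^{-4Nt})` — out of a deleterious
  state into either fit state, with `t = s/(1-s)` the advantage of a fit
  invader after renormalising the resident fitness to 1. A literal-`s`
  variant (`advantage = "s"`), which some rate-matrix presentations use,
  differs at order `s^2`.
* `r3 = r4` — the *direct double-substitution* rate `AB -> ab`, the
  quantity this machinery exists to compute, extracted as described
  below.

Both kernels switch to their neutral limit `1/(2N)` when `|4Ns| <
1e-8`, avoiding the 0/0 of the raw expressions.

### The stationary density and the origination rate

Let `x` be the pooled frequency of the two deleterious haplotypes. Under
pooled mutation (rate `2 mu` per copy in each direction between the
fitness classes), genic selection and drift, `x` has the Wright
equilibrium density

```
phi(x) = C exp(-4 N s x) x^(2 theta - 1) (1 - x)^(2 theta - 1).
```

Two numerical decisions matter here:

* **Sign of the exponent.** Some presentations print the exponent as
  `+4Nsx` even though `x` is the frequency of the class selection acts
  *against*. Re-deriving the density from Wright's formula (the focal
  class has selective effect `-s`) gives `-4Nsx`; this orientation also
  agrees with the fixation kernels, and with the long-run simulated mean
  of `x`, which `stationary_density()` is tested against (a 300k-
  generation run matches the quadrature mean within 10%). The package
  default is therefore the negative exponent; `sign = "printed"` exposes
  the positive-exponent variant, under which essentially all mass piles
  onto the deleterious class and the direct probability degenerates
  towards 1.
* **Quadrature.** For `theta < 0.5` the exponents `2 theta - 1` are
  negative and the density is endpoint-singular (integrably so for any
  `theta > 0`; at `theta = 0` it is not integrable and construction is
  refused). The singular factor is therefore absorbed into the weight
  function of a Gauss–Jacobi rule (`statmod::gauss.quad`, `alpha = beta
  = 2 theta - 1`, mapped to the unit interval); integrands evaluated on
  the rule are smooth. 128 nodes are the default; node doubling is
  asserted to change the normalising integral by less than `1e-8`
  (observed changes are at machine precision across the whole study
  grid, because the remaining factor is an entire function).

The total rate at which *successful* double mutants arise is

```
alpha = 2 N mu * Int x p_ab(x) phi(x) dx,
p_ab(x) = p_y(x) / (2 N y'),   y' = (1 - x) + 1/(2N),
p_y(x)  = (1 - e^{-4 N s y'}) / (1 - e^{-4 N s}),
```

the product of the per-generation probability `2 N mu x` that an `ab`
copy arises from an intermediate, the fixation probability `p_y` of the
fit class at its post-mutation frequency `y'`, and the neutral
within-class share `1/(2N y')` of the new lineage. At `s = 0` this
collapses to `alpha = mu E[x] = mu/2`.

### Extracting the direct rate

At stationarity the total flow into `ab` decomposes over the source
states, `alpha = (pi_aB + pi_Ab) r2 + pi_AB r3`, so

```
r3 = (alpha - (pi_aB + pi_Ab) r2) / pi_AB .
```

The stationary probabilities are taken from flow balance of the chain
itself: the deleterious class is entered at rate `r1` and left at rate
`r2`, hence `pi_X / pi_Y = r1 / r2`, split evenly within each class by
symmetry. (Deriving `pi` instead as mass of `phi` above a frequency
threshold gives similar values under strong selection but produces
negative `r3` under weak selection, so the flow-balance form is the
default and only construction.)

The subtraction is numerically delicate: `alpha` and the
via-intermediate flow nearly cancel whenever direct events are rare.
Residuals within `1e-12 * alpha` of zero are floating-point noise and
are clamped to exactly 0; larger negative residuals raise an error that
reports all inputs. That error is a feature: it fires in the
weak-selection, very-low-mutation corner (for example `theta = 0.001`,
`Ns = 1`), where the decomposition's own error exceeds the tiny true
rate — the approximation announces its breakdown rather than returning
a sign-violating rate.

From `r3` follow the direct double-substitution probability and the
pooled jump chain of fixed states (`DEL` = either intermediate, `ab`
absorbing to match the simulation's stopping rule):

```
beta      = r3 / (2 r1 + r3)
P(Type 2) = 2 beta / (1 + beta)
E[reversions to AB] = (1 - beta) / (1 + beta)
```

`absorption_pathway_split()` and `reversion_count_distribution()`
recompute the last two from the chain's transition matrix by first-step
linear equations and cycle enumeration, so the closed forms are verified
against an independent route rather than restated.

## The forward simulator

`run_replicate()` starts from fixed `AB` and iterates per generation:

1. **Mutation** — `Poisson(4 N mu)` events; copies are selected
   uniformly *without replacement* (a copy is never mutated twice in one
   generation; a draw exceeding `2N`, astronomically unlikely on the
   study grid, is capped at `2N`); each selected copy flips one locus
   with a fair coin.
2. **Recombination** — `Poisson(2 N rho)` events applied sequentially;
   each picks two distinct copies uniformly (equivalent to
   frequency-proportional haplotype choice without replacement) and
   exchanges their second-locus alleles. Marginal allele counts at each
   locus are conserved exactly.
3. **Resampling** — the next generation is `2N` draws with replacement
   with probabilities proportional to `count * fitness` (sequential
   conditional binomials over the classes present).

Fixation is checked once per generation, after resampling; every novel
fixation is recorded, the initial fixed-`AB` condition counting as an
`AB` fixation at generation 0 (required both to classify direct first
passages as Type 2 and to time the final path). A replicate ends at the
`ab` fixation, or is flagged censored at `max_generations` (default
`5e7`; censored replicates are excluded from every estimator and their
count reported — at `theta = 0.001` censoring is expected to be heavy
and those cells are not part of the routine test tier).

While the population is monomorphic, mutation is the only move that can
change it — recombination and fitness-weighted resampling are identities
there — so the simulator jumps ahead by a geometric waiting time to the
next generation containing at least one mutation and draws that
generation's count from a positive-truncated Poisson. The two-step
construction (geometric gap, truncated count) is distributionally
identical to stepping generation by generation; it changes only which
random numbers are consumed. The state is the vector of four haplotype
counts, not an individual list: individuals are exchangeable, so the
count process is the same Markov chain at a small fraction of the cost.

All randomness flows through R's RNG; `(params, seed)` reproduces a
replicate bit-identically, and batch seeds are spawned deterministically
from a base seed. The suite cross-checks the compiled simulator against
a naive generation-by-generation R implementation at `theta = 1`.

## Estimators

* `estimate_beta()` pools over all replicates and event-list positions:
  every transition out of a fixed-`AB` state is a trial, those entering
  `ab` directly are successes. (Pooling transitions, rather than
  averaging per-replicate proportions, weights every departure equally;
  the per-replicate average would overweight short paths.)
* `estimate_p_type2()` is the proportion of uncensored replicates whose
  last fixed state before `ab` was `AB`.
* Proportions carry Wilson score intervals, which behave sensibly at
  estimates of 0 or 1 — routine at the corners of the grid.
* `path_time_statistic()` compares final-path durations (last `AB`
  fixation to `ab` fixation) between the pathway types with the pooled
  two-sample z statistic `z = (m1 - m2) / sqrt(s_p^2 (1/n1 + 1/n2))`;
  a Welch variant is available but the pooled form is the default. Two
  degenerate equal groups give `z = 0`; groups with fewer than two
  members give a flagged undefined result rather than an exception.

## The phylogenetic layer

`build_q()` turns a rate set into a 4×4 instantaneous rate matrix over
the fixed states, with `q(aB <-> Ab) = 0` structurally (direct movement
between the two intermediates would have to cross the valley twice
while dodging both peaks). Two constructions are shipped:

* `raw` (default) — the chain's arrow rates themselves. This
  matrix provably has stationary distribution `pi` and satisfies
  detailed balance, which the suite verifies to `1e-12` together with a
  left-null-vector eigencheck.
* `pi_weighted` — each off-diagonal rate additionally multiplied by
  the target state's stationary probability, a GTR-style weighting that
  appears in print. It is *not* balanced with respect to `pi` when
  `r1 != r2`; both forms are provided rather than guessing intent, and
  the default is the internally consistent one.

Both are rescaled by `u` so the expected substitution rate at
stationarity is 1 — the only reading under which branch lengths are
expected substitutions per paired site. Transition probabilities use a
dense scaling-and-squaring matrix exponential (no reversibility
assumed, so the weighted mode is covered), and `pruning_loglik()` runs
Felsenstein's recursion with the root weighted by `pi`, verified against
brute-force enumeration over interior-node states on small trees. The
rates, and hence the model, describe the *origination* process — when a
mutation destined to fix arises, not when its fixation completes — so
simulated fixation times sit very slightly above `1/alpha`; the
single-mutant check (a conditional fixation time of about `4N`
generations, small against the waiting times on this grid) bounds the
difference.

## What the generator emulates, and what it does not

The simulator *is* the data generator for every stochastic check, run
at the study conditions: `2N = 200`, `theta` in `{0.01, 0.1}` (with
`0.001` and `1` exercised analytically), `Ns` in `{0..3}`, `2N rho` in
`{0, 5}`, 500 replicates per cell (the acceptance tier; 1000 is the
full-study count, and `reproduce-grid` accepts any count). It emulates
exactly the model above — and therefore none of: asymmetric mutation or
selection, diploid genotype selection or dominance, more than two
alleles per locus, linked background variation, or population-size
change. Passing tests certify the internal consistency of theory and
simulation under the model, not the model's fit to any real population.

The recombination comparison runs with a `1e7`-generation censoring
horizon: under `2N rho = 5` and strong selection a large fraction of
replicates exceeds any practical horizon, and censored replicates are
excluded from both arms of the comparison alike.

## Validity envelope

The suite measures, rather than assumes, the quality of the analytic
approximations, and three boundaries are worth knowing:

* **Diffusion kernels.** Against the exact 201-state chain, the
  beneficial kernel stays within about 1% over the study grid, and the
  deleterious kernel within about 1.5% up to `s = 0.01`; at `s = 0.03`
  (`4Ns = 12`) the deleterious kernel's relative error grows to roughly
  `2 N s^2`-sized (about 18%), an intrinsic diffusion limit for
  exponentially small fixation probabilities, not a coding artefact.
* **The direct probability.** The simulated direct-departure proportion
  tracks the analytic `beta` closely at the grid corners (near 0 and
  near 1) but sits systematically below it through the transition
  region — at 500 replicates per cell the difference is several Wilson
  interval widths in mid-grid cells, and two independent simulator
  implementations agree on the simulated value. The `alpha`
  decomposition attributes some genuinely polymorphic, multi-state flow
  to the direct arrow, so `beta` from the decomposition is best read as
  a figure-level approximation that is excellent near the corners and
  upward-biased by up to roughly a quarter in the transition region.
  The corresponding acceptance checks are asserted at their stated
  statistical tolerances and record this bias where they fail.
* **High mutation.** The derivation of `alpha` assumes mutation is rare
  relative to the population size; at `theta = 1` only qualitative
  directions are asserted.

## Problem sizes

The routine suite uses 500 replicates per grid cell, a 300k-generation
stationary-density comparison, 200 conditional fixation trajectories,
and `1e5`-draw resampling checks; these sizes put binomial standard
errors around 1–2 percentage points, which is what the stated
tolerances assume.
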