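---
title: "Programmed cell death as an accessory to microbial bet hedging: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Programmed cell death as an accessory to microbial bet hedging: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcdbet)
```

## The question

Many microbes hedge against unpredictable environmental shifts by
stochastic phenotype switching: at each reproduction the offspring takes an
alternative phenotype with a small probability $p$, so a clonal genotype
maintains a standing mix of phenotypes even though only one of them is fit
at any moment.  Switching needs reproduction, and reproduction needs room.
In a population pinned at carrying capacity nothing reproduces, nothing
switches, and an initially uniform clone stays uniform until the next
catastrophe sorts the survivors.  `pcdbet` implements a family of models in
which programmed cell death (PCD) — genetically encoded cellular suicide at
a per-round probability $c$ — creates that room.  Cells die, clonemates (or
competitors) replace them, and every replacement is a fresh chance to
switch.  The package asks when a PCD+ genotype beats an otherwise identical
PCD− genotype in an environment where disasters strike one of two
phenotypes, $A$ or $B$, at random.

Three models share this skeleton and differ in how the *assortment*
$r$ — the probability that a cell dying from PCD is replaced by growth of
its own genotype — is treated:

1. **Fixed assortment** (`deterministic_round()`, `run_competition()` and
   friends): $r$ is a parameter.  A deterministic one-round map gives
   closed-form costs and benefits; a stochastic twin runs full
   competitions.
2. **2D lattice** (`init_lattice()`, `run_lattice_competition()`): cells
   occupy a 100×100 grid, dead cells are refilled from the 8-site Moore
   neighbourhood, and each PCD+ cell has its own local $r$ (same-genotype
   fraction among living neighbours), so assortment is an emergent,
   measured quantity.
3. **3D agent-based model** (`init_world()`, `run_abm()`): cells live in
   patches (default $10\times10\times10$ patches of capacity $K = 10$) with
   reproduction, migration, PCD, and disasters that kill 99% of the
   susceptible phenotype; assortment emerges from demography alone.

## The closed-form layer

For real-valued counts $(A_p, B_p, A_n, B_n)$ (PCD+ and PCD− genotypes,
phenotypes $A$/$B$) one round of PCD and repopulation is

$$
\begin{aligned}
A_p' &= A_p - cA_p + cr(1-p)A_p + prcB_p\\
B_p' &= B_p - cB_p + cr(1-p)B_p + prcA_p\\
A_n' &= A_n + c(A_p+B_p)(1-r)\,\big(f_A(1-p) + f_B\,p\big)\\
B_n' &= B_n + c(A_p+B_p)(1-r)\,\big(f_B(1-p) + f_A\,p\big),
\end{aligned}
$$

with $f_A, f_B$ the competitor's phenotype frequencies.  The map conserves
the total, and the PCD+ genotype shrinks by $c(1-r)$ per round, so after
$t$ disaster-free rounds it has decayed by `cost_factor()`:
$\big(c(r-1)+1\big)^t$.  At $r = 1$ the factor is 1: perfectly assorted PCD
is costless.

The benefit is diversification.  Right after a disaster each genotype holds
a single phenotype, $m$ cells for PCD+ and $N - m$ for PCD−.  One round of
PCD/regrowth then produces $prcm$ switched PCD+ cells and $p(1-r)cm$
switched PCD− cells in expectation (`expected_switch_counts()`); the
probability that *only* the PCD+ strain diversifies is

$$(1-p)^{cm(1-r)} - (1-p)^{cm}$$

(`prob_exclusive_diversification()`), maximised at
$p^\ast = 1 - (1-r)^{1/(cmr)}$ (`optimal_switch_rate()`).  Against this
stands the chance $c^m(1-r)^m$ that PCD wipes its own strain out in a
single round (`prob_pcd_extinction()`), and the ratio of the two
(`benefit_cost_ratio()`) is the headline quantity: at $p = 10^{-6}$,
$r = 0.5$, $c = 0.09$, $m = 11$ it exceeds $10^6$.

```{r closed-forms}
cost_factor(0.1, 1, 50)
optimal_switch_rate(0.1, 100, 0.5)
benefit_cost_ratio(1e-6, 0.09, 11, 0.5, log10 = TRUE)
time_to_stationary_diversity(1e-3)
```

`time_to_stationary_diversity()` iterates the expected minority-frequency
recursion $x_{t+1} = x_t(1-p) + (1-x_t)p$ from $x_0 = 0$; its default
tolerance 0.005 (1% of the stationary frequency 0.5) is a documented
choice — the source claim ("more than 1,000 generations at $p = 10^{-3}$")
names no threshold, and any tolerance below ~0.15 keeps the answer above
1,000 generations.

### Numerical choices

* `benefit_cost_ratio()` works in log space with an `expm1` step:
  at $p \lesssim 10^{-6}$ the factor $(1-p)^{-cmr} - 1$ is a difference of
  nearly equal numbers and direct evaluation loses all precision.  A zero
  denominator ($c = 0$ or $r = 1$) is reported as `Inf` rather than an
  error: the cost of PCD-driven extinction is exactly zero there.
* The exponent $cm$ is used as printed, a real number; no rounding of
  expected deaths.  The stochastic model uses integer deaths, and agreement
  between the two is asserted only within Monte-Carlo error.
* When the competitor is extinct, the frequency terms $f_A, f_B$ are
  undefined; the package then returns the whole replacement flow to the
  PCD+ genotype (equivalent to $r = 1$ while the competitor is absent).
  Only living cells can regrow; this also keeps the map conservative.

## The stochastic fixed-r model

`pcd_regrowth_round()` is the per-cell counterpart of the map above:
binomial PCD deaths per phenotype, each dying cell replaced in kind (own
genotype, same phenotype, switch with probability $p$) with probability
$r$, else by a competitor offspring drawn from the competitor's phenotype
frequencies and then switched.  `run_competition()` chains rounds of
*(disaster with probability $d$, regrowth to capacity, PCD/replacement)*
until a genotype dies out or 10,000 rounds pass, at which point the
majority genotype wins; exact ties and double extinctions are their own
outcome classes and are excluded from win fractions.  Regrowth is a
sequential urn: each birth's parent is uniform over the current growing
population and the offspring switches with its genotype's probability.

The round structure is a documented convention: the source text alternates
"rounds of PCD" with randomly timed disasters without fixing an order, so
the package defines a round as disaster-then-regrowth-then-PCD, which makes
$t$ in the cost factor count exactly the PCD steps between disasters.  One
PCD step per round is the default; the initial state is $N/4$ of each type
with $N = 10{,}000$.

Sweeps (`win_fraction_sweep()`, `max_tolerated_pcd()`) cross parameter
vectors, run replicate competitions per combination with child seeds
derived arithmetically from one root seed, and return tibbles.  Because
derived seeds are deterministic functions of the (combination, replicate)
index, a sweep is a pure function of its configuration and root seed;
re-running writes byte-identical tables.

## The lattice model

Sites hold one of the four cell types or are empty; the neighbourhood is
the 8-site Moore neighbourhood with non-periodic edges (edge and corner
cells simply have 5 or 3 neighbours).  A round is: lattice-wide
annihilation of a uniformly chosen phenotype with probability $d$, then
simultaneous PCD deaths, then pass-based repopulation — in each pass the
empty sites with at least one neighbour alive at the start of the pass are
filled (in random order) by offspring of a uniformly chosen such
neighbour, and new offspring become available as parents from the next
pass on.  The per-round change $\Delta \bar r$ is measured as mean
assortment after repopulation minus before the round's first death.

Initial configurations with a target mean assortment are built by random
same-phenotype genotype swaps accepted whenever they move the measured
mean towards the target (starting from two half-grid blocks for targets
at or above 0.8, a uniform mix otherwise).  For a 50:50 genotype mixture
the attainable range is roughly $[0.5, 0.99]$ — maximally anti-assorted
stripe patterns bottom out near 0.25 under the Moore neighbourhood, and
the accept-if-closer walk cannot reach targets below ~0.3; an unreachable
target fails with the achieved value in the message rather than looping.

Two conventions worth noting: per-cell assortment is defined only for PCD+
cells over *living* neighbours (cells with no living neighbour are
excluded, and a lattice with no qualifying cell yields a flagged-undefined
summary); and the first disaster of a run belongs to neither the
"target-switched" nor the "repeat-target" class in
`delta_r_statistics()`, since it has no predecessor.  The lattice switch
probability defaults to 0.1, the value the fixed-r competitions use in the
phase-diagram figures; the source does not state it for the lattice run
and the argument is exposed.

## The agent-based model

Each time step runs four phases in order: disaster (probability $d$; a
uniformly chosen phenotype keeps binomial 1% survivors in every patch),
reproduction (cells present at the start of the phase each place one
offspring into their own patch while it is below $K$; when space is short
the reproducing subset is uniform — the random global update order makes
the first free slots a uniform sample), migration (each cell moves with
probability $m$ to a uniformly chosen adjacent patch, blocked if full;
face adjacency by default, 26-neighbour adjacency behind a flag), and PCD.
Patch capacity is an invariant after every phase and can be asserted
per-step (`check_capacity = TRUE`).

Metrics follow the package-wide conventions: per-genotype phenotypic
diversity is the Shannon entropy of the genotype's $A/B$ split normalised
to $[0,1]$ (an absent genotype is flagged `NA`, not 0), and assortment is
the patch-local analogue of the lattice estimator — the mean over PCD+
cells with at least one patch-mate of the same-genotype fraction among
patch-mates.  The source plots $r$ for this model without defining it;
mirroring the lattice estimator keeps the three models on one scale.

Unstated knobs are configuration, not inference: grid dimensions default
to $10\times10\times10$ patches so the global capacity (10,000) matches
the other two models; worlds start half full with cells placed uniformly
at random over patch slots; a step cap (default 20,000) bounds sweeps.
The ABM switch probability defaults to 0.1, the value the fixed-$r$
competitions state for their phase diagrams, keeping the three models'
competition conditions aligned; at much lower switch rates per-genotype
diversity at these population sizes is dominated by drift rather than by
the PCD turnover mechanism the model is built to expose.

## What the tests do and do not show

The test suite validates the stochastic engines against the closed-form
layer (componentwise agreement of Monte-Carlo means with the deterministic
map at 3 standard errors; the log-linear decay of the PCD+ genotype
against the cost factor within 5%), checks the structural invariants
(conservation at capacity, complete lattice refill, patch capacity,
determinism under fixed seeds, symmetry of neutral competitions), and
re-derives the headline directional results at reduced scale: a larger
PCD-favourable region at high assortment, monotone growth of the maximal
tolerated PCD rate in both assortment and disaster frequency, negative
small / positive large conditional assortment changes on the lattice, the
~0.9 late-time assortment plateau in PCD+-winning lattice runs, and the
ABM's monoculture demography, diversity ordering and win-fraction trends.

Problem sizes are the package's own reduced designs: 25–200 replicates per
well-mixed grid cell at $N = 10^4$; 21 lattice runs (7 per initial
structure) capped at 2,000 rounds plus 45 capped at 4,000 for the plateau;
$8^3$-patch worlds, 1,200–3,000 steps and 5–15 replicates for the ABM.
The Fig-5C-style diversity comparison averages the per-genotype diversity
across 12 replicate competitions at each recorded step (after the first
disaster, before which the two time series are identical by construction)
and asks at what fraction of steps the PCD+ mean is higher; per-run step
fractions would instead be dominated by near-tie noise between two curves
both sitting at entropy ≈ 1.

The synthetic worlds these tests run on are exactly the models' own
initial conditions (random 50:50 placements, block-or-swap lattices), so
passing them shows internal consistency and reproduction of the models'
published behaviour — not that any particular real microbial population
behaves this way.  Real populations have structured (non-random) starting
configurations, non-binary phenotypes, correlated disasters and
density-dependent death, none of which are modelled here.

## Known limitations

* The fixed-$r$ model treats the assortment of every dying cell as
  independent; spatial correlations between consecutive deaths exist only
  in the lattice and patch models.
* Lattice repopulation is pass-based: offspring become parents one pass
  later.  Site-by-site immediate availability is a defensible alternative
  reading; at the default parameters the fill is dominated by
  single-empty-site rounds where the two schemes coincide.
* Disasters are memoryless and unbiased; regimes with correlated or
  biased targeting are out of scope, as are continuous-time dynamics,
  evolving PCD rates, and more than two genotypes or phenotypes.
* Child seeds are derived arithmetically from the root seed per
  (combination, replicate); streams are reproducible and effectively
  independent, but inserting new grid points re-indexes later
  combinations' streams.
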