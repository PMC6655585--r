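---
title: "De novo syntrophy in random viable metabolisms: models and methods"
author: "SynFBA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{De novo syntrophy in random viable metabolisms: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SynFBA)
```

## The scientific question

Syntrophy is a mutual nutritional dependency: a pair (or community) of
organisms grows on a substrate that no member can use alone, mediated by
metabolite exchange. The usual explanation is degenerative co-evolution of
initially self-sufficient partners. SynFBA implements the alternative
hypothesis test: draw metabolisms *at random* from the space of reaction
networks viable on a given primary carbon source — so that they share no
evolutionary history — and ask how often two such metabolisms, allowed to
exchange metabolites freely, become viable on carbon sources neither can
use alone.

The package covers the whole computational pipeline: constraint-based
model containers, flux balance analysis (FBA), a viability-constrained
Markov chain Monte Carlo (MCMC) sampler of random viable metabolisms,
pairwise syntrophy detection with explicit exchange modelling and minimal
exchanged-metabolite computation, the formal syntrophy statistics with a
no-exchange null model, and core–periphery analysis of the carbon-source
syntrophy network.

## The growth model

A `ReactionUniverse` holds a sparse stoichiometric matrix $S$ (metabolites
$\times$ reactions, negative coefficients consumed), reversibility and
transport flags, one biomass reaction, a per-metabolite extracellular
flag, and the universe's declared minimal-medium metabolites. A
`Metabolism` is a subset of the universe's reactions that always contains
the biomass reaction, tagged with its primary carbon source.

Growth of a metabolism in an environment (a `GrowthMedium`: one bounded
carbon source plus the minimal medium) is the FBA optimum

$$\max_v \; v_{\mathrm{biomass}} \quad \text{s.t.}\quad S v = 0,\; v \in
[l, u],$$

with the exchange conventions implemented by `buildSystem()`:

* medium metabolites: unbounded uptake and secretion;
* the carbon source: uptake bounded by `uptakeBound` (default **10** flux
  units — the standard reading of supplying ten concentration units of the
  carbon source to a steady-state model);
* every other extracellular metabolite: secretion only. This is the strict
  interpretation under which losing a transport reaction genuinely blocks
  a carbon source, which matters because transport loss turns out to be a
  main obstacle to syntrophy.

A metabolism is *viable* when the optimum strictly exceeds the threshold
**0.001** (growth at exactly 0.001 counts as zero). The biomass reaction
is a single aggregate sink consuming all precursors jointly; demanding
each biomass compound separately is a stricter alternative reading which
the aggregate objective upper-bounds (any flux distribution satisfying
the aggregate demand produces every precursor in ratio), and the
aggregate form is what a single growth objective expresses.

### The LP engine

No linear-programming backend is assumed: the package ships its own
bounded-variable two-phase revised simplex (C++, `solveLP()`), with
reversible reactions split into forward/backward columns, explicit basis
inverse with periodic refactorisation, Bland's rule as the anti-cycling
fallback, a pivot tolerance of $10^{-10}$ and flux clamping at
$10^{-9}$. It is cross-checked in the test suite against `boot::simplex`
(an independent pure-R implementation) on random LPs and against
hand-enumerated pathway yields.

## Sampling random viable metabolisms

`swapStep()` deletes one non-biomass reaction uniformly at random, inserts
one universe reaction not currently present uniformly at random (the
exclusion keeps the metabolism size exactly constant), and accepts iff the
result is still viable on the primary carbon source; otherwise the swap is
reverted. `randomWalk()` iterates this (default **50,000** proposals, the
scale needed to randomize a genome-scale reaction complement; desk-scale
analyses use shorter walks, see below). Viability is re-checked by a full
LP at every step; for speed the walk assembles the full-universe system
once and imposes membership through flux bounds, which is mathematically
identical to rebuilding the subsystem (asserted in tests).

`reduceMetabolism()` shrinks a metabolism to a target size (default
**520**, a quarter of a genome-scale complement) by repeatedly deleting a
reaction drawn uniformly from the currently removable set, recomputed
after every deletion as the reactions carrying zero flux in a current
optimal solution — such a reaction is provably deletable because that
optimal solution remains feasible without it; the result is nevertheless
re-verified by LP after each removal. The stand-alone
`zeroFluxReactions()` operation answers the stricter question "which
reactions are zero in *every* optimal solution" by flux variability over
the optimal face (objective fixed within a relative $10^{-9}$), which
avoids degenerate-optimum false positives.

`samplePopulation()` runs `perSource` walks per primary carbon source with
per-walk seeds derived as `seed + walk index`, so one integer reproduces
the whole population. The alternative of reducing first and
walking afterwards is available as `mode = "reduce-then-walk"`; it
constrains the walk much harder (acceptance drops sharply) and is off by
default. All randomness flows through R's RNG; generator and pipeline
functions take explicit seeds and restore the caller's RNG state.

## Detecting syntrophy

For metabolisms $A, B$ and carbon source $C_k$, let $G(A, B, C_k)$ be the
FBA optimum of the *pooled* metabolism (union of reaction sets,
`poolMetabolisms()` / `jointGrowth()`). The pair is syntrophic on $C_k$
when

$$G(A, A, C_k) = 0,\qquad G(B, B, C_k) = 0,\qquad G(A, B, C_k) > 0,$$

with the 0.001 threshold applied throughout; a metabolism is never
syntrophic with itself. `explicitExchangeGrowth()` implements the more
explicit two-compartment model: internal metabolites are duplicated per
partner, the extracellular space is shared, and reversible transfer
reactions couple the copies of each metabolite in an allowed set;
the objective is the summed biomass flux. With every metabolite
transferable this is mathematically equivalent to pooling (asserted to
$10^{-6}$ on hundreds of seeded pairs); with no transfers it decouples to
the better individual growth, because the LP allocates the shared bounded
carbon to the higher-yield partner.

Transfer reactions are reversible — either partner may donate — because
the exchange model is direction-agnostic free exchange. Only internal
metabolites touched by both partners' reactions are transfer candidates;
moving any other metabolite cannot change either partner's feasible set.

### Minimal exchanged metabolites

`minExchangedMetabolites()` finds a smallest metabolite set whose
transfer sustains joint growth above threshold. The default method solves
the mixed-integer program — one binary per candidate metabolite gating
its two transfer fluxes via a big-M bound ($10^3 \times$ the carbon
uptake bound), objective the number of open gates, joint growth
constrained above threshold — by depth-first branch and bound on the LP
relaxation, with integer incumbents re-verified by an exact LP so big-M
leakage can never produce an infeasible "minimum". The exhaustive method
enumerates subsets by increasing size and doubles as the test oracle;
both methods agree on every small instance in the acceptance suite. Ties
between distinct minimum sets of equal size are resolved in favour of
whichever the search reaches first; only the count is unique.

## Statistics and the null model

With $N$ metabolisms, the *syntrophic potential* $\bar s$ of a metabolism
is the fraction of its $N-1$ pairings that yield at least one syntrophic
source; the *carbon-source pair syntrophic potential* $\bar s_p(C_i,C_j)$
is the syntrophic fraction of the $n^2$ (between sources) or $n(n-1)/2$
(within a source) pairings of their metabolisms. The canonical design (50
sources, 20 metabolisms each) gives the denominators 999, 400 and 190;
the package keeps them general (`populationPairCounts()`) so populations
of any size work, and recovers the canonical constants in tests.

The no-exchange null model asks what a pair would gain without
metabolite transfer: if members are viable on an additional source with
probabilities $p_i, p_j$ (estimated per metabolism as additional viable
sources over $n_{\mathrm{sources}}-1$), the pair covers a source with
probability $1-(1-p_i)(1-p_j)$, and the expected additional-source count
is $(n_{\mathrm{sources}}-2)$ or $(n_{\mathrm{sources}}-1)$ times that,
for different or identical primaries. Observed gains (sources outside
both individual profiles where the pooled pair grows) are compared with
this expectation by an exact two-sided binomial sign test with ties
dropped (the tie rule is the package's choice; the test itself follows
the analysis design). The augmentation control — single metabolisms
padded with randomly drawn reactions rather than a partner's functional
network — is compared by a chi-squared two-proportion test
(`twoProportionTest()`).

## The carbon-source network

`buildCarbonNetwork()` turns the $\bar s_p$ matrix into a weighted
network over carbon sources. The display threshold 0.55 applies only to
the thresholded igraph view; analysis runs on the full weighted matrix.
`corePeriphery()` fits the two-role disassortative pattern (core–core and
core–periphery dense, periphery–periphery sparse) by maximizing the
Pearson correlation between the off-diagonal weights and the ideal
pattern, with greedy single-node refinement from 50 random restarts under
a fixed seed — the fit is deterministic given the seed and invariant
under node relabelling. A node whose mean weight to the periphery
exceeds its mean weight to the core by more than `outlierMargin`
(default 0.15) contradicts both roles and is reported as an outlier,
mirroring the "ties the periphery strongly but not the core" anomaly
pattern. Uniform-weight networks are flagged degenerate with a warning
rather than partitioned arbitrarily. `assortativityWeighted()` reports
the strength-assortativity of the weighted network; core–periphery
structure shows up as a negative value.

## The synthetic reaction universe

Real curated genome-scale models and reaction universes are inputs the
user supplies (`readUniverse()`, tab-separated tables or SBML Level 3).
Everything else is exercised on synthetic universes built by
`generateUniverse()` from a `universeSpec()`:

* each carbon source $C_k$ has an extracellular species, a transport
  reaction ($C_k^{ext} \to C_k$), and an upstream pathway of
  `pathwayLength` reactions into a shared trunk;
* the trunk (`nSharedIntermediates` species) ends in a distribution
  reaction producing three biomass precursors consumed jointly by the
  single biomass reaction;
* every non-transport pathway reaction exists in `nBranchRedundancy`
  parallel copies, giving the sampler and the reducer redundancy to act
  on;
* decoy reactions interconvert a separate metabolite pool, never touch
  the biomass route (hence carry zero flux in seeds), and model the
  large neutral fraction of a real reaction universe.

All stoichiometric coefficients are 1, so every pathway yield equals the
carbon uptake bound and can be checked by hand. Defaults — 5 carbon
sources, pathway length 3, redundancy 2, 2 trunk intermediates, 40
decoys, 1 transport per source, seed metabolisms holding 45% of the
universe — were chosen once to reproduce the qualitative regime of the
genome-scale study: walked metabolisms are viable on few sources beyond
their primary, while pairs frequently complete each other's upstream
pathways. What the synthetic universe does *not* emulate: mass/energy
conservation at the atomic level, cofactor coupling, thermodynamic
constraints, and the heavy-tailed connectivity of real metabolism — so
green tests demonstrate the correctness and behaviour of the machinery,
not quantitative genome-scale predictions.

`plantComplementarity()` cuts a single-copy route at a chosen upstream
position into two templates — neither viable on the planted source, the
pooled pair viable, the designed minimum exchange exactly the one cut
metabolite — and optionally grafts full single-copy routes so each
template is viable on its own primary, which is the fixture used for the
essentiality cross-classification. `generateNullPopulation()` includes
complete routes all-or-nothing with known probability $p$, so pairs are
non-interacting by construction and the null-model formula is exact for
them.

## Problem sizes and numerical choices

The shipped analyses run at desk scale: the headline study uses 5 carbon
sources × 5 metabolisms with 2,000-step walks (300 pairs), the sampler
invariants 10 walks × 500 steps, the null-model recovery 10,000
simulated pairs, the minimal-exchange cross-check 50 instances on
12-metabolite universes, and the network recovery 100 planted 9–14-node
networks. These sizes make the whole pipeline reproducible in minutes on
one CPU while preserving every qualitative contrast of the genome-scale
design (individual vs null vs pair gains, planted recovery at 100%).

Numerical conventions: LP pivot tolerance $10^{-10}$; fluxes below
$10^{-9}$ clamped to zero before the strict `> 0.001` viability
comparison; the FVA optimal face fixed at a relative $10^{-9}$; pooled
vs explicit equivalence asserted at $10^{-6}$; branch-and-bound prunes
with integer-ceiling bounds at $10^{-6}$ slack. Degenerate inputs —
infeasible systems, unbounded flux cycles in variability analysis,
saturated swap proposals, unreachable reduction targets, uniform
networks — are either handled (reported as zero growth / infinite range)
or raised as named errors rather than silently mis-answered.

## Known limitations

* The sampler asserts viability-preserving reachability, not detailed
  balance; as in the original design, uniformity over the viable space is
  an approximation justified by divergence, not proved.
* The minimal-exchange MILP fixes one optimal set; biologically distinct
  equal-size exchange sets are not enumerated.
* Exchange is cost-free and direction-agnostic; energetic cost, toxicity
  and ecological feasibility of exchange are explicitly outside the
  model.
* The aggregate-vs-per-compound biomass question above is resolved in
  favour of the aggregate objective; per-compound demands would be
  stricter for fragmentary networks.
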