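# SynFBA

**De novo syntrophy in random viable metabolisms, by flux balance
analysis.**

Syntrophy — a pair of organisms growing on a substrate neither can use
alone, by exchanging metabolites — is usually explained as the product of
degenerative co-evolution. SynFBA implements the alternative test: sample
metabolisms *at random* from the space of reaction networks viable on a
primary carbon source (so they share no evolutionary history), let pairs
exchange metabolites, and measure how often new carbon sources become
usable. The package is aimed at researchers in constraint-based
metabolic modelling and microbial ecology who want to run, extend or
scrutinize this analysis.

## What it computes

For a metabolism pair $(A, B)$ and carbon source $C_k$, with $G$ the FBA
biomass optimum of the pooled reaction set under a minimal medium with
$C_k$ bounded at 10 flux units, the pair is **syntrophic** on $C_k$ iff

$$G(A,A,C_k) = 0, \quad G(B,B,C_k) = 0, \quad G(A,B,C_k) > 0,$$

growth below the 0.001 threshold counting as zero. On top of this
predicate the package provides:

* a viability-constrained **MCMC reaction-swap sampler** (delete one
  reaction, insert one absent universe reaction, accept iff viability on
  the primary source survives), plus size reduction and the
  random-augmentation control;
* the **explicit two-compartment exchange model** (equivalent to pooling
  when all metabolites are transferable) and the **minimum number of
  exchanged metabolites**, by branch and bound over binary transfer
  gates with an exhaustive oracle;
* **syntrophic potential** $\bar s$ (fraction of a metabolism's pairings
  that are syntrophic), **carbon-source pair syntrophic potential**
  $\bar s_p$, the **no-exchange null model**
  $(n-2)\,[1-(1-p_i)(1-p_j)]$ with an exact sign test, and per-source
  syntrophy incidence;
* the **carbon-source syntrophy network** with core–periphery
  (disassortative) structure detection and weighted assortativity;
* a **synthetic reaction-universe generator** (multi-source pathways
  through shared intermediates, redundant routes, decoy reactions,
  plantable complementary pairs) so the full pipeline runs with no
  external model downloads;
* readers/writers for a tab-separated reaction-table format, minimal
  SBML Level 3 import, and JSON-lines metabolism populations.

FBA itself runs on the package's own bounded-variable two-phase simplex
(C++), cross-checked in the tests against an independent implementation.

## Worked example

```r
library(SynFBA)

gen  <- generateUniverse(universeSpec(seed = 1))
gen$universe
#> ReactionUniverse: 80 reactions, 45 metabolites
#>   biomass: R_biomass | transport: 5 | reversible: 8
#>   extracellular metabolites: 5 | medium: (none)

samp  <- samplePopulation(gen$universe, gen$seeds, perSource = 2,
                          nSteps = 500, seed = 42)
pairs <- pairSyntrophy(samp$population, gen$universe, gen$sources)
head(pairs[nzchar(pairs$syntrophicSources), c(1, 2, 5, 6)], 3)
#>     labelA   labelB syntrophicSources nJointAdditional
#> 4 C1_ext.1 C3_ext.1            C5_ext                1
#> 6 C1_ext.1 C4_ext.1            C2_ext                1
#> 9 C1_ext.1 C5_ext.2            C3_ext                1

round(head(syntrophicPotentials(pairs), 4), 3)
#> C1_ext.1 C1_ext.2 C2_ext.1 C2_ext.2
#>    0.333    0.333    0.111    0.111
```

Each pair row records the carbon sources on which the pooled pair grows
although neither member does (here, e.g., the two metabolisms sampled on
`C1_ext` and `C3_ext` jointly unlock `C5_ext`); the syntrophic potential
is the fraction of a metabolism's pairings that yield at least one such
source.

The full study design — walk long enough to randomize the reaction
complement, then screen all pairs against the no-exchange null model —
is one call:

```r
res <- runPipeline(runConfig(perSource = 5, nSteps = 2000, seed = 1))
syntrophyReport(res)
#> population: 25 metabolisms, 5 carbon sources, 300 pairs
#> swap acceptance rate: 85.1% - 88.3%
#> mean additional sources, single metabolism: 0.400 (sd 0.645)
#> null expectation for pairs (no exchange): 0.604 (sd 0.647)
#> mean additional sources gained by pairs: 0.927 (sd 0.806)
#> fold vs single: 2.32 | fold vs null: 1.53
#> sign test observed vs null: p = 4.01e-06
#> syntrophic potential: median 0.708, range [0.292, 0.917]
#> most syntrophic carbon source: C5_ext (share 27.0%)
#> network: 2 core / 3 periphery / 0 outlier nodes, assortativity -0.175
```

Pairs gain significantly more carbon sources than the no-exchange null
expects (sign test), every metabolism participates in some syntrophy,
and the carbon-source network is disassortative — the qualitative
signature of spontaneously emerging syntrophy, at desk scale.

## Documentation

The methods vignette (`vignettes/synfba-methods.Rmd`) describes the
growth model and exchange conventions, the sampler, the minimal-exchange
MILP, the null model, the network analysis, what the synthetic universes
do and do not emulate, the numerical tolerances, and known limitations.
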