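---
title: "Models and methods: metastatic-primary divergence on simulated tumors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: metastatic-primary divergence on simulated tumors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpdiverge)
```

## The problem

When a paired primary tumor and metastasis are sequenced, their genomic
divergence is usually summarized by two branch lengths: the number of
somatic variants substantially present in the metastasis but undetectable
in the primary (`B_m`), and the converse count (`B_p`). "Substantial
presence" and "absence" are operationalized by two variant-allele-frequency
thresholds, `gamma` (default 0.2) and `alpha` (default 0.01): a variant
contributes to `B_m` when its pooled metastasis VAF exceeds `gamma` while
its pooled primary VAF stays below `alpha`. Interpreting these counts as a
clock for *when* the metastasis seeded is common practice but, as this
package lets you explore, only valid under particular growth dynamics of
the primary tumor.

The package provides three coordinated layers:

1. a single-cell spatial simulator of paired primary/metastatic growth with
   full lineage tracing;
2. tree-based definitions of the divergence elements — detectable
   ancestors, the most recent detectable ancestor (MRDA) of the seeding
   cell, and the pre-dissemination branch `B_md` — together with virtual
   multi-region sequencing that measures `B_m`/`B_p` the way a sequencing
   study would;
3. a closed-form branching-process model of the expected `B_md` and `B_p`
   as functions of seeding time, detectability and growth mode.

## The spatial growth model

Growth starts from a single founder cell at the center of a 3D integer
lattice with the 26-cell Moore neighborhood. Cell `i` divides at rate
`lambda0 * m_i * psi_i`, where `psi_i` is its fraction of empty Moore
neighbors and `m_i` its inherited birth-rate multiplier; one daughter keeps
the mother's site, the other fills a uniformly chosen empty neighbor. The
default `lambda0 = 0.25`/day encodes a four-day mean cell cycle. Each
daughter birth gains one new passenger variant with probability `u = 0.15`
(a Poisson(`u`) option exists) and, independently, a driver with
probability `ub`; the driver's selection coefficient is drawn from a
Gaussian with mean `s` and sd `s/2`, truncated at zero by resampling
(coefficients are beneficial by definition; a raw Gaussian has negative
mass). A driver multiplies the lineage's birth rate by `1 + s`. Variants
follow the infinite-allele convention: every gain is a new variant id;
the uniform genomic coordinates (5e7 positions for passengers, 2e5 for
drivers) are bookkeeping labels only.

**Death is density-modulated by default.** The death rate of cell `i` is
`mu * psi_i`, mirroring the birth rule. This choice is load-bearing: it
makes the embedded per-cell process along active lineages an exact
`lambda:mu` branching process, so the extinction probability of a founder
is `rho = mu/lambda0`, the expected number of births to reach `N` cells is
`N/(1-rho)`, and the tumor interior is dense and quiescent (a sphere of
radius 6.3 lattice units holds on the order of a thousand cells). Applying
the death rate uniformly to all alive cells instead (available as
`densityDependentDeath = FALSE`) hollows the interior to density `1-rho`,
inflates total births, and makes near-critical growth (`rho = 0.99`) to
large sizes impossible — none of which matches the growth regimes the
divergence analysis targets.

Growth regimes are set by `(rho, s, ub)`: fast growth with weak selection
(`rho = 0.72`, `s < 0.05`) gives progressive diversification; moderate
selection (`s = 0.1-0.2`) branched evolution; near-critical growth with
strong selection (`rho = 0.99`, `s >= 0.5`) linear evolution with recurrent
sweeps. Near-critical fronts are heavily ramified, so the lattice allocates
a much wider margin there (the growth cluster can reach several times the
dense-ball radius).

Metastatic seeding is monoclonal and size-triggered: each time the primary
first reaches `I * Ns` cells, the next-born cell disseminates — it is
recorded but never occupies a primary lattice site — and can be grown into
a metastasis on a fresh lattice at `rhoMet = 0.72` with all other
parameters inherited and its full variant set clonal. Extinct metastasis
attempts (probability ~`rhoMet` each) are refounded from the same genotype
until one survives; the retry count is recorded. The defaults `Ns = 25000`,
`Nfinal = 1e7` reproduce a sequence of 400 virtual metastases; desk-scale
work in this vignette and in the tests uses `Nfinal = 1e5`, `Ns = 2.5e3`,
metastases of `5e4` (40 seeding events per primary), which keeps a full
five-replicate batch within minutes on one core.

```{r quick-sim}
p <- simParams(rho = 0.72, sMean = 0.02, ub = 1e-5, Nfinal = 2e4, Ns = 5e3)
prim <- simulatePrimary(p, seed = 1)
prim
seedingEvents(prim)
```

## Tree-based divergence elements

For an observation set of cells (by default all cells alive at observation)
a cell is a *detectable ancestor at threshold `a`* (DA) if its observed
descendants make up at least a fraction `2a` of the observation set — the
factor 2 converts a VAF threshold to a cancer-cell fraction under the
heterozygous-diploid assumption. The *most recent detectable ancestor*
(MRDA) of a seeding cell is the deepest DA on its root path; it always
exists because the founder has fraction 1.

With `k` the seeding cell's total variant count, the tree-based elements
are:

* `bmd_variants = k - variants(MRDA_alpha)` — the pre-dissemination part of
  `B_m`, i.e. the branch from the seeding cell back to its MRDA measured in
  variants;
* `bmd_generations` — the same branch in cell divisions;
* `bp_tree` — the variant-weighted total branch length of the DA-gamma
  genealogy minus the founder-to-MRDA-gamma branch of the seeding cell: the
  tree counterpart of `B_p`.

`B_md` is not monotone in seeding time: if an ancestor of the seeding cell
founds a subclone that later becomes detectable, the MRDA jumps forward and
`B_md` collapses to the few variants gained since — the mechanism behind
the zigzag pattern of `B_m` under selective growth.

```{r tree}
dt <- divergenceTree(prim, alpha = 0.01, gamma = 0.2)
head(dt)
```

### Which cells define "the fraction of the primary"?

Two observation frames are supported. Pure tree analyses default to all
alive cells. The paired-measurement pipeline (`divergenceSeries()`)
defaults instead to the union of the sampled regions: measured `B_m` exists
only relative to what the sequencing saw, and evaluating the tree threshold
on a different cell set injects spatial-sampling disagreement into the
tree/measurement comparison that has nothing to do with either definition.
At full scale the two frames converge; at desk scale the sampled frame is
the one under which the tree branch explains the measured divergence the
way it should (`treeObserved = "alive"` switches back).

## Virtual multi-region sequencing

Ten spherical regions of radius 6.3 lattice units (about a thousand cells
each on a dense tumor) are centered on uniformly chosen occupied sites;
overlap is allowed (a `disjoint` flag exists for sensitivity checks), and
spheres near the surface simply contain fewer cells. Per variant and
region, sequencing depth is `D ~ NegBinom(mean = 100, size = 10)` — the
`size` (dispersion) parametrization gives `Var(D) = 100 + 100^2/10` — and
the alt count is `M ~ Binom(D, F)` with `F` the carrier fraction over twice
the region size (heterozygous variants). Zero depth reads as frequency 0.
Pooled frequencies are read-weighted: `f = sum(M)/sum(D)` across regions.
`B_m` and `B_p` then apply the strict threshold pair to the pooled
frequencies of the two tumors over the union of their variant universes;
a variant private to one tumor has exactly zero carriers in the other, so
its frequency there is exactly 0 and is not re-drawn.

Between-region divergence within a tumor is summarized by a Hudson-style
fixation index: per variant the squared frequency difference minus the two
within-region sampling corrections, and the cross-products in the
denominator, are each summed over variants before the ratio is taken;
`fstMean()` averages the estimate over all region pairs.

```{r vseq}
set.seed(1)
rs <- sampleRegions(prim, nRegions = 10, radius = 6.3)
rs
sq <- virtualSequence(regionCarrierMatrix(prim, rs))
fstMean(sq)
```

The full paired pipeline — regions, sequencing, tree elements, one
metastasis per seeding event (each on its own RNG substream, so adding one
does not perturb the others) — is `divergenceSeries()`:

```{r series}
ds <- divergenceSeries(prim, metTarget = 1e4, seed = 1)
ds[, c("seed_index", "size_fraction", "k", "bmd_variants", "B_m", "B_p")]
```

## The analytic model

The non-spatial model follows a supercritical birth-death process
conditioned on survival, `N(t) = (1/rho) e^{lambda t} - (1/rho - 1)
e^{-lambda t}`. Variants along the seeding cell's lineage appear with
exponential waiting times of rate `u * lambda`, so the `j`-th lineage
variant maps to absolute population order `g(c_j) = u * N(j/(u*lambda))`
(the birth rate cancels). Its probability of ending up detectable at
population frequency `f` is

`d_j = (u / (u - log(1 + (rho - 1) f)))^{g(c_j)}`,

a strictly decreasing sequence pinned to `d_0 = 1` (the founder variant is
clonal; the raw formula at `g = u` is slightly below 1 and the clonality
argument overrides it). The number of undetectable lineage variants at
seeding time `k` then has the telescoping pmf `Pr[B = k - j] = d_j -
d_{j+1}`, whose mean `expectedBmdNeutral()` also evaluates directly. Under
neutral growth the expectation is monotone with two phases: a near-flat
start whose total mass (`sum_j d_j`) grows with `rho`, then unit-slope
growth once new variants are almost surely undetectable. The expected
primary-specific branch follows as `B_p(k) = |M| - k + B_md(k; gamma)`,
with `|M|` the number of detectable primary variants; it is flat where
`B_md` has unit slope and tracks its drops.

Advantageous types break the monotonicity. A chain of nested types (type 1
arising inside type 0 at clock index `T_1` and reaching final fraction
`f_1`, etc.) mixes neutral expectations with rescaled thresholds: the
type-`i` branch uses clock `k - T_i`, ratio `rho_i` and threshold
`2*alpha/f_i` (the variant must reach `2*alpha` of the whole tumor from
inside a subpopulation of final fraction `f_i`); the type-0 branch uses
`2*alpha/(1 - f_1)`. The seeding-origin weights implement three scenarios:
`most_advanced` (all mass on the newest extant type), `fitness_proportional`
(weights by birth rate; by default `lambda_i` is proportional to `1/rho_i`,
i.e. a shared death rate), and `uniform` (weights by expected type sizes;
size ratios are governed by the net growth rates `lambda_i - mu` over the
elapsed clock `(k - T_i)/u`, so a fitter late type overtakes gradually —
the mechanism behind the gradual monotonicity change under purely
stochastic seeding).
The reported standard deviation is the between-origin component
`sqrt(sum_i phi_i E_i^2 - E^2)` — the variability induced by the
uncertainty in the seeding origin, which is exactly zero under the
deterministic `most_advanced` scenario and widens after each introduction
under the other two.

```{r analytic}
ts <- typeStructure(rho = c(0.95, 0.93, 0.83), Tk = c(0, 6, 13),
                    f = c(1, 0.873, 0.771), scenario = "most_advanced")
curves <- analyticCurves(21, structure = ts)
curves$E_bmd
```

**On the introduction clock.** The analytic clock is `k`, the number of
variants on the seeding lineage. Type-introduction indices `Tk` are
parameters on that clock. For illustrative configurations specified by the
population size at introduction, this package places `T` at the population's
e-folding age, `T = round(log(rho0 * N_intro))` — e.g. introductions at 600
and ~4.6e5 cells give `T = (6, 13)` with detection around `k = 21` for a
~1e9-cell tumor. Converting instead through the lineage variant clock
(`k = u * log(rho * N)`) collapses every introduction to `k <= 2` at
`u = 0.15` and erases the drop structure entirely, so it is not used.

## Series statistics

`runningStats()` (centered truncated windows, default 20 events) feeds the
zigzag partition — a percent-reversal filter (default 10%; when an extremum
is 0 the threshold falls back to a fraction of the series mean so count
series stay segmentable) — and `valleyDetection()`, which flags positions
where the observed running mean falls below the pointwise 5th percentile of
running means over shuffles of the series (1000 by default; the literal
"below 5% of the mean of the randomized data" reading is available behind
`literalFraction`). Shuffling whole values is the randomization unit.
`detectExpansions()` reports every cell whose descendants reach 5% of the
final sampled population, with the primary size fraction at its birth; and
`cooccurrenceTest()` asks whether those birth times fall inside
drop/valley intervals more often than chance, restricting to growth beyond
20% of final size and building the null by circularly shifting the
intervals within that domain (which preserves their number and lengths).
Heteroscedasticity of a divergence series over seeding order is assessed
with White's test (auxiliary regression of squared residuals on the
regressor and its square). Permutation p-values use the add-one convention
`(1 + #{perm >= obs})/(n + 1)`.

## Numerical and design choices

* **Event scheduling** is an exact Gillespie loop; cells are selected by
  rejection sampling against the bound `26 * maxMult` (birth) or `26`
  (death), which is exact, and the running rate sums are rebuilt exactly
  every 2^16 events to cancel floating-point drift.
* **Seeding-site bookkeeping**: the disseminating newborn never occupies a
  primary site, so no vacancy or `psi` update is needed; its recorded
  coordinates are the site it would have filled.
* **Drivers and passengers** can be gained at the same birth
  (independent draws).
* **Lattice margins**: dense regimes use twice the dense-ball radius plus a
  fixed pad; near-critical regimes (`rho > 0.9`) use eight times, reflecting
  the measured ramification of surviving near-critical clusters.
* **Ties and boundaries**: threshold comparisons on measured frequencies
  are strict (`> gamma`, `< alpha`) as printed; tree-side fractions use
  `>=` on the CCF cut. Zero-depth observations count as frequency 0.
* **Degenerate inputs**: a seeding cell with zero variants has an undefined
  detectable fraction (`NA`, excluded from averages); `expectedBp()` clamps
  negative values to zero with a warning; Fst with a zero denominator is
  `NA` and region pairs with depth < 2 at a variant drop that variant.

## What the desk-scale simulations do and do not show

The reference experiments behind the bundled checks use primaries of 1e5
cells (40 seeding events each, metastases of 5e4, five seeds per regime).
These sizes preserve the qualitative structure — peripheral growth, the
B_md/B_m correspondence, the passenger-rate slope, heteroscedastic series
under selection, the Fst contrast between branched divergence and
linear-evolution convergence — but three full-scale phenomena are
attenuated and should not be over-read:

* the driver supply scales with total births, so a 1e5-cell run at
  `ub = 5e-5` carries ~20 drivers where a 1e7-cell run carries ~2000;
  deep staircase patterns of `B_p` and near-complete sweeps need the
  larger supply, and the `B_p` tree/measurement regression has very little
  variance to explain at desk scale;
* lineage depths span tens of generations rather than hundreds, so
  variant-count correlations (e.g. mutation burden vs distance to center)
  are attenuated by Binomial(`g`, `u`) thinning even where the underlying
  division-depth signal is strong;
* the detectable fraction of the seeding lineage under branched growth
  sits a few points below its full-scale value for the same reason.

Simulated tumors also idealize real data: pure diploid cells, heterozygous
variants, fair detection at `alpha`, no purity/ploidy confounding, no FFPE
artifacts, and no intra-tumoral migration (`mIntra = 0`). Passing tests
bound the model's internal consistency, not the fidelity of any of those
assumptions to a given cancer.
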