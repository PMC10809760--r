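---
title: "Respiratory guilds, redox zones, and decay kinetics in hadal sediment MAG collections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Respiratory guilds, redox zones, and decay kinetics in hadal sediment MAG collections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hadalguilds)
```

## The scientific problem

Hadal trench sediments develop a sharp redox zonation within the first
decimeters: aerobic respiration depletes oxygen within a few centimeters
(here 2.6–4.1 cm across sites), nitrate/nitrite and Mn respiration carry the
*nitrogenous* zone down to roughly 8 cm, and below that ferrous iron
accumulates (*ferruginous* zone). Because these sediments are essentially
unbioturbated, depth doubles as time: with a constant sedimentation rate
$\omega$ (mm yr⁻¹), a horizon at depth $z$ cm has age

$$a(z) = \frac{10\,z}{\omega}\ \text{years}.$$

The package asks how the *functional composition* of the microbial community
— read from the gene content of metagenome-assembled genomes (MAGs) — tracks
this zonation, and at what rate guilds adjusted to one electron acceptor are
replaced once that acceptor is gone. The core quantitative object is the
exponential decay (or growth) of a guild's relative abundance against
sediment age, summarized as a half-life $t_{1/2} = \ln 2/\lambda$ (decay) or
doubling time (growth).

## Guild classification rules

Each MAG is mapped to capability flags from its annotated gene content:

* **Aerobic**: any of three terminal-oxidase classes (cytochrome *c*
  oxidase, *cbb3*-type, *bd* ubiquinol oxidase) with module completeness
  $\ge 50\%$. A module is an ordered list of steps, each a set of
  alternative orthologs; completeness is the fraction of steps with at least
  one alternative present. The 50% comparison is made on integer step counts
  (`2 * hits >= n_steps`), so exactly half passes and no floating-point
  artifact can flip the boundary case. Module definitions are *input data*
  (KEGG content is versioned); the package ships three illustrative
  three-step definitions only.
* **Taxon override**: ammonia-oxidizing archaea of the family
  *Nitrosopumilaceae* carry a Complex IV too divergent for ortholog-based
  module annotation; membership in a configurable override family list
  (default exactly that family) marks a MAG aerobic regardless of module
  hits. The override is applied at family rank after stripping GTDB rank
  prefixes.
* **Nitrogen**: seven marker rules — napAB (both subunits), narGHI (≥ 2 of
  narG/narH/narI), nrfAH (both), nirBD (both), nirK/S (≥ 1), norBC (≥ 1),
  nosZ (present). A *full denitrifier* has a nitrate reductase plus nirK/S,
  norBC and nosZ. The both-subunit readings for napAB/nrfAH/nirBD follow the
  joint gene naming; single-subunit hits in draft genomes are commonly
  fragments. narGHI's "≥ 2" and nirK-S/norBC's "≥ 1" are explicit printed
  thresholds.
* **Sulfur**: dsrAB, by default both subunits (configurable to ≥ 1). The
  flag is deliberately "dsrAB present", not "sulfate reducer": the enzyme
  also runs oxidatively in some lineages and the package does not resolve
  direction.
* **Metal**: copied from a per-MAG porin-cytochrome homolog flag table
  (emulating FeGenie output); the package performs no homology searching.
* **Fermenter** (operational): none of the four capabilities above. Such
  genomes may respire via pathways outside the rule set; the label is a
  hypothesis about dominant lifestyle, not a measurement.

The rule engine is validated against an independently written truth-table
oracle on the exhaustive $2^{12}$ subsets of the relevant marker universe,
and is monotone: adding genes can never remove a capability, and the
fermenter flag is antitone in gene content.

## Zones, abundances, profiles

Horizon intervals are half-open `[top, bottom)` centimeters below the
sediment surface; wherever one depth per sample is needed the midpoint is
used. A sample's zone follows from comparing its midpoint with the site's O2
and NO3 penetration depths; ties at a boundary go to the deeper zone. Which
convention (midpoint, top, containment) underlies published zone labels is
usually unstated; the midpoint rule was chosen once and is encoded in the
tests. Redox boundaries in real cores wobble by a couple of centimeters, so
`annotate_zones(boundary_buffer_cm = )` can flag near-boundary samples as
`transitional` for exclusion from per-zone summaries.

Relative abundance of MAG $i$ in sample $s$ is its mean mapping coverage
over the summed coverage of all MAGs in the sample,
$p_{is} = c_{is}/\sum_j c_{js}$. Group profiles sum member abundances; a MAG
with two capabilities contributes fully to both guilds (guild rows are not a
partition), while taxon or stratum partitions conserve the per-sample total
of 1. Depth profiles report mean ± SE ($\mathrm{sd}/\sqrt{n}$) across the
sites sharing a horizon; horizons present at a single site get `NA` SE.

CAZyme family abundance is *presence-weighted*: the abundance of a family is
the summed relative abundance of the MAGs carrying it at all, so copy number
does not enter. Secretion strata count the *distinct* CAZyme families with
at least one signal-peptide-positive copy per MAG, binned into eight groups
{0, 1, 2, 3, 4, 5, 6–8, >8}. Published analyses alternate between "CAZymes",
"CAZyme genes" and "CAZyme families" and do not list the bin edges; both
choices here (distinct families; these bin edges) are package decisions,
with copy-based counting available behind `count_basis = "copies"` and the
bin table fully configurable.

## Kinetics

Decay/growth fits are ordinary least squares on $\ln(\text{abundance})$
against age; $\lambda$ is the negated (decay) or plain (growth) slope and
$t_{1/2} = \ln 2/\lambda$. Choices that matter:

* **Window.** Decay fits default to the ferruginous zone: from the site's
  NO3 penetration depth to the deepest horizon. Growth fits use an explicit
  window, by default 6.5–9.5 cm, the depth interval in which putative
  fermenters grow exponentially before plateauing.
* **Zeros.** Zero abundances cannot enter a log fit; they are dropped and
  counted, and if more than half of the window points are zero the fit is
  refused rather than silently fitted on a remnant.
* **Sign.** A fitted slope contradicting the requested direction returns a
  flagged (`converged = FALSE`) result rather than an error, so a sweep over
  sites and guilds completes and reports which fits are meaningless.
* **OLS vs NLS.** `method = "nls"` refits on the natural scale starting
  from the OLS solution. The two weight noise differently (log-space OLS is
  maximum likelihood under multiplicative lognormal noise, which is how the
  simulator generates data); both agree exactly on noise-free input, which
  the tests assert.
* **Ranges.** Cross-site summaries are the (min, max) of per-site
  half-lives — no pooled fit — matching how such ranges are quoted.
* The constant-total-community assumption (total cell abundance roughly
  flat over depth) is inherited throughout: relative abundances are treated
  as proportional to cell densities. Where it fails, "half-life of relative
  abundance" is still well-defined but no longer a cell-decay rate.

## The statistics layer

Bray–Curtis dissimilarities, the Hellinger transform
($h_{sf}=\sqrt{x_{sf}/\sum_f x_{sf}}$), classical-scaling PCoA, covariance
PCA, one-way PERMANOVA (Anderson's pseudo-F) with pairwise tests and
Benjamini–Hochberg adjustment, Welch's *t*, and Ward clustering
(`"ward.D2"` on Euclidean distances) for heatmap ordering. Numerical
conventions: permutation p-values use the add-one estimator
$(1+\#\{F^\pi \ge F\})/(1+B)$ and are therefore never 0; the permutation
stream is seeded and samples are internally ordered by label, so p-values do
not depend on input row order; PCoA reports negative eigenvalues rather than
dropping them, with a Cailliez-corrected variant behind a flag; PCA is
covariance-based on Hellinger-transformed data (the standard pairing —
correlation-based PCA would undo the transform's variance structure); Ward
rows are pre-sorted lexicographically so tie-breaks are deterministic.
PERMANOVA calibration is checked empirically: under a true null the type-I
error at $\alpha = 0.05$ over 1000 simulations (20 samples, 2 groups, 999
permutations) must land in [0.035, 0.065].

## The synthetic community simulator

No sequence data ships with the package; every downstream stage is tested
against a simulator with planted, recorded truth.

**What it emulates.** Six hadal sites; 1-cm slices to 10 cm and 2.5-cm
slices to 30 cm (the coring protocol's resolution, truncated to the depths
that matter for the kinetics); per-site O2 penetration spanning 2.6–4.1 cm,
NO3 penetration 7.6–8.4 cm, sedimentation rates spanning exactly 0.29–0.76
mm yr⁻¹; respirer half-lives spanning 135–419 yr; fermenters doubling every
1.4 cm within 6.5–9.5 cm. Eight MAG archetypes (strict aerobe,
aerobe+nitrogen dual, Nitrosopumilaceae-like nitrifier, cbb3-carrying
anammox-like, dsrAB carrier, metal reducer, fermenter, filler) receive gene
content that is *sufficient and necessary* to trigger exactly their intended
flags, which makes the classifier round-trip an exact test. The
aerobe+nitrogen archetype outnumbers the strict aerobe (50 vs 30 MAGs, with
every second dual MAG a full denitrifier), reflecting that most
oxidase-carrying genomes in such collections also carry nitrogen-respiration
markers. Fermenter CAZyme repertoires draw distinct-secreted-family counts
from a zero-inflated geometric so all eight strata are populated.

**Trajectory family.** Expected relative abundances are piecewise
log-linear in age with C0 continuity. Above the ferruginous top the shapes
(surface levels, a mild dual-archetype peak, a nitrifier surface maximum,
rises of anammox/sulfur/metal toward the nitrogenous zone) are free
simulator parameters — no claim of realism is attached to them, since
within-zone trends of non-focal guilds are not constrained by published
values. Below the ferruginous top *every* aerobic/nitrogen-capable
archetype decays at the site's single planted rate, so guild sums (sums of
same-rate exponentials) are exactly exponential and noise-free recovery is
exact to floating-point; the tests assert ≤ 1e-9 relative error. One planted
rate per site for both fitted guilds is a simplification the data support:
reported aerobic and nitrate-reducer half-life ranges are nearly identical.

**Closure.** A `filler` archetype takes up the complement so that total
expected coverage is exactly constant over depth — the constant-total
assumption built in by construction. The filler carries dsrAB (sulfur
guild), which is never kinetically fitted, so closure never distorts a
fitted quantity. If configured surface levels plus the fermenter peak ever
exceed the total, the simulator refuses rather than renormalizing (which
would silently bend the planted exponentials).

**Noise.** Observed coverage multiplies the expectation by lognormal(0, σ)
noise, σ = 0.3 by default — multiplicative, positive, heavy-tailed, as
coverage data are. Nothing else is noisy: completeness/redundancy are
cosmetic draws, and gene content is deterministic given the archetype.

**What passing tests do not show.** The simulator plants clean single-rate
exponentials, independent noise, perfectly aligned horizons across sites,
and gene content with no annotation error. Real MAG collections violate all
four (incomplete genomes lose marker genes; coverage noise is correlated
within samples; cores differ in slicing; exponential decline is itself a
model choice). Recovery results here therefore validate the *estimator*,
not the biology: they show the pipeline returns the truth when the model
holds.

## Problem sizes and runtime choices

Default simulations use 168 MAGs × 108 samples (6 sites × 18 horizons),
which keeps a full pipeline run under a few seconds and a 20-replicate
recovery experiment under a minute; the PERMANOVA calibration uses 1000 null
datasets of 20 samples × 8 features with 999 permutations each. These sizes
were chosen to make the stochastic checks statistically meaningful (binomial
SE of the type-I rate ≈ 0.007; 120 recovery fits) while staying desk-scale.

## Known limitations

* Guild flags are genomic potential, not activity; MAG incompleteness
  biases single-subunit rules downward (hence the configurable ≥ 1
  readings).
* The age model is a constant-rate depth scaling; no compaction correction,
  no lead-210 inversion, no event deposits — at sites with turbidites the
  half-lives inherit the age-model error.
* Half-life ranges estimated from real hadal cores (aerobic on the order of
  135–367 yr, nitrate reducers 154–419 yr) cannot be re-derived without the
  underlying coverage profiles; the package validates by parameter recovery
  on synthetic cores planted across the union of those ranges instead.
* The eight-bin strata composition and the presence-weighting of family
  abundance are documented interpretations of ambiguous published wording;
  both are configurable.
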