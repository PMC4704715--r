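---
title: "Methods: analysing a plate-based extracellular-ATP deletion screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analysing a plate-based extracellular-ATP deletion screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atpscreen)
```

## The measurement and its normalization

The screen measures extracellular ATP in saturated cultures of a yeast
deletion library. Each 96-well source plate is assayed in three biological
replicates; each well yields a culture density (OD660) and a luciferase
luminescence reading (LUM) proportional to ATP in the cleared medium.
Medium-only control plates (eight by default) estimate the optical
background of every well position.

The per-strain score is built in four steps:

1. **Well-specific background.** Each well position's OD660 background is
   the arithmetic mean of that position across all blank plates
   (`compute_background()`). Positions differ systematically (plate optics,
   meniscus shape), which is why the background is per-well rather than a
   single scalar.
2. **Linear-range exclusion.** OD readings outside the reader's linear
   range `[lo, hi]` are flagged and excluded (`apply_linear_range()`). The
   interval is closed at both ends; the bounds are instrument properties
   and must be supplied by the user (defaults 0.1–1.0 OD in the pipeline
   wrapper). Excluded readings propagate as flagged-missing values, never
   as zeros — a zero would contaminate every well mean downstream.
3. **log2 RLU per cell.** `compute_rlu()` computes
   `log2(LUM / (OD660 − background))`. Wells with non-positive net OD or
   zero LUM are flagged (`nonpositive_net_od`, `zero_lum`) rather than
   raising errors: both occur in real screens and must not abort a run.
4. **Positional centering.** `normalize_positional()` subtracts, at every
   well position, the mean log2 RLU of that position over all assay
   plates. This removes well-position effects (edge evaporation, optical
   bias) and, after replicate averaging, any shared plate-level offsets.
   Only valid entries enter the means; after centering, each position's
   across-plate mean is zero to within 1e-9.

Strains are then averaged over replicates (`average_replicates()`); a
strain must be valid in at least two replicates to be scored ("two of
three" rule — slow growers whose OD falls below the linear range in two or
more replicates are excluded with the `excluded_linear_range` flag).
Finally `select_tails()` ranks the scored strains and takes
`floor(fraction × n)` strains per tail — with 4609 scored strains and a 5%
fraction, 230 per tail. `floor` is used because it is the only rounding
rule consistent with a 230-strain tail at that problem size; ties spanning
the cutoff break by strain identifier so the selection is deterministic
under input permutation.

### What per-well centering can and cannot recover

Centering at a well position subtracts the mean score of *all strains that
occupy that position* across source plates. The recovered score of strain
$i$ at well $w$ is therefore

$$\hat e_i = e_i - \overline{e}_w + \varepsilon,$$

where $\overline{e}_w$ is the mean true effect of the strains sharing
position $w$ (one per source plate). With many source plates and a
randomized layout $\overline{e}_w$ concentrates near the global mean and
the distortion is $O(\sigma_{\text{strain}}/\sqrt{n_{\text{plates}}})$;
with few source plates it mixes well-mates' effects into each other's
scores appreciably. This is a property of the centering itself, not of the
implementation: the test suite asserts *exact* recovery (to 1e-9, up to
one global constant) on zero-noise screens whose effects are constant
within each source plate — the layout in which per-well means are equal
across positions and exactness is attainable — and asserts the analytic
identity $\hat e_i = e_i - \overline{e}_w$ on generic zero-noise screens.
Analyses of small simulated screens should use at least ~10 source plates
if planted-set recovery matters.

Two alternative centering schemes are exposed but off by default:
`per_replicate = TRUE` centres each replicate batch separately, and
`per_plate_centering = TRUE` additionally subtracts each plate's median
(a true plate-offset correction). The default — one centering over all
assay plates — matches the screen design this package models.

## Enrichment statistics

`hypergeom_tail()` computes exact hypergeometric tail probabilities by
summation of the probability mass in log space (log-binomial terms
combined with log-sum-exp), so tails of order 1e-60 are returned without
underflow. Upper tails (`P(X ≥ k)`) test over-representation; lower tails
(`P(X ≤ k)`) test depletion. The suite checks the implementation three
ways: against exhaustive enumeration of all draws in small universes,
against the complementary-tail identity
`upper(k) + lower(k−1) = 1` (tolerance 1e-12), and against R's reference
distribution function across parameter grids.

Fold enrichment is `(k/n)/(K/N)` — the set's frequency among hits over its
frequency in the background. The background universe is the set of strains
*with a measured score* (4609 in the screen this models), not the whole
genome; using the genome would overstate enrichment of any category
depleted among measurable strains.

`enrich_terms()` reports raw upper-tail p-values with a 0.01 cutoff and a
2-fold minimum, ordered by descending fold; this mirrors the screen's
reporting. No multiplicity correction is applied by default (a
Benjamini–Hochberg option exists) — with raw p-values and ~50–100 tested
terms, a handful of modest null-term "hits" per analysis is expected, and
the null-calibration test verifies the raw false-positive rate is at (or
below, given tail discreteness) nominal.

Redundancy among enriched terms is trimmed by `trim_redundant()`, which
collapses significant terms whose *hit-gene sets* have Jaccard similarity
≥ 0.8, keeping the smallest-p term (ties: larger fold, then lexical id).
This is a deliberately ontology-free surrogate for DAG-aware trimming
tools: it needs no ontology file, but it cannot distinguish a parent term
from a child term annotating the same hits, and its output is tagged
`trim_method = "jaccard_surrogate"` so downstream consumers know which
rule produced it. Exact agreement with DAG-aware trimmers is out of scope.

`set_overlap_test()` handles the direction-aware question ("is this
labelled list over- or under-represented in a tail?"): the set is first
intersected with the measured universe, the direction is chosen by
comparing `k` to the chance expectation `nK/N` (exact equality counts as
enriched, which makes the reported p ≥ 0.5 there), and the tail p-value is
taken in the direction of deviation. The depletion side is reported as a
lower tail; that convention yields 0.196 for an overlap
of 11 of 230 against a 293-member list in a 4609-gene universe.

## Network statistics

Hit groups are anchored to an undirected functional-interaction network;
`induced_subnetwork()` keeps only edges with both endpoints in the group
("direct interactions"). `summarize_subnetwork()` reports edges per node
with the *mapped group size* in the denominator, isolated mapped nodes
included — excluding isolates would inflate the connectivity of sparse
groups; the alternative denominator is available via a flag since either
reading of "overall average" is defensible. "Modules" are connected
components with more than 5 nodes (strictly), matching the screen's
display rule. Graph primitives (components, induced subgraphs,
deduplication) are delegated to igraph; edge weights are carried through
I/O but ignored by all statistics, which are unweighted counts.

## Retest statistics

Retests compare selected mutants against the parent strain under matched
conditions. The default signal is per-culture background-corrected
luminescence, *not* divided by OD: retest cultures are grown to matched
densities and the retest protocol this models subtracts background rather
than forming the RLU ratio. A `per_cell` flag restores the OD division.
Fold changes are ratios of cell means to the matched reference cell;
significance is a two-sided Student's t-test (pooled variance,
df = n1+n2−2) per cell, Welch by flag, with stars at p < 0.05 / 0.01 /
0.005. Degenerate cells (zero variance on both sides) give p = 1 when the
means agree and a flagged p = 0 otherwise. Tests are unpaired; pairing
structure (day, plate) is not modelled. No multiplicity correction is
applied across retested strains, matching the per-strain reporting the
analysis emulates.

Time-courses use the cultures assayed immediately after inoculation
("0 hr") as the assay background, and report each strain's level
*relative to its own time-zero mean* (a ratio of raw luminescence means),
the normalization retest figures in this field use; subtracting the background and then
dividing by the near-zero corrected time-zero value would be numerically
meaningless. When a background exceeds a sample reading, the corrected
value is floored at a small epsilon with a warning rather than going
negative.

## The synthetic-screen generator

`simulate_screen()` emulates the statistical structure the analysis
assumes, so every stage is testable without external data:

- a strain-effect mixture: baseline effects
  `Normal(0, sigma_strain = 0.5)` log2 units, with planted Low and High
  sets (5% each, shifts ∓1.2) and 2% slow growers;
- measurement: `OD_raw = bg + OD_strain`,
  `LUM = lum_base · 2^(effect + plate_offset + well_offset + ε) · OD_strain`,
  `ε ~ Normal(0, sigma_noise = 0.4)`; log2(LUM/net OD) then recovers the
  effect plus nuisance terms by construction;
- nuisances: centred per-position well offsets (sd 0.3) and per-assay-plate
  offsets (sd 0.2), blank plates with `OD ~ Normal(0.04, 0.005)` and
  near-zero truncated-normal luminescence;
- slow growers receive below-linear-range OD in a random two or three of
  the three replicates, exercising the exclusion rule;
- strains are placed on plates in seeded random order, so planted sets are
  never confounded with layout.

Quantitative noise estimates are not available for the modelled screen, so the noise
scales are chosen to be realistic for saturated-culture luminescence
assays and to leave recovery non-trivial (default screens recover the
planted effects with Pearson r ≈ 0.9, as the test suite verifies); they
are defaults of the generator, not fitted quantities. The generator does
not model luciferase kinetics, cell-lysis contamination, growth dynamics
beyond a saturated-OD draw, or spatial correlation between neighbouring
wells — so passing tests demonstrate correctness of the statistical
machinery under the stated model, not robustness to every artefact a real
reader can produce.

Companion generators plant structure for the downstream modules:
`simulate_annotations()` builds GMT-style term collections whose planted
terms draw a configurable fraction of members from the Low or High set;
`simulate_network()` overlays Erdős–Rényi background edges with dense
planted modules inside the tails; `simulate_retest()` produces endpoint
and time-course retest tables with planted log2 effects and a
relative-to-background rise profile (default: 7.5× background at 21 h,
then plateau).

## Problem sizes and numerical choices

The test suite runs default-scale screens (4609 strains, 155 plates) where
a single pipeline pass is sub-second, and 10-plate screens for
recovery-sensitive checks; null-calibration tests use 2000 simulated
nulls, giving binomial standard errors of ~0.005 at α = 0.05. All
generators are seed-deterministic; identical configurations reproduce
byte-identical outputs. Tolerances: exact identities are asserted at
1e-9–1e-12; stochastic recovery checks use tolerances derived from the
generator's noise scales. Well addresses are case- and
zero-padding-insensitive; missing wells are recorded as absent, never
zero-filled.
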