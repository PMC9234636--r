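---
title: "Auditing ex situ collections: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing ex situ collections: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exsituaudit)
```

## The problem

Botanic gardens and arboreta safeguard threatened plants as living
collections, but how much of a species' wild (in situ) diversity those
collections actually hold is rarely measured. `exsituaudit` implements a
reproducible audit of that question for a diploid, microsatellite-genotyped
species sampled range-wide: what fraction of wild alleles is represented ex
situ, how is that representation distributed across regions and gardens, how
many ideally-sampled wild plants would be needed to reach a target capture
level, and how well do the geographic and ecological footprints of the seed
collection cover the occupied range?

The package was designed around the data structure of a range-wide audit of
a disjunct desert shrub oak: hundreds of wild individuals in tens of
populations split between an eastern and a western region, a few hundred
garden seedlings grown from wild-collected seed and organised in half-sib
maternal families across several institutions, eleven microsatellite loci,
and a few percent missing genotype calls. Nothing in the code is specific to
that layout beyond the defaults.

## Allele capture accounting

The unit of measure is the allele: a `(locus, allele)` pair observed in the
reference cohort. `build_catalog()` pools all reference individuals (two
gene copies per non-missing call) into per-locus counts and frequencies.
`classify_alleles()` bins entries into the four conventional frequency
classes. The stated bins overlap at their boundaries when written as
percentages (5%–10% vs 1%–5%), so the package fixes the half-open-from-below
convention and applies it uniformly:

* rare: `[0, 0.01)`
* low frequency: `[0.01, 0.05)`
* common: `[0.05, 0.10)`
* very common: `[0.10, 1]`

`reduce_catalog()` produces the "reduced" view by deleting entries observed
as singletons or doubletons (≤ 2 copies) in the reference cohort — these may
be genotyping artefacts or strongly deleterious variants. Two deliberate
choices: frequencies are *not* re-normalised after the deletion, and class
labels keep their full-catalog values, so both views share one class
structure and are directly comparable row by row.

`capture_report()` then asks, per class, what fraction of reference entries
occurs at least once among a target cohort's non-missing calls. The
denominator is always the reference catalog: alleles private to the target
are ignored. Regional reports rebuild the reference from the region's in
situ populations only, and take as target the ex situ plants whose *source
population* lies in the region (the plants' physical location is a garden;
what matters is provenance). The East-versus-West contrast is a Pearson
chi-square on the 2×2 table of reference alleles captured versus not
captured per region; Yates continuity correction is applied by default
(matching the common default for 2×2 tables) with `correct = FALSE`
exposed, since the exact construction behind the published test is not
recorded.

## Clone filtering and missing data

Vegetatively spreading shrubs can be sampled twice. `identify_clones()`
flags identical multilocus genotypes *within a population* (clonal spread is
local; a dataset-wide scope is easily obtained by setting one population
label) and keeps the first-encountered member of each group. Matching is
strict: any missing call disqualifies an individual from matching anything.
This is conservative — with eleven polymorphic loci, chance identity of
complete genotypes is vanishingly rare, while imputing through missing calls
would manufacture false clones. `missing_rate()` is the straightforward
fraction of missing individual × locus calls.

## Resampling: accumulation curves and minimum sample sizes

An idealised collector visits wild plants at random and takes one seed or
cutting per plant. `accumulation_curve()` simulates this by drawing, for
each sample size `n = 1..N`, random subsets of `n` individuals without
replacement and recording the mean percent of reference alleles captured.
One uniform permutation yields every `n` at once (an allele is captured by
the first `n` individuals exactly when the smallest permutation rank among
its carriers is ≤ `n`), so a replicate costs one pass over the
individual-by-allele incidence; the kernel is a small C++ routine driven by
R's RNG, making runs bit-reproducible under a seed. A missing call
contributes no alleles, but the individual still occupies a sampling slot,
mirroring a real collection. Replicates default to 75,000 — desk-scale
analyses and this package's tests use far fewer, since the Monte-Carlo error
of a mean over `R` replicates is already tiny at thousands of replicates.

Because sampling is uniform without replacement, the curve has an exact
expectation: an allele carried by `m` of `N` individuals is missed by a
sample of `n` with probability `choose(N - m, n) / choose(N, n)`.
`expected_capture_closed_form()` implements this hypergeometric identity and
serves as the independent oracle for the Monte-Carlo engine in the test
suite (alongside brute-force enumeration of all subsets of a 5-individual
fixture). `minimum_sample_size()` reads the smallest `n` whose replicate
mean meets or exceeds the threshold (ties at exactly the threshold count as
reaching it); the default threshold is 95%.

`fit_log_reference()` supports the cross-species comparison: an OLS fit of
`percent ~ ln(n)` over reference taxa, with `reference_residual()` giving a
focal species' signed departure from that relationship.

## Garden-level diversity and differentiation

`garden_summaries()` scores each institution's plants against the pooled in
situ catalog and attaches counts of plants, maternal accessions, and
distinct source populations. `fit_transform_regressions()` regresses a
class's capture percentage on a predictor under identity, square-root and
log transforms and reports all three with adjusted R²; the best transform is
flagged but all are returned, because which transform fits best is itself a
finding. The regressions are unweighted OLS over all gardens — no garden
exclusions or weights are applied, as none are documented for the original
analysis.

Differentiation uses Weir & Cockerham's (1984) θ: variance components `a`
(among cohorts), `b` (among individuals within cohorts) and `c` (within
individuals) are computed per allele per locus and summed before the ratio
is taken (ratio of sums, the canonical multilocus estimator). Negative
per-locus components are retained — truncating them at zero would bias the
estimator. Missing calls drop an individual from that locus only. A
Nei-(1987)-style `(Ht − Hs)/Ht` variant is available behind
`method = "nei"` as a cross-check, since the published analysis does not
name its estimator variant. `fst_contrast()` computes θ between each garden
and each pooled wild region and contrasts the two per-garden vectors with a
two-sided paired t-test (the published direction of the test is not
recorded; two-sided is the conservative default). If the two vectors are
identical the t statistic is defined as 0 with p = 1 rather than erroring
on zero variance.

## Ecogeographic coverage

Geographic coverage follows the buffered-occurrence gap-analysis tradition:
place a circular buffer of 10, 50 or 100 km around every occurrence point,
dissolve, and report the percentage of the in situ buffered area overlapped
by the ex situ source buffered area. No geospatial vector stack is assumed:
the package projects coordinates with a spherical Albers equal-area conic
(standard parallels from the one-sixth rule on the data's latitude range,
configurable), buffers as planar discs in km, and evaluates dissolved areas
and intersections by midpoint scanline integration of the union
cross-sections — unions and intersections of intervals on a line are exact,
so the only error is the 1-D discretisation, which at the default 512
slices per disc diameter is well inside 0.05% for a disc (the tests assert
0.5% including projection distortion). Duplicated coordinates are removed
before buffering, making the dissolve idempotent. Both roles share one
projection and one scanline grid so the ratio is internally consistent.

Ecoregion coverage counts distinct Level-III (coarse) and Level-IV (fine)
ecoregion identifiers whose polygons intersect the dissolved buffers with
nonzero area; the conserved count is restricted to identifiers already in
the in situ total, and any nonzero-area overlap counts (no minimum-overlap
threshold). A union of discs intersects a polygon's interior exactly when
some disc centre lies within one radius of the polygon, so the test reduces
to point-in-polygon plus point-to-segment distance — no polygon clipping is
needed. Layers are read from GeoJSON (`Polygon`/`MultiPolygon`, outer rings;
holes are not modelled) with configurable property fields for the two
levels. East/West scoping of occurrence points uses the supplied region
column — the disjunction is a biological grouping provided with the data,
not a longitude cut.

## The synthetic-data generator

`simulate_metapopulation()` provides study-shaped data with no download: a
hierarchical drift model in which each locus draws a skewed base frequency
spectrum (Dirichlet with small concentration, giving many rare alleles),
perturbs it once per region and once per population using a Balding–Nichols
Dirichlet draw with concentration `(1 − d)/d`, and samples diploid genotypes
under random mating. Missing calls are injected at the configured rate and a
fixed number of brand-new singleton alleles are planted as exact single
copies, which pins the reduced-catalog boundary in tests.
`simulate_ex_situ()` grows half-sib maternal families: each family's
seedlings share a mother drawn from the source population and take their
paternal allele from the population's pooled allele copies.
`simulate_landscape()` places populations in two disjoint geographic boxes,
scatters extra wild occurrence records around them, and overlays a
rectangular two-level ecoregion mosaic. All stages derive their randomness
from one seed through per-stage substreams, so any stage can be reproduced
in isolation.

Defaults encode the audited study's stated conditions: 667 wild individuals
in 35 populations (18 East, 17 West), 11 loci, 2.6% missing calls, 290
seedlings from 66 maternal families out of 26 source populations across 8
gardens, with the West under-collected (53 of 290 seedlings). Where no
value is stated, defaults were chosen once for realism: 50 candidate
alleles per locus with Dirichlet concentration 0.18 (realised in situ
richness of roughly 240 alleles over 11 loci), region-level divergence
`d = 0.03` and population-level divergence `f = 0.08` (garden-versus-region
θ of a few hundredths, larger toward the under-collected region), and 20
injected singletons.

What the generator does *not* reproduce: real rare alleles are strongly
spatially localised (private to a population or region), whereas the
Dirichlet hierarchy spreads low-frequency variants more evenly. Synthetic ex
situ collections therefore capture a higher fraction of wild alleles than
the real collection did, and passing tests on synthetic data demonstrate
correctness of the accounting, not the empirical capture level of any real
species. Linkage, selection, masting phenology and coalescent-exact
genealogies are likewise out of scope.

## Numerical and scale choices

* Allele pairs are unordered (microsatellites are unphased); calls are
  stored sorted, and all comparisons are on the sorted pair.
* GENEPOP parsing auto-detects 2- versus 3-digit allele encoding per file
  and rejects mixed encodings; all-zero tokens (or the explicit missing
  code) are missing at both slots; individual IDs must be globally unique
  because the metadata join is keyed on them.
* Curve/threshold comparisons use `>=` on the replicate mean, so a mean of
  exactly 95.0 reaches a 95% threshold.
* Test and acceptance runs use desk-scale problem sizes chosen for quick
  iteration: cohorts of 60–240 individuals, 3–8 loci, 2,000–10,000
  Monte-Carlo replicates, and 20 replicates per divergence level for the
  parameter-recovery check. The divergence-recovery design uses five levels
  `d ∈ {0, 0.05, 0.1, 0.2, 0.4}` and requires the level means of
  between-region θ to increase strictly.
* Monte-Carlo agreement with the closed form is asserted within three
  Monte-Carlo standard errors plus a rule-of-three floor
  (`100 · 3 / (R · n_alleles)`) for sample sizes at which every replicate
  captured the class, where the observed standard error collapses to zero
  while the exact mean sits just below 100.

## Known limitations

* Heterozygosity, allelic-richness rarefaction, null-allele checks,
  Hardy–Weinberg and linkage tests are intentionally absent; the audit is
  allele-presence accounting.
* The geometric engine assumes planar buffers in an equal-area projection;
  for continental extents the projection choice (configurable) bounds the
  area error, and published coverage figures obtained with other
  projections should be reproduced to within a percent or two, not
  bit-exactly.
* Ecoregion polygons are treated as solid outer rings; layers that encode
  enclaves as holes will count an enclosing region as overlapped if a
  buffer falls inside the hole.
* The paired t-test across gardens treats gardens as independent units; the
  shared seed-distribution history of a garden network violates this mildly,
  as it did in the original analysis.
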