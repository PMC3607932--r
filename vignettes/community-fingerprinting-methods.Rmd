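---
title: "Methods: T-RFLP community fingerprinting, diversity statistics and FISH quantification"
author: "TRFLPtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: T-RFLP community fingerprinting, diversity statistics and FISH quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TRFLPtools)
```

TRFLPtools implements the complete desk-side analysis of a microbial
community study built on three measurement techniques: 16S rRNA gene clone
libraries, terminal restriction fragment length polymorphism (T-RFLP)
fingerprinting and fluorescence in situ hybridization (FISH). The running
example throughout the package is an activated-sludge Archaea community
dominated by *Methanosaeta*-like methanogens, but nothing in the code is
specific to that system. This vignette explains the models and procedures,
the tunable parameters and their defaults, the synthetic-data generator and
its limits, and the design choices made where the underlying methods leave
room for interpretation.

## Clone-library diversity statistics

**Distances and OTUs.** Aligned sequences are compared with the uncorrected
p-distance under pairwise gap deletion: the proportion of differing
positions over the columns where both sequences carry a determinate,
non-gap base (`pairwiseDistances()`, computed via `ape::dist.dna`). The
uncorrected distance is deliberate: the operational thresholds used to
delimit taxa — 98.7% for species, 95% for genus, 90% for family/class, 80%
for phylum — are *sequence identity* conventions, not evolutionary
distances. An evolutionary model (e.g. `"JC69"`, `"K80"`) can be selected
through the `model` argument for users who want model-corrected distances.

OTUs are formed by complete-linkage (furthest-neighbor) agglomeration
(`assignOTUs()`): clusters merge while their *largest* inter-member
distance stays at or below `1 - threshold`, which guarantees that every
pair inside an OTU meets the similarity threshold. Complete linkage was the
de-facto standard of OTU clustering tools of the clone-library era; the
choice matters only for borderline sequence pairs, and the linkage is
isolated inside one function should another rule be preferred. A direct
consequence, covered by the tests, is that partitions at nested thresholds
are themselves nested. OTU numbering follows the lexicographic order of
each cluster's smallest member id, which makes partitions reproducible
across platforms.

**Richness.** `chao1()` implements the classic (non-bias-corrected) Chao1
lower bound,

$$S_{\mathrm{chao1}} = S_{\mathrm{obs}} + \frac{f_1^2}{2 f_2},$$

with the degenerate form $S_{\mathrm{obs}} + f_1(f_1-1)/2$ when no
doubletons exist. The classic form, rather than the bias-corrected
$f_1(f_1-1)/(2(f_2+1))$ variant, is used because it is the estimator that
reproduces the reference library's published richness from its abundance
vector; the distinction is documented here so users comparing against
other software (which often defaults to the bias-corrected form) are not
surprised. Coverage is reported as $100 \cdot S_{\mathrm{obs}} /
S_{\mathrm{chao1}}$, the share of estimated richness that the library
captured.

**Accumulation curves.** `accumulationCurve()` averages the number of
distinct OTUs among the first $k$ clones over random orderings of the
library (1000 permutations by default; a seed is required so curves are
reproducible). The closed-form hypergeometric expectation
$E[S_k] = S - \sum_i \binom{n-n_i}{k} / \binom{n}{k}$ is available via
`exact = TRUE` and doubles as the independent oracle in the test suite.

**Evenness.** `paretoLorenz()` ranks OTUs from most to least abundant and
accumulates proportions of OTUs ($x$) against proportions of abundance
($y$). The functional organization index Fo is the curve's height at
$x = 20\%$: the combined relative abundance of the top fifth of the OTUs.
A perfectly even community gives 20%; specialization pushes Fo toward
100%. When $0.2\,S$ is not an integer the curve is linearly interpolated
between vertices — the natural reading of "the projection at the 20%
line", and the only case where any numerical choice is involved.

## In-silico terminal fragment prediction

A T-RFLP assay sizes only the fragment carrying the 5' fluorophore, so the
in-silico digest (`predictTRF()`) needs just three ingredients: the label
origin (the first base of the labeled forward primer, located with IUPAC
degeneracy via `matchPrimer()`; an `N` in the target matches nothing), the
first occurrence of the enzyme's recognition site at or after the origin,
and the cut offset within the site. For a site starting at position $s$
(1-based) with cut offset $c$, the retained labeled strand is
$s - \mathrm{origin} + c$ bases — for the blunt cutters AluI (AG^CT) and
RsaI (GT^AC), $c = 2$. Fragments outside the 50–1020 base window of the
sizing standard are flagged `OUT_OF_RANGE` (the raw length is kept);
sequences without a downstream site are `ND`.

Clone-library inserts typically begin 50–100 bases downstream of the
primer. `predictTRFOffset()` anchors such a clone in a primer-bearing
reference by its leading bases (20 exact-matching bases required, so
mapping stays unambiguous even near degenerate positions) under the
assumption of no indels between the primer and the anchoring region. If
the reference carries a recognition site *upstream* of the clone's start,
the clone's own sequence cannot determine its terminal fragment and the
prediction is declared `ND` rather than guessed.

Predicted fragments systematically run longer than observed ones — in the
reference data by 4–6 bases, a well-known discrepancy between sized and
sequence-derived fragment lengths. The package treats this drift as a
matching window rather than a correction: `identifyCombinations()` accepts
a database sequence as a candidate identity for an observed (AluI, RsaI)
pair when *both* predicted-minus-observed differences fall inside the
drift window, default `[3, 7]` — the observed 4–6 base bias widened by one
base of size-calling jitter on each side. Out-of-range observation slots
match `ND`/`OUT_OF_RANGE` predictions. Widening the window can only add
candidates, never remove them.

## The raw-peak-to-consensus pipeline

`runPipeline()` chains five steps per sample and enzyme, each exported on
its own:

1. **Detection filter** (`filterPeaks()`): keep peaks of 50–1020 bases
   with height strictly above 50 fluorescence units (FU). The strictness
   matters at the boundary: a 50 FU peak is noise by definition.
2. **Replicate quality control** (`selectReplicates()`): a sample×enzyme
   is analyzed only if at least two replicates exceed 500 FU total
   fluorescence (the sum of peak heights, a DNA-load proxy); the two
   strongest are kept, ties broken by replicate id. Rejection is a
   reported outcome, not an error.
3. **Normalization** (`normalizeProfiles()`): iteratively scale every
   profile to the smallest total fluorescence and delete peaks whose
   scaled height falls to or below the 50 FU floor, until a fixed point is
   reached. The deletion uses `<=` because a scaled peak *at* the
   detection limit is indistinguishable from noise. The fraction of each
   profile's original fluorescence removed is reported; on well-behaved
   data it is small, and the QC report makes it visible when it is not.
4. **Alignment** (`alignPeaks()`): pooled peak sizes are clustered by a
   moving average — sorted ascending, a new bin opens when the next size
   exceeds the running bin mean by more than `gap` (default 1.0 base,
   chosen because size-called fragment coordinates of the same fragment
   scatter by a few tenths of a base while genuinely adjacent fragments
   sit ≥ 1 base apart). Two peaks of one profile landing in one bin are
   summed with a height-weighted size. The exact moving-average rule of
   historical fingerprint-alignment software is not fully documented
   anywhere; this reconstruction is confined to one function so it can be
   swapped out, and the manual error check of the original workflow is
   replaced by the QC report.
5. **Consensus** (`consensusProfile()`): only fragments present in *both*
   replicates survive; size, height and area are averaged and heights are
   converted to relative abundances (height over total fluorescence).

Consensus profiles whose total fluorescence falls below 25% of the
per-enzyme median are excluded (`minConsensusFrac`), because normalizing a
time series against a profile with very little DNA deletes
disproportionately many peaks elsewhere. The original workflow excluded
"low total fluorescence" profiles without giving a number; 25% of the
median is this package's operational definition, it is configurable, and
every exclusion is logged in the QC report.

The same normalization and alignment operations are applied a second time
at the *series* level (`buildProfileSeries()`) before profiles are
compared across dates — one implementation, two scopes.

The pipeline is deterministic, invariant to the row order of the input
peak table and to common rescaling of all heights, and — the key
correctness property — on noiseless synthetic data it returns consensus
relative abundances equal to the generator's ground-truth weights to
within 1e-9, with bin sizes equal to true fragment lengths minus the
planted drift. These are tested, not asserted.

## Community dynamics

`brayCurtis()` implements $100 \cdot \sum_i |p_i - q_i| / \sum_i (p_i +
q_i)$; `distanceToBaseline()` compares every profile in a series against
the chronologically first, the standard stability display for a monitored
community. `correlateParameters()` computes Pearson's product-moment
correlation between each fragment's relative abundance and each process
parameter over shared dates, with significance from the two-sided t-test
$t = r\sqrt{(n-2)/(1-r^2)}$ and stars at the conventional 0.05 / 0.01 /
0.001 levels (the source workflow reports stars without defining the
levels; the conventional ones are adopted and configurable). Two policies
exist for fragments missing from an existing profile: abundance 0 (the
default, consistent with "not detected means below detection") or missing
(`zeroFill = FALSE`, which drops those dates pairwise). The observation
count reported per fragment is the number of profiles in which it appears.
No multiple-testing correction is applied — the correlation tables mirror
the exploratory, unadjusted convention of the field and say so here.

## FISH quantification

`quantifyImage()` reproduces the area-based estimate of relative Archaea
abundance from three probe channels: EUB (Bacteria), ARC915 (Archaea) and
MX825 (Methanosaetaceae). Channels are binarized at an intensity of 100
(8-bit scale assumed; strictly above), pixels positive for EUB *and* an
archaeal probe are ambiguous and removed everywhere, and — because ARC915
does not cover all Methanosaetaceae — the archaeal area is ARC915-positive
plus MX825-positive-not-ARC915 pixels, so nothing is counted twice. Images
with fewer than 1000 combined signal pixels show dispersed cells rather
than flocs and are excluded; the exclusion count is always reported next
to the mean, since the reference value's denominator ("90 images") is
ambiguous about sub-threshold images. Aggregation is the mean of
per-image percentages with its sample standard deviation (matching how
such values are reported with error bars); the pooled-area ratio is
available behind `pooled = TRUE` because the two differ on heterogeneous
image sets.

## The synthetic-data generator

`makeReferenceTaxa()` builds primer-anchored sequences with exactly one
AluI and one RsaI site each, at controlled positions ≥ 60 bases from the
labeled end, with all (AluI, RsaI) fragment-length pairs distinct — so
dual-enzyme identification has unambiguous ground truth. The generator
recomputes every planted fragment length through `predictTRF()` before
recording it, making the reference set self-consistent by construction.

`renderElectropherograms()` is the observation model: per replicate a
total-signal factor $H \sim U(800, 3000)$ FU (a range that straddles the
500 FU quality gate, so replicate QC is exercised on both sides), peak
height $w \cdot H \cdot (1+\varepsilon)$ with
$\varepsilon \sim N(0, \mathrm{noiseSd})$, peak size = true fragment
length minus the planted drift, area = height (area is carried through
the pipeline but enters no formula except consensus averaging, so a
neutral definition suffices), plus a Poisson(2) number of spurious 10–49
FU peaks that the detection filter must remove. `generateParameterSeries()`
draws weekly plant parameters uniformly from realistic operating ranges
(water temperature 10–20 °C, SRT 2–4 d, F/M 0.006–0.010, COD 818–1298
mg/L, NO23-N 40–56 mg/L, SSVI 65–95 mL/g, effluent NSS 6–40 mg/L, EPS
protein 20–60 and carbohydrate 5–25 mg/g VSS, relative shear sensitivity
1–3) and plants linear taxon–parameter couplings on the z-scored
parameter with additive noise (default sd 0.25 against a baseline of 1,
which at slope 0.6 and n = 30 gives essentially complete power while slope
0 preserves the nominal type-I error — both properties are tested).

What the generator does **not** emulate: real replicate noise structure
(the multiplicative Gaussian model is a configurable stand-in — nothing is
published about the true covariance of replicate electropherograms),
partial digestion, pseudo-TRFs from single-strand artifacts, size-calling
nonlinearity across the gel, chimeras, or primer-mismatch bias.
Consequently, passing tests demonstrate the correctness of the
*computations* under a controlled observation model, not the field
performance of T-RFLP itself.

## Numerical choices and degenerate inputs

* Clustering cut: merges happen while distance ≤ `1 - threshold`; the
  equality case belongs to the merge, matching the "at least x% similar"
  reading of a threshold.
* `paretoLorenz()` interpolation: linear, only needed when $0.2S$ is not a
  vertex.
* Normalization deletion: `<= floor`, see above; a profile losing all
  peaks is flagged `empty` and excluded downstream rather than erroring
  the whole run.
* Bray-Curtis of two all-zero vectors is undefined and raised as an error.
* Correlation with zero variance in either series is flagged
  (`zero_variance`), not silently `NA`; fewer than 3 paired dates is
  flagged `too_few_pairs`.
* Alignment tie-break: pooled peaks are processed in ascending size order;
  equal sizes join the current bin (gap 0 ≤ `gap`).
* Empty inputs: an empty peak table yields an empty result with a QC note;
  an empty consensus (no shared fragment) is a flagged outcome.

## Scale of the shipped checks

The test suite and the acceptance script are sized for interactive use:
reference communities of 1–8 taxa, clone libraries of up to 10 000 draws
where a distributional bound is being checked, 1000 random sequences for
the digest oracle, brute-force clustering on up to 6 sequences, and 100
seeded simulations for each Monte-Carlo property. These sizes were chosen
so every property is checked well beyond its noise floor while the whole
suite runs in well under a minute.

## Interface notes

The package is used from R; the file formats it reads and writes (FASTA
via Biostrings, peak-table and consensus CSVs, square Phylip distance
matrices) are the interchange points with instrument software and other
tools, and `scripts/acceptance.R` in the source repository shows a
complete scripted run. There is deliberately no separate command-line
binary: every operation is an exported, documented function.

## Known limitations

* The distance model and linkage are configurable but the defaults encode
  one specific historical workflow; results at a fixed threshold can
  differ from greedy or average-linkage OTU tools on borderline pairs.
* Dual-enzyme identification inherits the resolution limits of T-RFLP:
  distinct taxa with coincident fragment pairs are indistinguishable, and
  the drift window trades sensitivity against false identities.
* The genus-level Chao1 is computed like any other level, but no external
  reference value constrains it, unlike the species level.
* FISH quantification assumes masks are already the product of upstream
  segmentation; it performs thresholding and set arithmetic only, no
  microscope-format ingestion or deconvolution.
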