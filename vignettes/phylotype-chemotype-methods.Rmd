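---
title: "Methods: phylotype and chemotype analysis of MALDI-TOF isolate libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylotype and chemotype analysis of MALDI-TOF isolate libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectrotype)
```

## The analysis problem

Microbial drug-discovery programs isolate hundreds of bacterial colonies
from environmental samples and must decide which isolates are worth keeping:
redundant entries waste downstream effort, while genuinely distinct
phylotypes or chemotypes are the raw material of the pipeline. Intact-cell
MALDI-TOF mass spectrometry supports this triage cheaply in two modes:
linear-mode *protein spectra* (here analysed on 4–20 kDa), dominated by
ribosomal and other abundant intact proteins and informative at roughly the
species/subspecies level — a *pseudo-phylogeny*, since it reflects ionized
protein similarity rather than gene sequence — and reflectron-mode
*small-molecule (SM) spectra* (< 2 kDa), a proxy for the specialized
metabolites an isolate expresses.

`spectrotype` implements the full comparative analysis for a two-host
isolate collection:

1. peak picking and triplicate consensus per isolate and mode;
2. m/z binning into isolate × feature matrices;
3. cosine similarity and Ward clustering of protein profiles into a
   dendrogram;
4. matched-plate filtering and dendrogram pruning, so the two hosts stay
   directly comparable when isolation plates are lost;
5. a cut-height sweep that tallies, for every cut, whether each group
   contains isolates from host A, host B, or both;
6. bipartite metabolite association networks (MANs) linking isolates to
   shared SM mass features;
7. per-group Pearson correlation between protein and SM pairwise
   similarity — the phylotype–chemotype relationship.

A seeded generator produces synthetic collections with planted taxonomy so
that every stage can be validated end to end against known ground truth.

## Preprocessing model

Raw profile spectra are reduced to peaks by a standard intact-cell MALDI
chain: optional square-root intensity transform (variance stabilization for
count-like detector noise), Savitzky–Golay smoothing (polynomial order 3,
half-width 10 points by default), SNIP baseline estimation (100 iterations;
the iteration count bounds the half-width of the widest structure treated
as baseline), and local-maximum picking with an SNR threshold. Noise is
estimated robustly as `1.4826 * MAD` of the baseline-subtracted residual;
the default SNR cutoffs are 3 for protein mode and 5 for the noisier SM
mode. If the residual has zero MAD (noise-free synthetic input) the
standard deviation is used so the degenerate case stays well defined.

Replicate consensus: peaks from an isolate's replicates are pooled, grouped
by the same relative m/z tolerance used for binning, and a group is kept
when its *presence fraction* reaches `replicateMinFraction` (default 2/3,
i.e. at least 2 of 3 replicates). The denominator is the number of
replicates actually observed, so losing a replicate does not silently
penalize an isolate. Consensus m/z is the intensity-weighted mean and
consensus intensity the median of per-replicate intensities. Optional
matrix-blank subtraction (`subtractBlank()`) removes peaks matching a
solvent/matrix control; it is off by default.

Two analysis windows are built in: the default protein range 4–20 kDa, and
a selectable legacy preset of 3–15 kDa that reflects an older convention
for intact-protein acquisition. The SM range defaults to 200–2000 Da; the
200 Da floor excludes the MALDI matrix-cluster region.

### Binning

The primary *reference binning* is greedy single linkage on the pooled,
sorted peak list: a peak joins the open bin while its gap to the bin's
running reference (mean of members) is within `tolerance × reference`
(default relative tolerance 0.002, i.e. 2 Da at 1000 Da, 20 Da at 10 kDa —
appropriate for linear-mode mass accuracy). The bin reference is the mean
member m/z and each isolate contributes its summed intensity per bin. A
second, deliberately different algorithm — *strict binning* on a fixed grid
(`floor(mz / gridWidth)`) — exists purely as a robustness check: if a
conclusion survives swapping the binning algorithm and distance measure it
is unlikely to be an artifact of either. Fixed grids split peaks that
straddle a boundary; that boundary effect is documented, not hidden.

Exact binning tolerances and replicate rules for this kind of analysis are
rarely printed in publications; conclusions that are sensitive to them are
therefore validated here by property (oracle equivalence, recovery of
planted structure) rather than by matching any specific published matrix.

## Clustering model

Protein similarity is the cosine of binned consensus-intensity vectors
(values in [0, 1] for non-negative features). All-zero rows — isolates with
no surviving peaks — get similarity 0 to everything and 1 to themselves,
with a warning rather than silent coercion. Whether intensities enter
sqrt-transformed (the default, inherited from peak picking) or as
presence/absence is a configuration choice (`presence = TRUE`).

The dendrogram is built by Ward's method on `d = 1 − s` using the
Lance–Williams recursion on squared dissimilarities (the "ward.D2"
convention), so that two singletons at dissimilarity `d` merge at height
`d` and heights are monotone non-decreasing. The variant matters because
cut heights are reported in these units; fixing and documenting it keeps
heights comparable across runs. Ties in the merge criterion are broken by
the lexicographically smallest cluster pair, and isolates are sorted by id
before clustering, making the tree bit-reproducible and invariant to input
row order. The implementation is cross-checked in the test suite against an
exhaustive oracle that recomputes the ESS increase of every candidate merge
from the original pairwise distances, and against `stats::hclust`.

*Matched-plate filtering*: when an isolation plate is excluded (e.g.
overgrown), the plate with the same (media, pretreatment, dilution)
condition from the other host is excluded too, keeping the comparison
symmetric. *Pruning* then removes the affected leaves from the already-built
tree without re-clustering — groupings are more reliable when estimated
from all isolates, so heights are preserved exactly. Internally pruning
reconstructs the subtree from the restriction of the cophenetic
(ultrametric) matrix via single linkage, which is exact: heights are copied
values, never recomputed, and cutting a pruned tree provably equals
restricting the cut of the full tree.

k-means on L2-normalized feature vectors (`kmeansPartition()`) provides the
flat-clustering robustness check; `k` defaults to the group count of the
cut under study, since a flat method needs the number of clusters as an
input. With `k` equal to the number of isolates the partition is returned
directly as singletons (inertia 0), a case the Hartigan–Wong algorithm does
not accept.

## The cut-height sweep

A dendrogram is a family of partitions indexed by cut height. The sweep
cuts at `step, 2·step, …, ceiling(maxHeight/step)·step` (default step
0.05 height units). The grid starts at `step`, not 0 — a cut at 0 is all
singletons and carries no overlap information — and its last point is at or
above the top merge, so the final cut is always a single group; for a tree
whose top merge lies in (7.95, 8.00] this grid has exactly 160 cuts. An
epsilon guard (`ceiling(maxH/step − 1e−9)`) keeps the count stable when
`maxH` is an exact multiple of the step.

Each cut's groups are classified A-only / B-only / Both by member sources.
Group-level proportions and raw isolate counts are both reported: the
number of groups shrinks rapidly with height, so proportions alone can
mislead about how many isolates they represent. The Both proportion is
identical to the Jaccard index `|G_A ∩ G_B| / |G_A ∪ G_B|` of the two
hosts' group sets, because every group contains at least one isolate from
one of the hosts; the identity is asserted property-style over thousands of
random partition/label instances in the tests. Groups are named after their
smallest member isolate id for stable reporting.

`summarizeBands()` averages composition over height bands. The species-level
band (0, 2] and genus-level band (2.5, max] used in the examples and
acceptance checks correspond to where the default generator's species and
genus merges fall (see below); on real data the bands should be chosen from
the dendrogram under study.

## Metabolite association networks

A MAN is a bipartite graph: isolate nodes connected to the SM feature bins
in which they have positive consensus intensity. Edges are unweighted —
the analysis concerns *shared mass features*, not abundances. Two isolates
are connected through a feature node exactly when their presence vectors
have positive dot product, which makes the per-pair shared-feature count an
algebraic quantity that the tests verify directly. MANs are built per
dendrogram grouping (the analysis unit of interest is intra-genus
variation); a global MAN is available behind a flag. Node coloring by a
partition touches attributes only, never topology, so recoloring at a finer
cut is cheap and safe. Features whose isolates span a single group are the
interesting ones: candidate group-specific metabolites.

## Phylotype–chemotype correlation

The unit of correlation is the unordered isolate *pair*: within each group
of at least 3 isolates, Pearson r between the protein similarity and SM
similarity of its `n(n−1)/2` pairs, plus a global all-pairs r. Zero-variance
pair vectors yield `NA` ("undefined"), deliberately not 0 — a group whose
SM spectra are all identical carries no evidence either way. Because pairs
sharing an isolate are not independent, an optional one-sided Mantel-style
permutation test (`p = (1 + #{r_perm ≥ r_obs}) / (1 + nPerm)`, isolate-label
permutations of one matrix) is provided as the significance layer; no
GLS/MRM modelling is attempted. Both similarities-based and
presence/absence variants can be computed and labelled by the caller; the
package default correlates the same cosine similarities the clustering
uses.

## The synthetic-data generator

The generator is the package's study design, not a convenience: its
defaults define the conditions under which the pipeline is validated.

* **Taxonomy**: 4 genera × 3 species × 2 strains × 4 isolates = 96
  isolates. Each species occupies host A only, host B only, or both with
  probabilities 0.45/0.45/0.10 — weighted toward single-host species, so
  species-level non-overlap coexists with genus-level overlap, the pattern
  the sweep is designed to detect. Isolates of a both-host species land in
  either host at random. (The compact fixture is deliberately read as
  "isolates per strain = 4" so the count is exactly 96 rather than varying
  with the occupancy draw.)
* **Protein spectra**: each isolate's panel is the union of a 20-peak genus
  core, 10 species peaks and 5 strain peaks drawn uniformly on 4–20 kDa.
  The 20/10/5 sizing makes genus cores dominate similarity above the
  species level, so genus- and species-level merge heights separate — with
  these defaults species structure completes below height ≈ 2 and genus
  merges occur above ≈ 2.5, which is what the default band edges encode.
* **SM spectra**: each genus carries 10 candidate BGCs emitting 1–3
  features on 200–2000 Da (≥ 0.5 Da apart within a genus so planted sharing
  survives binning). Species inherit BGC subsets along a random species
  tree, with per-branch loss calibrated so a species retains about
  `speciesRetentionProb` (default 0.6) of the panel. The coupling parameter
  ρ acts per isolate: with probability ρ the isolate follows its species;
  otherwise it draws the same number of BGCs from the study-wide pool.
  Decoupling is deliberately isolate-level and study-wide: species-level
  shuffling within a genus would leave both within-species coherence and a
  genus chemotype signature intact, and ρ = 0 would not actually erase the
  phylotype–chemotype association it is meant to erase. Setting
  `speciesRetentionProb` near 1 yields genus-conserved chemotypes (low
  within-genus correlation, the *Chryseobacterium*-like regime); moderate
  retention with ρ = 1 yields species-private chemotypes (high correlation,
  the *Pseudomonas*-like regime).
* **Noise**: per replicate, Gaussian m/z jitter (200 ppm — an order of
  magnitude below the 0.002 binning tolerance), log-normal intensity noise
  (CV 0.3), 5% peak dropout and on average 1 spurious peak. Spurious peaks
  rarely repeat across replicates, so the 2-of-3 consensus rule removes
  them; this is the mechanism the defaults are meant to exercise.
* **Plates**: the full 9 media × 2 pretreatments × 3 dilutions factorial
  per host; `plateExclusionProb` marks random plates excluded to exercise
  the matched-plate filter. A deterministic campaign-scale preset
  (`campaignFixture()`) builds 851 isolates (522 + 329) with exactly 159
  on non-matched plate conditions, for filter/pruning bookkeeping at
  realistic scale.

What the generator does **not** emulate: physically realistic TOF peak
shapes, detector saturation, isotope envelopes, mass-calibration drift
between batches, horizontal BGC transfer between genera, and
culture-condition-dependent BGC expression. Passing tests therefore show
that the pipeline recovers the structure its model assumes, not that any
particular real collection satisfies those assumptions.

## Numerical choices and degenerate inputs

* Collections are canonically sorted by (isolate, replicate) on load and
  isolates sorted by id before clustering: results never depend on file
  order.
* All tie-breaks are deterministic (lexicographic smallest pair in
  agglomeration; smallest member id for group naming; children ordered by
  smallest leaf label in Newick output).
* Empty spectra, isolates with no peaks, empty SM panels, single-height
  trees and zero-variance correlation vectors all have defined, tested
  behaviour (empty sets, all-zero rows with warnings, single-cut sweeps,
  `NA` correlations).
* Newick branch lengths are height differences, so a two-leaf merge at 0.4
  serializes as `(a:0.4,b:0.4);` and leaf-to-leaf path length is twice the
  merge height.
* The provenance hash in output headers covers the analysis-relevant
  configuration; the output directory is excluded so the same analysis in
  two locations is recognizably one run.

## Scope decisions

The package is a library with an orchestrator, not an interactive tool:
`runPipeline()` consumes a YAML (or in-memory) configuration, composes the
stages through on-disk artifacts so partial reruns are possible, and writes
a run log with every parameter value; a thin `Rscript` wrapper lives in
`inst/scripts/run_pipeline.R`. No statistical test of host overlap against
a random-assignment null is attempted — the sweep is descriptive, and a
permutation extension is left to the user. Vendor raw formats are out of
scope (convert to mzML first); mzML reading goes through `mzR`, and the
built-in mzML writer exists only so simulated fixtures can exercise that
path.

Problem sizes in the test suite and acceptance script (96-isolate default
collections, 60-isolate coupling runs, 10-seed band summaries, the
851-isolate campaign preset) were chosen as the smallest sizes at which the
planted effects are comfortably detectable; they are the package's own
validation conditions.

## A worked example

```{r example, eval = FALSE}
sim <- simulateDataset(simConfig(), seed = 1)
params <- preprocessParams()
fm <- binPeaksReference(consensusByIsolate(sim$proteinPeaks, params),
                        params$binTolerance)
dend <- wardDendrogram(cosineSimilarity(fm))
sw <- sweepDendrogram(dend, sim$meta, step = 0.05)
summarizeBands(sw, list(c(0, 2), c(2.5, max(sw$height))))
```

See the README for the same example with the numbers it prints, and
`scripts/acceptance.R` for the full set of quantities the package
recomputes from scratch.
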