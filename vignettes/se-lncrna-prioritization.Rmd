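---
title: "Super-enhancer dynamics and cis-acting lncRNA prioritization: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Super-enhancer dynamics and cis-acting lncRNA prioritization: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sefunnel)
```

## Scope and model

sefunnel implements the computational core of a super-enhancer (SE)
lncRNA study of breast-cancer progression: rank-ordering SE
identification from H3K27ac peak/signal tables, stage-wise classification
of SEs as acquired, lost or retained across an ordered progression series
(with patient-cohort representation counts), and a stepwise funnel that
narrows a genome-wide panel of SE-associated lncRNAs to a handful of
potentially *cis*-acting candidates. qPCR quantification (ΔΔCt),
nuclear/cytoplasmic localization calls and the study's significance tests
round out the toolkit, and seeded synthetic-data generators produce every
input with planted ground truth.

The pipeline starts downstream of peak calling: inputs are peak intervals
with depth-normalized signal and bedGraph-like signal tracks. Read
alignment, duplicate filtering and peak calling are out of scope, as are
gene-set enrichment of the resulting gene lists and retrieval of external
patient atlases (atlas membership and the patient expression matrix are
plain injected inputs).

## Coordinates and interval semantics

All coordinates are 0-based half-open (BED convention). Two intervals
overlap iff they share at least one base; bookended intervals do not
overlap. This matches the default of the interval-intersection tools the
field uses for SE comparisons, where the minimum-overlap fraction is
rarely changed. Distances between non-overlapping features are
nearest-edge gaps, strand-ignored: enhancer-neighborhood windows in this
literature are symmetric and strand-agnostic. Ties in neighbor queries
break lexicographically by gene id so results are reproducible.

## Super-enhancer identification

Calling proceeds in four steps:

1. **TSS exclusion.** H3K27ac marks active promoters as well as
   enhancers, so peaks *fully contained* in the zone
   `[tss - e, tss + e)` of any annotated TSS are removed
   (default half-width `e` = 250 bp, giving a 500 bp zone). Containment
   rather than overlap is deliberate: a broad enhancer region that
   happens to span a promoter is kept, only promoter-sized peaks are
   dropped, and `e = 0` disables the step entirely.
2. **Stitching.** Remaining peaks within 12,500 bp on a chromosome are
   merged transitively; the stitched region's signal is the sum of its
   constituents. The 12.5 kb default is the conventional stitching
   parameter for this algorithm family.
3. **Ranking.** Stitched regions are ranked by descending signal, ties
   broken by (chromosome, start) for a stable permutation.
4. **Hockey-stick threshold.** With ranks and signals each min-max
   scaled to [0, 1], the cutoff is the signal at the first point (scanning
   from the low-signal end) where the two-point finite-difference slope
   of the curve exceeds 1 — the point where a line of slope 1 is tangent
   to a convex curve. Regions strictly above the cutoff are
   super-enhancers.

Degenerate inputs are handled explicitly: fewer than two regions cannot
define a curve (a single region is returned as a typical enhancer with a
warning); all-equal signals put the cutoff at the maximum, so nothing is
called. When the rank curve has no elbow at all — e.g. pure
exponential decoy signal with no high-signal population — the unit-slope
point sits mid-tail and a large fraction of regions exceed it. That is a
property of the geometric definition, not a bug; the statistic is
informative only when a distinct high-signal population bends the curve.
The synthetic fixtures show both regimes, and the elbow-free call count
is frozen in a test from a recorded run rather than asserted "small".

Uniformly rescaling all signals leaves the scaled curve, and therefore
the call set, unchanged; tests assert this invariance together with
equality against an independently coded exhaustive slope scan.

**Signal quantification.** Signal over a region is the per-base sum of a
bedGraph track scaled by `1e6 / library_size` (per-million
normalization; the convention is pinned here because "normalized to
sequencing depth" admits several scales, and any fixed scale cancels in
fold changes). Cross-stage comparisons collapse every stage's SE calls
into a zero-gap merged universe, quantify each stage over the universe,
and report pseudocount-stabilized fold changes
`(b + 1) / (a + 1)` so zero-signal stages stay finite.

## Acquired, lost and retained super-enhancers

"Present at a stage" means ≥ 1 bp overlap with any SE of that stage —
stitched boundaries shift between samples, so coordinate identity is
never required, and presence is boolean (overlapping two SEs counts
once). A region is *acquired* at stage *k* if it is an SE at stage *k*
and overlaps no SE at any earlier stage; acquired regions are reported
with the acquiring stage's coordinates. A baseline SE is *lost* at stage
*k* if it overlaps no SE of stage *k* (one comparison per stage, so a
region can be lost at several stages). An acquired region is *retained*
if it overlaps an SE at every later stage through the final one; regions
acquired at the final stage are vacuously retained, matching the reading
that a final-stage acquisition is "present through the end".

Cohort representation counts, for a query region, the number of patients
whose SE set overlaps it at least once — the "m of n patients" numbers
used to anchor cell-line findings in patient data.

## The prioritization funnel

Starting from a stage-wise expression table of SE-lncRNAs
(linear-scale intensities), the cascade applies, in order:

1. **Differential filter**: |log2 FC| ≥ log2(2) between the first and
   last stage. Fold changes use a pseudocount of 1 intensity unit on both
   sides; cutoffs are boundary-inclusive because the source convention
   ("± 2") does not state strictness, and inclusivity is the weaker
   assumption. The first-to-last contrast (not all pairwise contrasts) is
   the literal reading of "from normal to invasive".
2. **Neighbor pairing**: qualifying lncRNAs are paired with genes of the
   configured biotypes (default mRNA only) whose gene body lies within
   50 kb of the lncRNA gene body and whose own fold change passes the
   same cutoff. The window is measured between gene bodies, not
   TSS-to-TSS, consistent with the SE-neighborhood convention. miRNA
   neighbors can be enabled via `neighbor_biotypes`; the default stays
   mRNA-only because the microRNA neighborhood scan in the source study
   was a manual follow-up, not part of the automated screen.
3. **Atlas cross-reference**: pairs whose lncRNA is in the injected
   annotated-id list survive.
4. **Correlation filter**: pairs whose members correlate across patients
   with |r| ≥ 0.5 (inclusive) survive. Pairs with a member absent from
   the matrix are *routed to the trend branch*, not discarded — an
   unmeasured transcript is not evidence against cis action.
5. **Trend concordance**: pairs failing (or unmeasurable in) the
   correlation step survive if the neighbor gene's normal-to-tumor
   direction in patients equals its direction across the series (sign
   agreement with both signs nonzero). Sign agreement is the chosen
   quantification of "similar trends": the source does not state an
   effect-size or significance rule, and signs are the only scale-free
   comparison available across an array and a patient cohort.
6. **Highest-differential branch**: separately, lncRNAs with
   |log2 FC| ≥ log2(10) that are atlas-annotated are kept regardless of
   pairing.

The shortlist is the union of the correlation-retained, trend-retained
and highest-differential sets. The report records every step's lncRNA
and pair counts; at the pair level the correlation and trend branches
partition the annotated set, so counts are monotone along the funnel.
Note the lncRNA-level trend count can slightly exceed the annotated
count minus the correlated count, because one lncRNA may carry several
pairs that split across branches.

## qPCR quantification and localization

ΔΔCt follows the standard contract: per condition,
ΔCt = Ct(target) − mean Ct(references), with several reference genes
combined by the arithmetic mean of their per-gene mean Cts (equivalently
the geometric mean of relative quantities — the usual multi-reference
convention when the aggregation is unstated); ΔΔCt contrasts condition
against control and fold change is 2^(−ΔΔCt). A global Ct shift cancels
exactly, and the control contrasted with itself is exactly 1. Any
involved Ct at or above 40 cycles flags the result low-confidence.

Localization converts each fraction's Ct to relative abundance 2^(−Ct)
(optionally referenced per fraction to correct for recovery), normalizes
within the transcript across fractions, and calls nuclear at a nuclear
share ≥ 0.6, cytoplasmic at ≤ 0.4, undetermined between — numeric
stand-ins for "primarily localized", exposed as arguments because the
source states no thresholds. Transcripts near-undetectable in both
fractions (all Ct ≥ 40) are undetermined regardless of the ratio.

Group comparisons use one-way ANOVA with Tukey HSD (via `stats::aov` and
`stats::TukeyHSD`) and classical Student t-tests (pooled-variance
unpaired form, since the study names Student rather than Welch; paired
on within-pair differences). Zero-variance inputs error rather than
returning degenerate p-values.

## Synthetic data: what it emulates, and what it does not

The generators are pure functions of the seed (byte-identical on repeated
calls, caller's RNG stream restored) and record planted truth sufficient
for every recovery test.

* **ChIP-seq series** (default: 4 stages, 25 planted clusters, 400 decoy
  peaks per stage): planted clusters are 3–8 peaks spanning under
  12.5 kb with per-peak signal 50 + Exp(1); decoys are isolated Exp(1)
  peaks; a presence schedule cycles over all (first, last) stage windows
  so constitutive, transient, acquired, retained and lost classes all
  occur. Cluster, decoy and promoter-peak zones are separated by far
  more than the stitch distance, so planted truth is unambiguous and
  recovery is exact by construction, not by luck of the seed. Signal
  tracks tile peaks at 50 bp bins (coordinates are multiples of 50), so
  track quantification reproduces peak signal exactly.
* **Expression screen** (default: 8 planted cis pairs, 4 extreme
  responders, 200 decoys, 50 patients, target r = 0.9): planted pairs
  sit < 50 kb apart with both members' planted fold changes past the
  cutoff; roughly a quarter of them are withheld from the patient matrix
  and planted trend-concordant, exercising the trend branch. Decoy
  classes each fail exactly one filter (uncorrelated-and-discordant
  co-located pairs, unannotated pairs, correlated-but-distal pairs, flat
  features). Correlated rows come from a shared latent factor with
  loading √r; stage-extreme values are exact with jitter confined to
  intermediate stages, and empirical pair correlations are redrawn
  (deterministically, within the seeded stream) if they approach the 0.5
  boundary. These guards make planted-truth recovery a property of the
  construction for any seed — a design choice made when the generators
  were written.
* **qPCR tables**: planted fold changes as Ct shifts of −log2(f),
  planted nuclear shares as fraction Ct offsets log2(s/(1−s)), Gaussian
  well noise (default 0.05 cycles), triplicates.
* **Patient cohort** (default 47 patients): each focal region is carried
  by an exact planted number of patients, with jittered SE boundaries
  that still overlap.

What the generators do **not** emulate: mappability and GC structure,
input-chromatin background, fragment-length effects, array
normalization artifacts, correlated noise across stages, patient
subtype structure, or realistic lncRNA abundance distributions. Passing
recovery tests therefore demonstrates the *logic* of the pipeline —
set algebra, thresholds, ranking geometry, estimator contracts — not
robustness to the noise structure of real chromatin or array data.

## Problem sizes and numerical choices

The test suite runs the full synthetic defaults (425 peaks × 4 stages;
a 212-lncRNA screen; 1,000-instance oracle sweeps for interval algebra
and the hockey-stick scan; 100 random funnels for monotonicity and
order-invariance), sizes chosen so the whole suite completes in a few
minutes on one core while still exercising every code path. Interval
algebra is delegated to GenomicRanges/IRanges behind tibble-first
wrappers; tests compare those paths against independent brute-force
oracles (pairwise absorption, explicit base sets, per-base summation,
scalar slope scans) rather than trusting either side.

Reproduction of the source study's printed stage counts requires its
journal supplementary tables and deposited ChIP-seq data, which are not
distributed with the package; the corresponding acceptance test states
this and fails until those tables are supplied under
`inst/extdata/published/`.

## Known limitations

* The hockey-stick cutoff is meaningful only when an elbow exists; on
  elbow-free signal distributions it calls a large tail (see above).
* The correlation filter uses plain Pearson correlation on whatever
  scale the patient matrix is supplied in; no rank-based or
  partial-correlation options are provided.
* Trend concordance is sign-only; a tiny but consistently signed change
  counts as a trend.
* The unpaired t-test is the equal-variance Student form by design;
  there is no Welch option because the implemented protocol names
  Student's test.
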