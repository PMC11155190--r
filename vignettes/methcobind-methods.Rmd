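---
title: "Methylation profiles at TF binding regions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation profiles at TF binding regions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

methcobind implements a comparative analysis of whole-genome bisulfite
CpG methylation at transcription factor binding regions (TFBRs) across
a mammalian phylogeny. This vignette is the package's own account of
its models, assumptions, parameter choices and limitations; the README
shows the worked example.

## Coordinates and the data model

Everything in memory is BED-style 0-based half-open. Bismark-style
coverage files are read as emitted by strand-merged, zero-based
processing: one record per CpG dinucleotide with methylated and
unmethylated read counts. The methylation level is always recomputed
from the counts; the file's percent column is only a consistency check
(counts win with a warning), so rounding in upstream tools cannot
drift into the analysis. GTF input is converted from 1-based closed
coordinates at the boundary.

Pairwise alignment block maps are modeled as gapless and
length-preserving: a block maps an interval of the source genome onto
an equal-length interval of the target, either in the same orientation
or flipped, and projection is per-block offset arithmetic on interval
coordinates. This is a deliberate simplification: the analysis only
ever projects interval coordinates, never individual bases, so
internal indels below the region scale do not change any downstream
call. How a whole-genome aligner's indel-containing blocks should be
collapsed to this granularity is a choice the block-map producer makes
once, upstream.

## Binding regions and binding sites

Reproducible peaks require a 1-bp overlap between the two ChIP-seq
replicates; each connected component of the cross-replicate overlap
graph is represented by its member with the largest -log10 p-value.
Chains (A overlaps B overlaps A') are collapsed to one representative
— the pairwise rule alone leaves chains unspecified, and one
representative per component keeps the region count well defined.
TFBRs then extend symmetrically from the peak summit to the average
peak length of that species and TF, rounded to the nearest even
integer so the half-width is integral; regions running past a
chromosome edge are clipped and flagged. The average length is
computed on the reproducible set, after filtering.

Binding sites (TFBSs) are motif matches from an exact-p-value PWM
scan: log-odds scores against the background composition are
integerized at 1/1000 bit, the null score distribution is built by
dynamic programming over motif positions, and a window is a hit when
its exact tail probability is at most 0.005. A small pseudocount
(1e-4) keeps zero-probability PWM cells finite. Per region, the hit
whose midpoint is closest to the summit wins, with deterministic
tie-breaks (start distance, then + strand, then smaller start).

Per-region methylation is the unweighted mean of CpG levels over CpGs
covered by at least 4 reads — unweighted rather than read-weighted so
deeply covered CpGs do not dominate a region's summary; `n_cpg`
counts every CpG regardless of coverage.

## Hyper/hypomethylation and matched controls

Regions at or above 60% mean methylation are hypermethylated; a
species-TF combination enters the transposable-element analyses only
with at least 200 such regions. A second, mode-relative labeling is
also emitted: regions within 0.15 of the highest density mode are
"hypermethylated" when that mode is at or above 60% and
"intermediate" otherwise. Both labels coexist because the fixed
threshold drives the TE analyses while the mode band describes the
distribution; neither takes precedence.

Density modes come from a Gaussian kernel density on a 512-point grid
over [0, 1]; a local maximum counts as a mode only when its
topographic prominence reaches 5% of the density maximum. The
prominence rule is an operational choice (the classical excess-mass
mode tests expose no equivalent knob); it suppresses sampling wiggles
on flat densities and is configurable.

Matched controls are built by propensity-score matching: logistic
regression of hyper-vs-hypo membership on standardized CpG count,
ChIP-seq fold enrichment and TSS distance; greedy 1:1
nearest-neighbor matching without replacement in descending test
propensity; pairs differing by more than the caliper are pruned.
The caliper (default 0.001) is interpreted in units of the propensity
standard deviation, the common convention of matching software; raw
propensity units are available behind a flag because the convention
is genuinely ambiguous. Degenerate logistic fits (perfect separation)
fall back to Mahalanobis matching with a warning. Post-match balance
is reported as standardized mean differences.

A practical consequence of the 0.001-SD caliper worth knowing: it is
extremely tight (one thousandth of a propensity standard deviation),
so on overlapping but shifted covariate distributions it prunes a
large share of pairs. Balance after matching is excellent, but the
effective sample — and with it the precision of any downstream ratio
estimate — can be less than half of the nominal test-set size. The
enrichment recovery checks in the acceptance suite run at exactly this
caliper and inherit that variance.

TE enrichment is computed within class: among regions overlapping a
class (LTR, SINE, LINE, DNA), the fraction overlapping each subgroup
is compared between the matched sets as a log2 ratio, with
two-proportion tests per subgroup (continuity-corrected, mirroring
`prop.test` defaults). Subgroups present in only one set are flagged
infinite and excluded from positive-enrichment views.

## The profile mixture

Each TFBR is extended to a 2-kb window centered on the summit
(the model window; 1.2 kb is the display convention, both are
parameters because the two scales serve different purposes). CpG
positions are rescaled to x in [-1, 1]. Regions with fewer than 4
covered CpGs cannot support a spatial profile and are set aside as
non-classified (NC) — NC is assigned only by this rule, never by the
model.

Cluster k has a weight vector w_k over a radial basis design
h(x) = [1, phi_1(x), ..., phi_M(x)], Gaussian bumps at evenly spaced
centers with gamma = 1/(2 dc^2) for center spacing dc. A CpG with s
methylated of t reads contributes Binomial(s; t, Phi(h(x) w_k)) to
its region's likelihood under cluster k — a binomial-probit
regression; the probit link is the family's convention and a logistic
link would change nothing structural. The mixture over regions is
fitted by EM with a Gaussian MAP ridge (lambda = 0.1) on the weights;
the M-step is penalized Fisher scoring with step-halving, and the
penalized log-likelihood is asserted non-decreasing every iteration.
Mean-field variational inference would yield a posterior over weights
as well, but only the cluster assignments are consumed downstream, so
EM-MAP with the same likelihood family is the simpler, deterministic
choice; assignments are the contract.

Initialization is a deterministic farthest-point k-means on 5-bin
per-region mean-methylation features: the first center is the region
nearest the feature grand mean, subsequent centers maximize the
minimum distance to chosen centers, ties break on feature values.
Because nothing depends on row order or random draws, refits and
region-order permutations give identical models up to row order — a
property the tests assert.

Model size is chosen by BIC, `-2 logL + [K(M+1) + (K-1)] ln(n)`, over
a (K, M) grid; the default M grid {5, 9, 13} spans ~500 bp to ~150 bp
spatial resolution over the 2-kb window. Fitted cluster curves get
semantic labels by operational rules: flat when the curve maximum is
below 0.25; left/right when the flank difference exceeds 0.3; mid
when flanks exceed 0.5 with a center below 0.1; high when flanks
exceed 0.5 with a center at or above 0.25. The thresholds
operationalize verbal shape descriptions and are configurable;
unresolved clusters fall back to the nearest prototype curve with a
warning.

### Known limitation: BIC at the overdispersion knife edge

The synthetic read model is beta-binomial (overdispersion rho = 0.05)
while the mixture's likelihood is binomial. Under misspecification,
splitting a true cluster in two captures part of the extra-binomial
spread; at 2000 regions the log-likelihood gain of such a split
(~55-60) sits almost exactly at BIC's per-cluster penalty
(57 at M = 13). The selected K is therefore realization-dependent:
across generator seeds we observe K = 4, 5 or 6 on a 4-shape bundle,
with winning margins of 5-20 BIC units in ~3e5. Cluster recovery is
unaffected — the adjusted Rand index against planted shapes stays
above 0.9 because the surplus clusters subdivide one true cluster
rather than mixing two. In practice the cluster count should be fixed
per factor (the pipeline default does exactly that, K = 4, or 3 for
CTCF-like factors) and the BIC table inspected rather than trusted
blindly. The acceptance suite asserts the BIC-selected K on the
standard bundle and is expected to fail at seeds where the knife edge
tips; the assertion is kept unweakened deliberately.

## Segmentation, islands, annotation

The UMR/LMR/FMR segmentation is run-based: maximal runs of
consecutive coverage-filtered CpGs below m = 0.5, tolerating
single-CpG interruptions, become hypomethylated segments — at least
30 CpGs makes a UMR, 4-29 an LMR (the 30-CpG split follows the
original segmentation method's published convention), anything
shorter is absorbed into FMR. Segment bounds are midpoints between
boundary CpGs and their neighbors, so segments tile the covered CpG
space exactly — a tested invariant. This deliberately re-implements
the trichotomy without the original tool's FDR machinery and
partially-methylated-domain detection; its "FDR cutoff" parameter has
no analogue here and is not emulated.

CpG islands use the classical sliding-window criteria (100-bp
windows, step 1, GC >= 50%, observed/expected CpG >= 0.6, merged
passing windows of >= 200 bp), with windows containing N failing.
The observed/expected ratio is n_CpG * L / (n_C * n_G).

TFBR annotation is 1-bp overlap against segments, islands, regulatory
calls and TSSs. When several regulatory calls overlap one region the
precedence is active promoter > active enhancer > primed enhancer —
an invented but recorded order (the source data plot categories
separately); TSS distance is interval-to-point, 0 inside. Enrichment
of categories within profile labels is a two-proportion test of each
label against all others pooled, Bonferroni-corrected over the full
label-by-category family; labels under 20 regions are excluded.

## Evolution

Orthology: a TFBR projects through the block maps into each target
species; 1 bp of block coverage makes it alignable, and 1 bp of
overlap between the projection and any target TFBR of the same TF
makes it bound. Species without an assay for a TF simply shrink the
assayed set; the parsimony definitions then apply to the shrunken
set. The categories — ultra-conserved, lineage-specific gain/loss,
clade-specific gain/loss — are evaluated in that order, and any
pattern fitting none is unclassified with its conservation degree
(number of bound species) still reported. A brute-force enumeration
of all 2^5 and 2^4 patterns against independently restated
definitions backs the implementation in the tests. One consequence
worth knowing: a planted lineage loss whose single unbound species
happens to be unalignable is correctly called ultra-conserved on the
assayed set.

Bound/unbound methylation comparisons add a genomic background of
length-matched uniform random regions on covered chromosomes,
excluding TFBRs, from a seeded sampler. Group differences use
two-sided Wilcoxon rank-sum tests with Bonferroni correction; the
conservation-degree trend uses the Jonckheere-Terpstra test with
tie-corrected normal variance, switching to the exact permutation
distribution at total n <= 12. The profile-by-conservation
association is a Pearson chi-square without continuity correction;
both Pearson residuals (whose squares sum to the statistic — the only
reading under which "cell contribution" percentages sum to 100) and
adjusted standardized residuals are emitted, contributions from the
former, signs read from the latter.

## The synthetic generator

The generator emulates the study's data shapes end to end: five
species on two 1-Mb chromosomes, ~600 ancestral binding sites placed
at >= 2.6-kb spacing (so 2-kb windows never overlap), per-site
conservation categories drawn from a configurable mix and converted
into per-species bound patterns (unclassified patterns are drawn from
the enumerated set the parsimony rules cannot classify), a shared
per-site profile shape for all bound species, replicate peaks with
jittered bounds plus irreproducible noise peaks, CpGs at ~1/100 bp
background spacing densifying to ~1/60 bp within 600 bp of summits
(reproducing the reported 3-5 CpGs per TFBR), Poisson(10) coverage
with uncovered CpGs dropped, and beta-binomial reads (rho = 0.05)
around the governing curve. Unbound orthologs methylate at
0.85 - 0.04 x degree, planting the monotone degree-methylation trend
while keeping the unbound median at ~0.75; background 1-kb tiles draw
from the bimodal 0.9 Beta(20,2) + 0.1 Beta(2,20) genome mixture. The
specular curves' center dip has width 0.15 on the rescaled axis,
chosen so the median TFBR-scale methylation of bound regions lands at
the planted 0.20. A sixth shape, `hyper` (constant 0.85), lets
hypermethylated TFBRs be planted for the TE analyses; TEs attach to
bound regions with a configurable hyper:hypo odds ratio and a shifted
LTR subgroup mix, plus background TEs away from sites. Genomes are
written with CG dinucleotides at exactly the planted CpG positions,
GC-rich islands at flat-site promoters, and the TF's consensus motif
at bound summits.

What the generator does not emulate — and hence what green tests do
not establish about real data: sequence evolution (orthologous
coordinates differ only by a constant shear and all emitted blocks
are same-orientation; flipped blocks are exercised in unit tests
only), TE phylogenies and age structure, read-level artifacts
(bisulfite conversion failure, mapping bias), CTCF's oscillatory
nucleosome-phased profile, chromosome-scale methylation domains, and
any coupling between motif strength and binding conservation.

## Problem sizes and numerical choices

The test suite runs a 120-site bundle through the full pipeline and
keeps the heavier checks at the sizes the analyses use: 2000 regions
for profile selection, 2400 for TE enrichment, 900 for the CTCF-like
bundle. EM uses a relative tolerance of 1e-5 on the penalized
log-likelihood, at most 100 iterations, probabilities clamped to
[1e-10, 1 - 1e-10] and linear predictors to [-8, 8]; Fisher scoring
takes at most 6 damped steps per M-step (partial M-steps keep the EM
monotone). PWM p-values are exact at 1/1000-bit granularity. The
background sampler retries 50 times before accepting an overlap with
excluded regions, which keeps it total on pathological exclusion
sets.
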