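---
title: "Diversity analysis of structured germplasm collections with germdiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diversity analysis of structured germplasm collections with germdiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(germdiv)
```

## The analysis problem

A genotyped genebank collection is a samples × markers matrix — allele
dosages 0/1/2 (with missing calls) for biallelic SNPs, or present/absent
calls for dominant markers — plus marker metadata (chromosome, genome
class, bp and cM positions) and passport metadata (taxon, biological
status, declared ploidy, origin). `germdiv` takes such a collection
through quality control, diversity description, structure discovery,
differentiation testing, core-subset construction and consensus-map
building. This vignette records the models behind each stage, the
parameters that matter, and the design choices made where the methodology
leaves room.

## Quality control

Markers are filtered first, then samples, because marker-level missingness
and allele frequencies are estimated across all samples before any sample
is judged: markers are kept when their missing fraction is at most 0.50
and their minor allele frequency strictly exceeds 0.001; samples are kept
when their missing fraction is at most 0.50 (0.75 for wild relatives,
whose ascertainment against cultivated references is poorer).
The MAF rule is a *strict* keep (`> 0.001`): a marker sitting exactly at
the threshold is discarded. For presence/absence markers a single filter
retains markers with missing fraction at most 0.80 — dominant markers
tolerate more missingness since absence itself is informative. All filters
are idempotent and report per-rule removal counts that reconcile exactly
with the input/output dimensions.

Ploidy QC rests on the fraction of each sample's scored markers that map
to the D genome. Bread wheat (AABBDD) carries it; durum-type tetraploids
(AABB) do not. A declared tetraploid with more than 10% D-genome markers
is flagged suspect (strongly above 20%); a declared hexaploid with fewer
than 20% is flagged the other way; wild relatives are not judged. The
denominator is the sample's non-missing markers (for dominant data, the
*present* ones — an absent fragment is no evidence the genome is present).

## Diversity indices

For a biallelic locus with alternate-allele frequency $p$ (estimated as
the dosage sum over twice the number of called samples):

* expected heterozygosity $he = 1 - p^2 - (1-p)^2 = 2p(1-p)$, maximal at
  0.5 when $p = 0.5$; $2\,he$ rescales it to a 0–1 range;
* observed heterozygosity $ho$, the fraction of heterozygous calls among
  called samples;
* inbreeding coefficient $f = 1 - ho/he$, undefined (and excluded from
  averages) at monomorphic loci;
* Shannon index $sh = -p\log_2 p - (1-p)\log_2(1-p)$ with
  $0\log 0 = 0$, maximal at 1 when $p = 0.5$.

Population averages run over loci with defined values only, with the
counts reported.

## Distances

The Modified Rogers distance between individuals $x$ and $y$ treats each
genotype as a within-individual allele-frequency vector
$(1-d/2,\,d/2)$ for dosage $d$ and takes the Euclidean distance between
the stacked vectors scaled by $1/\sqrt{2L}$, which bounds it on $[0,1]$
(0 for identical genotypes, 1 for opposite homozygotes at every locus).
Under missing data the sum runs over each pair's pairwise-complete loci
with per-pair rescaling $1/\sqrt{2L_{xy}}$ — unbiased when missingness is
completely at random and identical to the complete-data formula otherwise.
Pairs sharing fewer than `min_overlap` loci (default 10) are flagged
missing rather than estimated. Whether to rescale or impute under
missingness is a genuine methodological fork; pairwise-complete rescaling
is this package's choice because it needs no imputation model.

For presence/absence data the Jaccard similarity
$n_{pp}/(n_{pp}+n_{pa}+n_{ap})$ excludes absent/absent agreements, which
dominate dominant-marker data and carry no shared-ancestry signal. The
formula as written is a *similarity* (1 for identical profiles); both it
and the distance $1 - j$ are returned, and clustering/MDS consume the
distance form.

## Embeddings and clustering

Classical (Torgerson) MDS double-centers the squared distances and takes
the top three eigenvectors; negative eigenvalues — expected, since MRD
under pairwise rescaling need not be Euclidean — are truncated at zero and
reported. SMACOF minimizes the same raw stress
$\sum_{i<j}(d_{ij}-\hat d_{ij})^2$ by Guttman-transform majorization,
initialized from the classical solution; the majorization guarantees a
monotonically non-increasing stress sequence, the convergence discipline
is a relative stress decrease below $10^{-6}$ or 300 iterations, and the
result can never be worse than its classical starting point. Embeddings
export directly to CurlyWhirly coordinate files for 3-D inspection.

Hierarchical clustering uses the Lance–Williams agglomerative recurrence;
Ward's minimum-variance linkage on the distances (the `ward.D2`
convention) is the default, as a single consistent choice also required by
the core-subset strata, with average and complete linkage available. The
number-of-clusters diagnostic is the pseudo-F (Calinski–Harabasz) ratio
computed purely from distances:
$W = \sum_c \frac{1}{n_c}\sum_{i<j\in c} d_{ij}^2$,
$T = \frac{1}{n}\sum_{i<j} d_{ij}^2$, $B = T - W$ and
$F(k) = \frac{B/(k-1)}{W/(n-k)}$, which coincides with the coordinate
variance ratio when the distances are Euclidean. The profile reports the
global maximum and all local maxima but never auto-commits a $k$ on the
user's behalf: cluster counts in germplasm studies are judgment calls made
against the profile, and the API reflects that (downstream defaults use
the global maximum, overridable).

## Differentiation

Diversity partitioning follows Nei: per locus, $H_S$ is the average
within-group expected heterozygosity, $H_T$ the expected heterozygosity of
the pooled frequency, $D_{ST} = H_T - H_S \ge 0$ by Jensen's inequality,
and $F_{ST} = D_{ST}/H_T$ (undefined and flagged when $H_T = 0$). Group
weighting defaults to *equal* — plain averages across groups, matching the
"average value" definition of $H_S$ — with size weighting available. The
global statistic is the ratio of sums $\sum D_{ST} / \sum H_T$ over
defined loci, which is robust to low-diversity loci in a way the mean of
per-locus ratios is not (the mean is reported alongside). The
Weir–Cockerham variance-component estimator is deliberately *not* used
anywhere: the package implements Nei's quantities throughout, including in
windows, for internal consistency.

Significance comes from permutation: group labels are shuffled uniformly
(preserving group sizes), the global FST recomputed per permutation, and
the observed value compared against the null's 90th and 95th percentiles;
the p-value uses the add-one estimator $(\#\{null \ge obs\}+1)/(B+1)$,
which cannot return 0. Windowed scans tile each chromosome with fixed,
non-overlapping, 0-based half-open windows (default 1 Mb) and aggregate by
the same ratio of sums; the per-cluster-split footprint scan walks the
tree from 2 to $k_{max}$ groups and profiles each split's two daughter
groups, ranking windows by weighted FST — the top windows localize the
variants driving that separation. AMOVA supports three
marker-informativeness modes (polymorphic in the pooled collection, per
compared pair, or within every group), because with heterogeneous
germplasm the informative marker set changes with the comparison.

## Core subsets (D-method)

The core workflow: Ward strata on the MRD matrix (stratum count from the
pseudo-F global maximum unless fixed); allocation of
$N = \mathrm{round}(0.20\,n)$ slots proportional to each stratum's mean
within-cluster MRD $d_k$ — diversity-proportional, *not*
size-proportional, so a small but diverse stratum outweighs a large
uniform one; largest-remainder integerization so the total hits $N$
exactly, with floors of one slot per non-empty stratum and caps at stratum
size redistributed by remainder order; 1000 stratified random candidates
each drawing the allocated counts without replacement; and selection of
the candidate maximizing the mean pairwise MRD among its members.
All-zero $d_k$ (every stratum a singleton) falls back to
size-proportional shares, recorded in the result. The candidate score is
the mean *within-candidate* pairwise distance; mean distance to the
remainder is a defensible alternative, and the scoring function is
isolated (`select_core`) so it can be swapped. Diagnostics compare the
core's diversity indices with the full collection and report the fraction
of segregating alleles retained. The whole workflow is deterministic given
the data and seed.

## Consensus maps

Per chromosome, the consensus starts as the seed map. Each pending
linkage group is scored by its commonality with the current consensus —
Pearson correlation $r$ of the shared markers' positions times
$\ln(n_{common})$, requiring at least three shared markers and non-zero
positional variance. The best-scoring eligible group joins when
$r > 0.5$, its new markers placed by piecewise-linear interpolation
through the shared anchors (anchors never move; markers beyond the
terminal anchors extrapolate at the local scale of the two nearest
anchors; coincident anchors with conflicting positions use the midpoint,
logged); otherwise it is rejected. Joined or rejected, the group leaves
the queue — rejected groups are not retried after later joins enlarge the
consensus, following the one-pass removal discipline, and ties on the
commonality score break by queue order, recorded in the join log. The log
base in the commonality score only rescales it monotonically, so group
ranking — the score's only use — is base-invariant; natural log is used.

## The synthetic-data generator

Real genebank datasets at the scale that motivates this pipeline are
access-restricted, so validation runs on generated collections whose
ground truth is known by construction:

* **Structure.** $K$ subpopulations drift from ancestral frequencies
  $p_i \sim U(0.1, 0.9)$ under the Balding–Nichols model,
  $p_{ik} \sim \mathrm{Beta}\!\big(p_i\frac{1-F}{F},\,(1-p_i)\frac{1-F}{F}\big)$,
  chosen over alternatives precisely because Nei's FST then has the
  closed-form expectation $F(K-1)/(K-F)$ under equal-weight pooling —
  the generator's headline recovery oracle. Genotypes are
  $\mathrm{Binomial}(2, p_{ik})$ draws; loci are independent (no LD), so
  the generator validates frequency-based machinery, not haplotype
  methods.
* **Missingness** is completely at random at a configurable rate — the
  simplest model consistent with marginal missing-rate filters; informative
  missingness (e.g. presence/absence confounding) is not emulated, so
  passing tests say nothing about MNAR robustness.
* **Positions.** Loci scatter uniformly over 100-Mb pseudo-chromosomes
  (named with wheat-style genome suffixes A/B/D), so 1-Mb windows hold
  about $L/(100\,\cdot\,\#chrom)$ loci at desk scale.
* **Sweeps** shift two subpopulations' frequencies in opposite directions
  inside a bp window (clipped to $[0,1]$) and regenerate the affected
  genotypes — a frequency-displacement caricature of a selective sweep
  adequate for testing window localization, without hitchhiking or
  haplotype structure.
* **Ploidy misclassification** relabels a fraction of passports against
  their D-genome marker profile, with clean margins (true D fractions near
  1/3 versus thresholds at 0.10/0.20), making QC recovery exact by
  construction.
* **Linkage maps** subsample a true map and distort each population's
  scale affinely (`a` near 1, random shift) plus Gaussian cM noise —
  monotone-transform distortion that exercises the consensus algorithm's
  anchor logic, not genotyping-error or inversion artifacts.
* **Admixed accessions** (optional) draw genotypes from 50/50 mixtures of
  two subpopulation frequency vectors — the minimal structure needed to
  exercise intermediate positions in MDS and clustering.

Everything is deterministic given the spec and seed.

## Numerical choices and degenerate inputs

* Missing dosage is `NA` at every layer, never conflated with dosage 0.
* bp positions are stored 1-based (as in VCF/map files); window arithmetic
  converts to 0-based half-open internally.
* $D_{ST}$ is clamped at 0 against floating-point jitter; the Jensen
  guarantee $H_T \ge H_S$ is asserted in the test suite under both
  weightings.
* All-missing loci, $he = 0$ loci (for $f$), $H_T = 0$ loci, zero-overlap
  sample pairs, all-absent profile pairs and singleton strata are each
  flagged and excluded from averages rather than silently zeroed.
* Merge ties in clustering and score ties in candidate selection and
  consensus joining break deterministically (lowest index / first
  occurrence / queue order).

## Validation scale

The test suite and acceptance script run at desk scale, chosen so each
property is measured where it is sharp: brute-force oracle comparisons at
$n \le 10$ (exact), Balding–Nichols FST recovery at $K=3$, 100 samples
per subpopulation, $L = 2000$ over 20 seeds (tolerance ±0.03 around
0.1429), permutation type-I error at 200 replicates × 1000 permutations
($L = 200$), sweep localization at 10 seeds with a 0.45 frequency shift,
consensus recovery over 5 maps × 200 markers at 0.5 cM noise, and the
full core pipeline at 2000 accessions × 1000 loci. The desk-scale
contract for interactive use is $n \lesssim 5000$ samples; the 60k-scale
out-of-core engineering such collections need upstream is out of scope.

## Known limitations

* Biallelic/binary markers only; multi-allelic VCF records are rejected
  (or dropped on request), and the index formulas are implemented for the
  two-allele case.
* Nei's estimators are uncorrected for small within-group sample sizes;
  with very small groups the within-group heterozygosity is biased
  downward, inflating FST slightly — visible as the few-thousandths excess
  over the closed form in the recovery tests.
* No LD modelling anywhere: simulator loci are independent and no
  LD-thinning utilities are provided.
* The consensus algorithm trusts chromosome assignments; it does not
  detect misassigned linkage groups beyond the correlation gate.
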