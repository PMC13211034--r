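---
title: "Grain counting from spike images and QTL mapping in doubled-haploid barley"
author: "grainQTL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grain counting from spike images and QTL mapping in doubled-haploid barley}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grainQTL)
```

# The problem

Grain number per spike is a primary yield component in barley. A
practical phenotyping route is to photograph intact two-rowed spikes on a
dark surface, isolate the spike from the background, count grains, and
feed the per-genotype averages into a single-QTL genome scan over a
doubled-haploid (DH) mapping population. grainQTL implements that whole
chain as reusable, tested functions, together with a synthetic-data
module that generates every input the chain needs — genetic maps, DH
genotypes, partially replicated field layouts, phenotypes with a planted
QTL, detector-style count errors, and rendered spike images with exact
per-grain ground truth — so the pipeline can be exercised and calibrated
end to end without any external data.

# Synthetic data: what it emulates, and what it does not

`simulateMap()` defaults to a seven-chromosome barley map with
204/493/472/236/609/308/454 markers (2776 in total); cM positions are
sorted uniforms and physical positions are affine in cM, which is all
that downstream interval queries consume. `simulateDHGenotypes()` builds
each line as one recombinant gamete doubled: a two-state Markov chain
along each chromosome whose switch probability is the Haldane
recombination fraction `rf = (1 - exp(-2d/100))/2` of the marker gap.
Haldane (no interference) is the standard genome-scan convention and is
used consistently here for simulation and for the genotype-probability
HMM. Missing-data masking is applied before genotyping error, so only
retained calls can be wrong.

`simulateField()` reproduces a partially replicated trial: 183 genotypes
on 229 plots, 36 duplicates and 5 triplicates (a 22.4% replication rate).
The source trial's grid dimensions are not published anywhere we could
consume, so a 12 x 20 grid is the package default; nothing downstream
depends on the exact dimensions. `simulatePhenotypes()` draws plot values
from the additive row-column model

y = mu + g + r + c + a*x + e,

with independent Gaussian genotype, row, range and residual effects and a
planted QTL coded x = +1/2 (allele A) / -1/2 (allele B), so the additive
effect `a` equals the A-vs-B mean difference in grains. Defaults are the
study conditions: mu = 25.36 and the REML variance partition
(0.0099, 0.787, 0.523, 7.286). Per-head counts add head-to-head noise
(default SD 2 grains, a plausible within-plot spread for 3-7 sampled
heads) and are rounded to integers >= 1; the latent pre-rounding plot
value is retained in the table because integer rounding hides sub-grain
differences that parameter-recovery harnesses need to see.

The spike renderer draws elliptical grains whose centroids sit on a
quadratic rachis curve, tilted alternately to the two sides in the
two-row pattern, with a connecting rachis stem, optional thin awns and —
in cluttered mode — a white label and ruler confined to a bottom clutter
band so that a fixed crop removes them deterministically. It makes no
attempt at lighting physics, awn texture or six-rowed morphology: it
exists to exercise the mask pipeline with exact ground truth, and passing
its tests shows the chain's logic is correct, not that the default HSV
bounds would segment arbitrary real photographs.

# The image chain

`preprocessSpike()` mirrors a classical OpenCV-style workflow: crop the
label margins; build an HSV colour mask (8-bit convention, H in [0,179];
default yellow-brown band H 10-40, S >= 50, V >= 50) OR-ed with a
value-channel mask; zero the background; convert to grey (luma weights
0.299/0.587/0.114, which the source workflow never specifies) and blur
with a 5 x 5 Gaussian; threshold with Otsu's method (ties broken toward
the smallest threshold; constant images are flagged degenerate);
morphologically open with a 2 x 2 element to break weak bridges (opening
rather than bare erosion, which would shrink grains); take the largest
8-connected component, fill its convex hull and dilate with a 15 x 15
element; AND the *unrefined* Otsu mask with the dilated hull (the
refined mask only serves to locate the main contour); and composite the
original pixels over black. Canny edges (bilateral prefilter, 50/150
hysteresis defaults) are an annotation aid only and never feed the mask.

Numerical conventions worth knowing: hull filling is implemented as a
half-plane test over the bounding box, so it agrees exactly with a
brute-force convex hull on pixel centres; connected components are
8-connected; the structuring elements are squares, with even sizes
anchored at the top-left of the central cell.

`countGrains()` stands in for a learned detector: 8-connected components
with a minimum area, optionally split at distance-transform maxima
(watershed, merge tolerance 1 in distance units) — this is what carves
grain bodies off the connecting rachis and separates touching grains.
`agreement()` computes the detector-validation statistics: Pearson r and
R^2, the OLS fit of model counts on manual counts, mean error bias, MAE,
the sample (n-1) SD of errors, the error range, and within-k fractions
using the inclusive rule |error| <= k (the convention is not stated in
the source; inclusive was chosen and is documented here). Because
simulated model counts are integers, the generator's exact error SD is
the discretized-normal SD (about 1.882 for an underlying 1.86); recovery
tests compare against that closed-form value.

# Phenotype QC and variance partitioning

Plot values are means over technical replicates. Replicate consistency is
summarised by per-genotype CV and range with class averages, and by
repeatability — the Pearson correlation across duplicate plot pairs,
ordered by plot id (the pairing order is not published; plot-index order
is a documented choice whose effect is confined to the sign-symmetric
correlation). Genotype values use the mean of plot means unless two
replicates differ by more than 5 grains, in which case the median is
used. For duplicates the median of two plot means would equal their mean,
so the rule is applied to the genotype's pooled head-level counts by
default (`medianOn = "plot_means"` restores the literal reading); this is
the one genuinely ambiguous rule in the source procedure and the package
makes the interpretation switchable.

Variance components of y = mu + g + r + c + e are fitted by REML with
`lme4::lmer` (genotype, row and range as independent random intercepts —
no spatial autocorrelation structure, matching the printed model), and
plot-level broad-sense heritability is
H2 = sG2 / (sG2 + sR2 + sC2 + sE2). A Shapiro-Wilk gate (pass iff
p > 0.05) guards the scan input.

# The genome-scan stack

`calcGenoprob()` runs a two-state forward-backward HMM per chromosome and
line: uniform start, Haldane transition from cM gaps, emission 1-e on a
match, e on a mismatch (default e = 0.002) and 1 on missing, so flanking
markers inform missing calls. `scan1HK()` is Haley-Knott regression on
P(AA): per marker, LOD = (n/2) log10(RSS_null / RSS_full), the null model
holding intercept plus any fixed covariates. Lines with missing
phenotype are dropped globally; genotype missingness never drops a line
because it is absorbed by the HMM posterior. Scan positions are markers
only — no pseudomarkers — so peaks are exactly reproducible at named
markers.

Kinship is the allele-sharing GRM: K_ij is the mean over markers of
sum_g p_ig p_jg, with unit diagonal; the LOCO variant excludes the
scanned chromosome. `scan1LMM()` eigen-rotates each LOCO matrix,
estimates the polygenic variance fraction once per chromosome by REML
under the null (profiled criterion optimised on (0,1), boundary checked
at 0; REML rather than ML is a documented choice), holds it fixed across
that chromosome's markers, and computes the LOD as the log10 likelihood
ratio of weighted least-squares fits — with identity kinship this
collapses exactly to Haley-Knott. Structure correction alternatives:
`pcaMarkers()` (A=0/B=1 coding, markers with >= 20% missing dropped,
mean imputation, centring and scaling) feeding the first five PCs as
fixed covariates, and `kmeansClusters()` (25 restarts on the first three
PCs, labels ordered by cluster size) feeding `nestedANOVA()`, which
F-tests whether the marker adds signal beyond cluster assignment and
errors out when the marker is aliased with the clusters.

`permutationThreshold()` shuffles the phenotype across lines — covariates
and kinship stay bound to their genotype rows, the configurable
alternative being noted but not default — reruns the scan per
permutation, and returns the empirical (1 - alpha) quantile
(order-statistic quantile with linear interpolation, R type 7) of the
genome-wide maximum LOD over 1000 permutations, seed 123 by default. The
permutations are batched through the same closed-form projection algebra
as the scans, so a full-map 1000-permutation threshold takes about a
second.

A calibration caveat that the test suite makes explicit: a permutation
threshold is exact for phenotypes exchangeable with respect to the
scanned genotypes. A polygenic background *linked to the scanned map* is
not exchangeable — LOCO deliberately refuses to absorb same-chromosome
signal (that is what protects a real QTL from being eaten), so under a
linked infinitesimal background the scan genuinely detects proximal
polygenic variation and the genome-wide error rate exceeds alpha. With a
biparental-DH GRM built from a few dozen markers the effect is dramatic,
because single kinship eigenvectors align with single-marker splits. The
null-calibration tests therefore draw the background from loci
segregating independently of the scanned markers; the type-I criterion
is checked with pure-noise phenotypes on the full-size map.

`alleleEffect()` reports class means, the pooled-variance Student's
t-test (the source names Student, not Welch), the effect mean(A)-mean(B),
and PVE = 100 R^2 from the phenotype-on-genotype regression.
`pickPeakMarker()` takes the maximal-LOD marker, breaking ties (within
1e-6, which covers perfectly concordant colocalized markers) by fewest
missing calls, then map order.

# Candidate-gene interval queries

`genesInInterval()` reads GFF3 via rtracklayer, keeps only features of
type "gene", and applies inclusive 1-based any-overlap semantics — a gene
containing an interval endpoint counts, which matches how the source
interval's boundary gene is treated; containment is deliberately not
required. `markerToBp()` / `flankingInterval()` turn flanking markers
into physical intervals.

# Problem sizes and test design

The suite runs the oracle equivalences (HMM vs exhaustive enumeration at
<= 8 markers, HK vs normal equations, Otsu vs exhaustive search, hull vs
brute force) at full fidelity, the permutation type-I check over 100 null
datasets of 153 lines on the full 2776-marker map with 1000 permutations
each, effect recovery over 100 seeds at the study's phenotype SD, REML
recovery at 200 genotypes x 2 plots over 20 seeds, and the imaging
corpus at 100 rendered spikes (recall and false-positive rates measured
on the first 50). These sizes keep the whole suite within a desk-scale
run while leaving each statistical check enough replication for its
stated tolerance.

# Known limitations

The classical counting path assumes grains form one connected silhouette
with the rachis and separates them by distance-transform splitting; it is
not a learned detector and is not expected to match one on real images
with crossing awns or occlusion. The renderer's hue band and the
pipeline's default HSV bounds are co-designed; real photographs need
user-supplied bounds. Interval queries do not perform any functional
annotation. And the LOCO mixed model's proximal-contamination behaviour
described above is a property of the method, not a bug in the
implementation.
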