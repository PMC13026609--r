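---
title: "Methods: kinship inference on medium-density SNP panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinship inference on medium-density SNP panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinsnp)
```

## The problem

Forensic investigative genetic genealogy works with medium-density SNP
panels of roughly 10,000 autosomal markers. At that density, pairwise
kinship must be inferred from noisy genotype data without phased
haplotypes, and the practical question is how far out (in degrees of
kinship) inference remains reliable. `kinsnp` is a workbench for answering
that question by simulation: it simulates truth-annotated relative pairs on
a synthetic panel, detects shared identity-by-descent (IBD) segments with
two different algorithms, classifies each pair with five inference methods,
and scores everything against the simulated truth.

Degrees of kinship are used as ordinals 1-9; parent-child and full siblings
are both degree 1, and a degree-d pair has expected kinship coefficient
$\varphi = 2^{-(d+1)}$. Unrelated pairs carry ordinal 10 internally (so
margin arithmetic extends naturally) and render as "unrelated".

## The simulator

Founders are drawn under Hardy-Weinberg equilibrium: each locus dosage is
Binomial(2, alt_freq), loci independent (linkage equilibrium). The panel
fixture spreads its loci over the 22 autosomes proportionally to GRCh38
chromosome lengths (about 2,875 Mbp in total) and draws alternate-allele
frequencies from Beta(2, 2) clipped to (0.05, 0.95).

Gene dropping propagates founder haplotypes through one of 18 pedigrees
(degrees 1-9, see `relationship_catalogue()`). Each meiosis places
crossovers as a Poisson process with intensity 1 per 100 cM along the
genetic map, with no crossover interference. The default map is uniform at
1 cM/Mbp, totalling ~2,875 cM; a measured map can be supplied as a TSV of
(bp, cM) anchors. Haplotype labels are tracked exactly, so the true
IBD1/IBD2 intervals between the two target individuals are known without
error; genotypes are read off at the panel loci. Genotyping noise is
applied per call: missingness with probability $10^{-3}$ and genotype error
with probability $10^{-3}$ (an error replaces the dosage by one of the
other two codes uniformly).

What the generator deliberately does *not* emulate: linkage
disequilibrium between panel loci, the ascertained (high-MAF)
frequency spectrum of a real kinship panel, population structure,
crossover interference, and sex-specific map lengths. These omissions
matter, and are discussed under *Limitations*.

## IBD segment detection

**A1 — concordance runs with informativity filtering.** Two genotypes are
*concordant* when they share at least one allele, i.e. they are not
opposite homozygotes; an IBD1 tract is only half-identical, so genotype
equality would be the wrong notion. The base scan reports maximal runs of
consecutive concordant SNPs per chromosome (identical-by-state regions).
Missing calls neither break nor extend a run and are not counted in its
SNP tally. Filtering then removes runs shorter than 10 Mbp; computes for
each run the informativity
$$I_s(j) = \sum_{i \in M(j)} \frac{\mathrm{med}(I_c)}{I_c(i)},$$
where $I_c(i)$ counts how many reference-set base runs contain SNP $i$ and
the median is over SNPs appearing in at least one run, and removes runs
with $I_s \le 50$; finally it trims survivors against masked regions
(coverage gaps), keeping remnants only if still longer than 10 Mbp with
$I_s > 50$. SNPs that never appear in any reference run contribute
nothing to $I_s$. The informativity map is calibrated on the *unfiltered*
base runs of all reference pairs: the count is then well defined for every
pair composition, and hotspot SNPs (high $I_c$) are down-weighted exactly
where spurious IBS is concentrated.

**A2 — windowed kinship-coefficient scan.** Every window of 80 consecutive
SNPs (one window per starting ordinal; short chromosomes yield a single
window) is scored with the robust kinship coefficient restricted to the
window, and windows with $\varphi > 0.23$ are stored. Overlapping stored
windows merge into segments, anchored at their terminal SNPs. Each
segment's purity $p$ — the fraction of its non-missing loci at which the
pair shares at least one allele — must be at least 0.95.

Masks default to the panel's own coverage gaps (`derive_gap_mask()`, gaps
strictly longer than 5 Mbp), since long gaps are where run boundaries lose
positional meaning; a BED file of masked regions can be supplied instead.
The threshold comparisons are deliberately strict (`> 10` Mbp after
trimming, `> 50` informativity, `> 0.23` window coefficient, `< 0.95`
purity removed), matching the stated operating point of each filter.

## Classifiers

All classifiers that need calibration are fitted on the reference half of
the cohort only. Ties resolve toward the higher degree ordinal — the more
conservative claim of relatedness. Abstentions are first-class results and
score as incorrect.

* **Mean total segment length.** The pair's total detected length is
  matched to the nearest per-relationship reference mean $M_S$.
* **Gamma profiles.** Segment lengths of a relationship are approximately
  gamma distributed (recombination acting approximately as a Poisson
  process); the shape $k$ is fitted by maximum likelihood
  (`fitdistrplus::fitdist`) to the pooled reference segments and the scale
  is set to $\bar{x}/k$, pinning the fitted mean to the sample mean. A
  pair's own fit is compared to each reference by the mean absolute
  difference of the densities over the integer grid 1-150 Mbp; fewer than
  two (distinct) segment lengths force an abstention.
* **Conditional probability.** Total shared length is binned into 50 Mbp
  intervals over 0-3,000 Mbp; $P(R \mid S)$ is the reference count of
  relationship $R$ in bin $S$ over the bin total. Totals beyond the table
  clamp into the last bin; an empty bin falls back to the nearest populated
  bin (ties toward the lower bin).
* **IBD0 proportion.** The fraction of the genome with no detected
  sharing, $(G - \text{total})/G$, is matched to analytic inference
  ranges: parent-child expects 0 ($\le 0.1$), siblings 0.25
  ($(0.1, 0.365]$), degree $d \ge 2$ expects $1 - 2^{1-d}$ over
  $(1 - 2^{-(2d-3)/2},\; 1 - 2^{-(2d-1)/2}]$, and proportions above
  $1 - 2^{-17/2}$ are unrelated. The genome length $G$ defaults to the
  panel's covered span (sum over chromosomes of last minus first SNP
  position), because detected segments cannot extend beyond panel
  coverage; a fixed constant can be supplied instead.
* **Kinship coefficient.** The robust IBS-count estimator
  $$\varphi = \frac{N_{Aa,Aa} - 2N_{AA,aa}}{2N_{Aa(i)}} + \frac12
    - \frac{N_{Aa(i)} + N_{Aa(j)}}{4N_{Aa(i)}},$$
  with $i$ the sample with greater heterozygosity, classified by the
  half-open intervals $(2^{-(2d+3)/2}, 2^{-(2d+1)/2}]$ (unrelated at
  $\le 2^{-21/2}$; values above the degree-1 bound clamp to degree 1).
  This estimator cannot separate parent-child from siblings. The formula
  is implemented exactly as printed above; note that taking $i$ as the
  *more* heterozygous sample makes the estimator very slightly positive
  for unrelated pairs (the ratio term has expectation just below 1/2),
  which is visible at the unrelated/ninth-degree boundary.

PCA and PCoA pair embeddings (`pair_sharing_matrix()`, `embed_pairs()`)
are exploratory views of pairwise sharing only; no classifier is built on
them.

## Evaluation

An inference is correct when its degree ordinal equals the true degree
(relationship types within a degree are interchangeable). The
unrelated-collapse rule relabels inferences of sixth degree or more
distant as unrelated before scoring, stabilising the unrelated class. The
ROC sweep varies an acceptable margin of error $t = 0,\dots,5$ degrees:
TPR$(t)$ is the fraction of related pairs inferred within $t$ degrees of
truth, FPR$(t)$ the fraction of unrelated pairs inferred more than $t$
ordinals away from unrelated; AUROC is the trapezoid area over the
FPR-sorted points augmented with (0,0) and (1,1). This margin-sweep
construction is fixed and documented here precisely because ROC inputs for
ordinal classifiers are otherwise ambiguous; its AUROC values are
comparable between methods run through this package, but not directly
against AUROCs computed with other constructions.

## Problem sizes and numerical choices

The package's standard benchmark simulates all 18 related types plus
unrelated at 100 pairs per type, split 50/50 into reference and test
(`scripts/acceptance.R`); the test suite uses 40 pairs per type, and
property checks (sibling IBD0 fraction, realised-kinship means,
ninth-degree zero-sharing) use 400-2,500 gene drops with IBD tracking
only, which skips genotype read-off. Seeds flow from a single integer per
run; all randomness is reproducible.

Degenerate inputs are handled explicitly: empty segment sets have total
length 0; gamma fits abstain below two distinct lengths and fall back to
method-of-moments if the likelihood optimiser fails; windows without a
usable heterozygous locus are skipped; empty conditional bins defer to the
nearest populated bin; kinship coefficients above the degree-1 bound are
clamped.

## Limitations

The linkage-equilibrium founder model with a Beta(2, 2) frequency spread
is *harder* for IBD detection than real panel data in one specific way:
the spread includes many low-MAF loci whose opposite-homozygote
probability $2p^2q^2$ is tiny, so chance concordance runs extend much
further than they would on a high-MAF ascertained kinship panel, and
without LD structure the SNP-informativity filter is nearly flat and
cannot prune them. The consequence, which the benchmark itself
quantifies, is substantial background "sharing" for unrelated and
distantly related pairs, degrading exactly the classifiers that use
analytic (uncalibrated) thresholds — the IBD0 proportion and, to a lesser
extent, the kinship coefficient at the unrelated boundary. Reference-
calibrated classifiers absorb the background into their models.
Accuracy figures from this benchmark are therefore conservative for close
relationships and pessimistic at the unrelated boundary relative to what
the same algorithms achieve on real ascertained panels.

Second, the default uniform map totals ~2,875 cM, noticeably shorter than
a realistic sex-averaged human map (~3,400-3,500 cM). Fewer expected
crossovers mean fewer, longer segments and a higher probability that very
distant relatives share no IBD at all: the ninth-degree zero-sharing
fraction computed by the acceptance script sits a few percentage points
above the ~30% figure classically derived on measured maps. Supplying a
measured genetic map moves this quantity accordingly.

Finally, Poisson crossovers without interference slightly overdisperse
segment lengths relative to interference-aware simulators, and the
single-map (sex-averaged) default ignores the large female-male map
difference; both mainly affect variance, not means.
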