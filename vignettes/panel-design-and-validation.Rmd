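---
title: "Methods: amplicon SNP panel design and validation for noninvasive samples"
author: "PanelForge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: amplicon SNP panel design and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(PanelForge)
```

PanelForge reimplements, as tested reusable code, the in-silico
workflow behind a multiplexed amplicon (GT-seq-style) SNP panel for
noninvasive wildlife samples: informativeness-driven marker selection,
amplicon-read genotyping with panel-health diagnostics, genotype QC,
and the downstream forensic applications (individual identification,
kinship, sexing, mark-recapture). This vignette documents the models,
the tunable parameters and their defaults, what the synthetic-data
generator does and does not emulate, and the design choices made where
the problem left the design open.

## Identity power

At a biallelic locus with allele frequencies $p$ and $q = 1-p$ under
Hardy-Weinberg equilibrium (HWE), the probability that two unrelated
individuals share a genotype is
$$P_{ID} = p^4 + q^4 + (2pq)^2,$$
and the full-sibling analogue — the conservative choice when the
sampled population contains close kin — is
$$P_{IDsib} = 0.25 + 0.5\sum_i p_i^2 +
  0.5\left(\sum_i p_i^2\right)^2 - 0.25\sum_i p_i^4.$$
These are the standard closed forms of the individual-identification
literature (Paetkau/Waits conventions). Both are unit tested against
independent brute-force enumerations: all nine ordered genotype pairs
for $P_{ID}$, and the offspring distribution of every ordered parental
mating for $P_{IDsib}$.

Multilocus values are cumulative products, accumulated in log space
(`identityPowerCurve()`); the agreement between log-domain and direct
products is asserted to within $10^{-12}$ relative error. Loci are
sorted most-informative-first (ascending per-locus $P_{ID}$) before
accumulation, matching the presentation convention of
increasing-locus-combination plots; `order = "input"` preserves input
order instead. The identification threshold defaults to the reciprocal
of the census sample size (`nIndividuals`); the bundled examples use
0.007, the conventional value for a census of ~140 animals. At a
uniform minor-allele frequency (MAF) of 0.45, cumulative $P_{ID}$
crosses 0.007 at 6 loci and $P_{IDsib}$ at 10 — the package's analytic
acceptance anchors.

## Dyad simulation and relationship classification

Five relationship categories are simulated through their
identity-by-descent (IBD) sharing distributions — the probabilities a
locus shares 0/1/2 alleles IBD: parent-offspring (0,1,0), full
siblings (0.25,0.5,0.25), half siblings (0.5,0.5,0), first cousins
(0.75,0.25,0), unrelated (1,0,0). Individual 1 is drawn HWE; per locus
a sharing count $k$ is drawn from the category's distribution, $k$
alleles of individual 2 are copied from individual 1 (a random one of
the two when $k=1$) and the rest drawn from the population. The
simulator records the realised IBD states, which the tests check
against the distribution expectations.

Kinship is estimated with the Loiselle allele-frequency-correlation
estimator (below). Classification fits a normal approximation
$(\mu_c, \sigma_c)$ per category on an independent training simulation
of the same size (training seed = seed + 1) and assigns each test dyad
by maximum likelihood; exact ties go to the less-related category. The
underlying distribution-overlap procedure this emulates does not fully
specify assignment, so the normal-ML classifier is this package's own
choice, and its seed policy is explicit.

Parent-offspring and full siblings share an expected kinship of 0.25
and differ only in estimate variance (siblings add pedigree variance
from the IBD process). Because both standard deviations shrink
proportionally to $1/\sqrt{L}$ in the locus count $L$, their mutual
overlap — and hence their five-way confusion — is essentially
scale-invariant: PO/FS confusion dominates the misclassification
matrix at any panel size, and five-way PO/FS accuracy does not improve
with more loci. Accuracy is therefore also reported at the
*relatedness-degree* level (PO and FS pooled as first-degree), the
level at which published assignment-accuracy curves are drawn; degree
accuracies increase monotonically with panel size for every degree in
the packaged sensitivity analysis.

`kinshipSensitivity()` runs the grid — MAF bins low (0.00-0.10),
moderate (0.20-0.30), high (0.40-0.49) and a proportional mixture;
panel sizes 50, 100, 200, 400; `replicates` independent
frequency-panel redraws (default 4) averaged per cell. The packaged
acceptance run uses 10,000 dyads per category with one replicate, a
scale chosen so the full grid completes in minutes while leaving
Monte-Carlo noise an order of magnitude below the effects being
ordered; at that scale the unrelated category's five-way accuracy is
statistically tied between the high- and low-MAF bins (the decision
boundary against first cousins moves with the noisier low-MAF
estimates), so the high-vs-low comparison is asserted on overall
accuracy and on the PO/FS/HS/FC categories.

## Loiselle kinship

For individuals $i, j$, with $x_{il}$ individual $i$'s half-dosage at
locus $l$ and $p_l$ the reference allele frequency, each locus and
allele contributes $(x_{il}-p_l)(x_{jl}-p_l) + p_l(1-p_l)/(n-1)$ to
the numerator ($n$ = gene copies behind the reference frequencies; the
second term is the original small-sample bias correction) and
$p_l(1-p_l)$ to the denominator. Locus contributions are pooled as a
ratio of sums, weighting loci by polymorphism as in the original
estimator; loci missing in either member are skipped pair-wise, and
monomorphic loci are excluded. Reference frequencies default to the
analysed sample set itself (bias term with $n = 2 \times$ samples); an
external table can be supplied, in which case the reference is treated
as exact and the bias term dropped. The diagonal of the kinship matrix
is not reported (`NA`): the estimator is defined for pairs of distinct
individuals, and self-comparisons are not meaningful under its dosage
algebra. Unbiasedness is verified by simulation: category means over
1,000 dyads at 500 loci sit within three standard errors of
0.25/0.25/0.125/0.0625/0.

## Sex markers

Candidate sex markers are screened by the absolute allele-frequency
differential between sexes, cutoff 0.20 by default
(`screenSexMarkers()`). The synthetic generator plants loci whose
per-sex frequencies differ by an exact construction differential
(female frequency uniform on $[0, 1-d]$, male offset by $d$);
$d = 1$ produces fixed differences, the gametolog-like limit, and the
default yield of 8 loci mirrors a typical RADseq screening outcome.

Sex assignment is a *supervised* naive-Bayes two-class model rather
than unsupervised Bayesian clustering: the practical use case is
effectively supervised (validated on known-sex animals), and HWE —
which unsupervised genotype-frequency models lean on — cannot be
assumed at sex-linked loci. Per sex and locus the three genotype-class
frequencies are estimated from training animals with a pseudocount of
0.5 per class; posteriors use equal priors over called loci only. A
call requires the winning posterior to reach `posteriorCutoff`
(default 0.9); samples with no called sex locus are always
`unassigned`.

## Amplicon genotyping

Reads are assigned to loci by exact substring containment of the
forward primer, and to alleles by exact containment of the allele
probe, matching the behaviour of the widely used amplicon genotyper
family; fuzzy matching is deliberately out of scope, which also keeps
the string-matching core checkable against a naive scan-everything
oracle. Probes are matched in read orientation only; panel definitions
must supply probes in read orientation. Calling uses the allele ratio
$r = c_1/\max(c_2, 0.1)$ — the 0.1 floor maps a zero allele-2 count to
$10c_1$ and avoids division by zero; that convention is recorded in
the report metadata. Defaults follow the cited genotyper family:
homozygous when $r \ge 10$ (or $\le 0.1$), heterozygous when
$r \in [0.2, 5]$, otherwise missing; allele depth $c_1 + c_2 < 10$
forces missing. All thresholds are arguments and are logged in the
report.

Panel health: `primerOverrepresentation()` flags primers whose share
of all reads exceeds ten times the uniform share $1/L$;
`primerInteractionScan()` flags read pairs containing two or more
distinct primers (either orientation, reverse complements included)
and no allele probe — the primer-dimer signature. The package emits
flag lists only; dropping loci is a human decision. Technical
sequencing runs of the same samples can be merged count-wise before
calling (`mergeTechnicalRuns()`), rescuing loci that were under the
depth gate in each run alone.

## Quality control

Missingness filters are strict: a sample (or locus) is removed only
when its missing fraction *exceeds* the threshold, so an exactly-50%
sample survives the default 0.5 cutoff — the literal reading of a
">50% missing" rule. The sample filter runs before the locus filter
in the pipeline. Discordance between paired samples counts a cell
comparable only when called in both members, and discordant when the
unordered allele pairs differ (het vs hom is discordant even with a
shared allele). The headline rate pools counts across pairs (total
discordant / total comparable) — the convention behind single
panel-level percentages — while per-pair rates are also returned, so
both pooling conventions are available.

## Forensic matching

Unique individuals are recovered by pairwise matching with a mismatch
tolerance: `same_individual` when the mismatch rate over co-called
loci is at most `matchTolerance` (default 0.02) with at least
`minOverlap` (default 50) co-called loci, then single-linkage
clustering over those decisions so chains of degraded samples still
merge (complete linkage available by flag). The 2% default is a
conservative same-individual bound given that measured replicate
discordance in optimised noninvasive panels sits well below 1%;
published workflows rarely state their matching rule, so the tolerance
is explicit and configurable here. Capture distances use Euclidean
geometry for projected coordinates and great-circle distances for
lon/lat.

## The synthetic-data generator

The generator is the package's study-condition stand-in for real
data. It emulates: MAF spectra drawn uniformly within design bins
(proportional mixing defaults to equal thirds — the empirical RADseq
MAF histogram behind the original proportional category is not
published — and is configurable); HWE genotypes; pedigreed dyads with
category-specific IBD sharing; sex-differentiated loci with exact
construction differentials; and per-sample FASTQ read sets with
negative-binomial depth (dispersion 5, chosen over Poisson to mimic
the overdispersed per-locus depths of real amplicon libraries,
e.g. mean ± SD of 149 ± 63), per-locus dropout, configurable
heterozygote allele bias, per-base substitution errors, and
uniform-random off-target reads of the read length (default 75 bp,
single-end). Four quality-tier presets (tissue, hair, colon feces,
field feces) encode the noninvasive degradation gradient with mean
depths 250/176/119/96 and dropout 0.01/0.04/0.08/0.12, so genotyping
success orders tissue > hair > colon > field.

It does **not** emulate PCR chemistry (primer thermodynamics,
chimeras beyond simple synthetic dimers), paired-end reads,
quality-score distributions, allele-specific amplification bias other
than the single bias knob, contaminant DNA, or linkage between loci.
Passing tests therefore demonstrate the correctness of the statistics
and the pipeline plumbing under idealised read structure — not
robustness to every real-world artifact.

All randomness flows through explicit seed arguments
(`withr::with_seed`, leaving the session RNG untouched), and
`runPipeline()` writes a manifest recording every stage seed, the
configuration, package version and output checksums; identical
configurations reproduce byte-identical deterministic outputs.

## Problem sizes and numerical choices

Test and acceptance scales are chosen to keep the full suite within a
few minutes while holding Monte-Carlo noise far below the asserted
effects: 10,000 dyads per category for the sensitivity grid (the
original design used 1,000,000), 1,000 dyads at 500 loci for kinship
parameter recovery, 20 seeds for the sexing re-enactment, and 244 x 40
cells for planted-error recovery. Cumulative identity products are
log-domain; classifier standard deviations are floored at $10^{-8}$
against degenerate training fits; ratio denominators floor at 0.1;
allele-frequency tables store a single tracked-allele frequency so the
two alleles sum to one by construction.

## Known limitations

* Exact substring matching means sequencing errors inside a primer or
  probe silently drop a read; real pipelines tolerate this the same
  way, but error rates above a few percent per base will bias depth
  downward.
* The relationship classifier is a normal-approximation ML rule; at
  very small locus counts (< ~20) the kinship estimate distributions
  are visibly non-normal and accuracy estimates degrade.
* PO-vs-FS discrimination is intrinsically variance-based and does not
  improve with panel size; report degree-level accuracy for panel
  sizing decisions.
* The sex caller requires known-sex training animals; it does not
  discover sex clusters unsupervised.
* Real-data percentages from any particular field study (genotyping
  success, replicate discordance, unique-genotype counts) depend on
  that study's samples and are not reproduced here; the package
  re-enacts their logic on synthetic constructions instead.
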