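---
title: "Methods: population structure and inversion karyotypes from SNP panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population structure and inversion karyotypes from SNP panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyopop)
```

`karyopop` implements the statistical chain used to describe population
structure in SNP-panel studies of marine fishes where a chromosomal
inversion segregates alongside ordinary habitat differentiation. This
vignette explains the models, the tunable parameters and their defaults,
the numerical decisions, and what the synthetic-data validation does and
does not demonstrate.

## The data model

Genotypes are diploid and biallelic, stored as the dosage of each locus's
B allele (0/1/2, `NA` missing) with per-locus allele codes kept in a
registry. Because calls are unordered pairs over two alleles, dosage is a
lossless encoding; `genotype_calls()` renders allele pairs back for
export. Sample metadata bind each individual to a site and each site to
exactly one habitat group, so the sampling hierarchy
(individuals ⊂ sites ⊂ groups) is well defined everywhere.

Quality control mirrors common panel practice: loci are dropped when
their missing fraction is **at or above** 25% or when their major-allele
frequency reaches 95% in every sample; individuals are dropped when
missing **strictly above** 25%. The asymmetry between the locus rule
(`>=`) and the individual rule (`>`) is deliberate — the two thresholds
are conventionally phrased differently ("dismissed due to ≥ 25%" for
loci, "threshold of acceptance was 25%" for individuals) and both
boundaries are exercised in the tests.

## Diversity and Hardy–Weinberg

Per sample and locus, `Ho` is the heterozygote fraction among typed
individuals, `He = 1 − p² − q²`, `uHe = 2n/(2n−1) · He` (the small-sample
correction), and `FIS = (He − Ho)/He` over loci polymorphic in that
sample. `FIS` uses `He`, not `uHe` (the GenAlEx convention); the choice
matters only in the third decimal at panel sizes but is fixed and
documented here. Sample summaries are means over loci with standard
errors `sd/√L`.

The Hardy–Weinberg test is a full-enumeration exact test: all
heterozygote counts compatible with the observed allele counts are
enumerated with their conditional probabilities
`P(n_AB | n, n_A) ∝ n! / (n_AA! n_AB! n_BB!) · 2^{n_AB}`, and the
two-sided p-value sums configurations no more probable than the observed
one. This targets the same distribution as the familiar Markov-chain
exact tests but is deterministic, which makes panel-scale results exactly
reproducible. Deviation direction is heterozygote deficit when
`Ho < He`, excess otherwise.

## Linkage

Pairwise LD uses Fisher's exact test on the joint genotype table (up to
3×3 over dosages), exact up to a configurable table total and seeded
Monte-Carlo above it. Note the Monte-Carlo p-value floor `1/(B+1)`: when
downstream steps threshold FDR-corrected p-values aggressively (LD
pruning defaults to `q < 1e-4`), use the exact branch
(`exact_max_n` ≥ the sample size) or raise the threshold knowingly.

The index of association treats each locus's pairwise allele-difference
count (0/1/2 between unordered genotype pairs) as a distance;
`IA = V_O/V_E − 1` compares the variance of summed distances with the sum
of per-locus variances, and `r̄_d` standardises by the pairwise
covariance bound `2·Σ√(var_j·var_k)`, so duplicated loci give exactly 1.
Missing dosages are mean-imputed per locus before distances are formed;
significance comes from permuting genotypes independently within loci.
LD pruning builds a graph on FDR-significant pairs and keeps one locus
per connected component — the one with least missing data, ties broken
by higher minor-allele frequency then lexicographic ID, making the
retained set independent of input order.

## Differentiation

Weir–Cockerham variance components a (among samples), b (among
individuals within samples) and c (within individuals) are computed per
locus and combined as the ratio estimator `θ = Σa / Σ(a+b+c)`. Negative
per-locus components are retained in the sums (the standard convention);
they are clamped at zero only when θ matrices feed the UPGMA dendrogram
as distances. Pairwise significance permutes individuals between the two
samples with the `(b+1)/(m+1)` p-value estimator.

AMOVA forms Excoffier-style sums of squares directly from squared
inter-individual distances: per locus the allele-difference count,
summed over loci typed in both individuals and rescaled by
`L_total/L_typed` for missingness. The flat design partitions
among/within samples (its percentage among samples is identically
`100·FST`, asserted in the tests); the hierarchical design adds groups
and yields F<sub>CT</sub>, F<sub>SC</sub>, F<sub>ST</sub> with the usual
method-of-moments n-coefficients. Permutation schemes: individuals among
samples (flat FST, FSC) and whole samples among groups (FCT). With few
samples per group the FCT permutation space is tiny; the result is
reported with a warning rather than suppressed.

## Ordination and driver loci

PCA operates on dosages with missing entries replaced by the locus mean
(which leaves column means unchanged), centred, unscaled. Axes are
oriented so the largest-magnitude loading is positive — PCA sign is
otherwise arbitrary and tests and reruns need stability. DAPC reduces to
`n` PCs then fits linear discriminants on group labels; `n_pcs = "auto"`
runs stratified 90/10 cross-validation over a small grid and takes the
best mean assignment success, ties toward fewer PCs.

Driver-locus discovery ranks loci by squared PC-loading. The default cut
is a changepoint: the largest ratio between consecutive sorted squared
loadings within the top quarter, accepted only when it reaches 1.5. A
tightly linked block dominating an axis produces a sharp break between
the block and the smoothly decaying background, whereas a
`mean + 3·SD` threshold — also available as `method = "sd"` — lets the
block inflate the SD and systematically truncates it (on the bundled
preset it recovers only the strongest ~6 of 12 block loci). On
structureless panels no ratio reaches 1.5 and the empty set is returned
with a warning.

## Karyotype classification

Individuals are clustered along one PCA axis (PC1 of the full panel by
default) by 1-D k-means with k = 3, initialised at the score minimum,
median and maximum plus 50 random restarts. The middle cluster must be
distinctly the most heterozygous at the driver loci (mean driver
heterozygosity highest *and* above 0.5) — heterokaryotypes are
heterozygous at essentially every diagnostic locus — otherwise
classification is rejected with diagnostics rather than silently
mislabelled; this also rejects structureless data. Individuals within
5% of the local inter-centre spacing of a k-means boundary are reported
as `unassigned` rather than forced. The "A" arrangement is anchored to
the flank cluster most frequent among open-water (Ocean) individuals
when habitat labels exist, else to the flank with the higher first-allele
frequency, so labels are invariant to PC sign flips. A fallback
`mode = "driver"` classifies on PC1 of the driver-locus submatrix for
datasets where background structure dominates the full-panel PC1.

The per-karyotype A-allele frequency table flags loci matching the
(1, 0.5, 0) diagnostic signature within a tolerance of 0.02 — loose
enough to tolerate roughly one miscall in fifty, tight enough to exclude
partially diagnostic loci.

The stripe count used to summarise PC1 multimodality is a 1-D gap
statistic (uniform reference on the score range). The decision rule is
the *global* gap maximum, accepted only when it beats the k = 1 gap by
two standard errors. The textbook first-SE-max rule was rejected after
it returned k = 1 even for cleanly separated three-cluster data in one
dimension; the global rule separates striated panels (distinct karyotype
clusters) from pruned panels (diffuse habitat clouds) reliably.

## Migrant screening

`habitat_memberships()` defaults to the classical leave-one-out
multilocus genotype-likelihood assignment test: group allele frequencies
are estimated with the focal individual excluded from its home group
(Jeffreys 0.5 smoothing), and memberships are normalised likelihoods.
DAPC posteriors are also available but are systematically overconfident
near group boundaries. `detect_migrants()` flags individuals whose
membership in a non-home cluster exceeds 0.7.

A calibration fact worth knowing: at a realistic background separation
(Ocean–Fjords multilocus θ ≈ 0.10 over ~109 loci) the probability that a
resident's genotype genuinely favours the other group — computed with the
*true* simulation frequencies, so irreducible — is on the order of 10⁻³
per individual. Screening a whole 1000+-individual panel at q = 0.7
therefore yields a handful of cross-group flags beyond any planted
migrants; the screening question should be posed per habitat (e.g.
"Ocean-assigned individuals within the fjord samples"), and even then a
small false-flag rate remains. The acceptance suite measures this
honestly rather than hiding it.

## Haplotype reconstruction

For ≤ ~12 loci the haplotype space (2^L) is enumerated and haplotype
frequencies are estimated by multinomial EM under random pairing:
genotypes are observed unordered pairs summed over compatible phases,
with missing calls summed over both alleles. The log-likelihood is
checked to be non-decreasing at every iteration; ten random restarts
guard against local optima (with near-diagnostic loci the likelihood is
essentially unimodal and restarts agree). Haplotypes estimated below
`1/(4n)` are pruned and the EM re-run once, stabilising the count of
"observed" haplotypes. A Bayesian coalescent-informed phasing model
would add nothing here: with a handful of near-perfectly diagnostic loci
the phase is almost fully determined by the data, so the simpler
estimator is used deliberately. Haplotype-level differentiation treats
each individual's best phase pair as a genotype at one multi-allelic
super-locus (allele-identity distance, Weir–Cockerham sums over
haplotype alleles).

## Admixture model and K selection

The Gibbs sampler implements the admixture model with independent
Beta(1,1) priors on cluster-locus allele frequencies — not the
correlated-frequencies prior of the reference implementation. The
correlated prior mainly improves sensitivity to *subtle* structure; the
structure this package targets is strong, and the independent prior is
simpler and mixes well. The sampler updates P (Beta), Q (Dirichlet), the
per-allele-copy origins Z (categorical), and the symmetric Dirichlet
concentration α by a Metropolis step (normal proposal, sd 0.05, uniform
prior on (0, 10)). The model likelihood `L(K)` is the mean of the
post-burn-in log-likelihood trace minus half its variance (the usual
"estimated ln probability of data"; the plain mean is also returned).
Desk-scale defaults (burn-in 1000, 3000 sweeps) are intentionally far
below the reference tool's 100k/1M settings; the K-selection statistics
stabilise long before then at these data sizes.

Evanno's ΔK is the absolute second difference of mean `L(K)` over the
run-to-run SD; Puechmaille's four statistics count clusters to which at
least one predefined sample assigns mean (or median) membership ≥ 0.5,
taking the max and median over replicate runs. Replicate runs are
aligned by exhaustive permutation search (K ≤ 8; greedy column matching
above) maximising `G' = 1 − ‖Q₁ − Q₂‖_F / √(2N)` against the highest-L
run before averaging.

## The synthetic generator

`simulate_dataset()` draws background loci from a hierarchical
Balding–Nichols model: ancestral B-allele frequencies uniform on a MAF
window (side randomised), group frequencies Beta-distributed around the
ancestral value with per-group drift, site frequencies likewise around
group values, genotypes in Hardy–Weinberg proportions within sites. A
named `fst_between` gives each group its own drift from the shared
ancestor; the expected among-group θ for two groups drifted
symmetrically at F is F itself (verified by estimator-consistency
tests). An optional Gamma multiplier (`drift_shape`) makes drift
heterogeneous across loci, emulating the right-skewed per-locus
differentiation of real panels; the preset keeps homogeneous drift
because heavy heterogeneity occasionally promotes a single high-drift
background locus into the PC1 block.

Inversion loci are generated by drawing each individual's karyotype from
its group's (f_AA, f_AB, f_BB) and then each allele copy from its
arrangement's allele-frequency profile — complete recombination
suppression, so the block behaves as one locus. Perfectly diagnostic
loci are fixed for opposite alleles on the two arrangements; partial
loci use configurable per-arrangement frequencies.

`preset_three_habitats()` encodes the emulated study design: 16 sites in
three habitats with realistic per-site sample sizes (~1290 individuals at
full scale), 109 background + 12 inversion loci (5 perfectly
diagnostic), Mediterranean karyotypes fixed BB, Ocean AA-rich (56.7%,
remainder in Hardy–Weinberg ratio — the source design reports only the
AA fraction), Fjords at 18.5/53.7/27.9%. Background calibration was
chosen once, by design, to reproduce the emulated study's stated
observables: uH<sub>e</sub> ≈ 0.29–0.33 in Ocean/Fjord samples versus
≈ 0.11–0.13 in the Mediterranean (MAF ~ U(0.05, 0.35), Mediterranean
minor-allele shrink ×0.35), PC1 carrying the inversion striation with
PC2 carrying geography, and Ocean–Fjords multilocus θ ≈ 0.10 (Ocean and
Mediterranean drift 0.02, Fjords 0.12). Fjord drift cannot be pushed to
the upper end of the reported pairwise range without depressing fjord
diversity below its reported rank (drift multiplies expected
heterozygosity by 1 − F); real fjord populations plausibly combine high
diversity with high divergence through admixture of lineages, a process
outside this generator's scope and noted as a limitation.

What passing tests on this generator demonstrate: the estimators are
correct (brute-force oracle equivalence), the classification and
selection machinery recovers planted truth under the stated conditions,
and the pipeline's qualitative conclusions (striation, its disappearance
after pruning, K = 2 under Evanno, three habitat clusters under
Puechmaille) are reproducible. What they do not demonstrate: behaviour
under genotyping artefacts (allele dropout, null alleles, batch
effects), linkage outside the inversion, isolation by distance, or
admixed/hybrid individuals — none of which the generator emulates.

## Numerical choices and problem sizes

Permutation p-values always use `(b+1)/(m+1)`. All stochastic routines
take explicit seeds; a global seed is expanded into independent
per-stage streams so adding draws in one stage never perturbs another.
The EM converges on a max-frequency change below 1e-8; k-means uses 50
restarts; cross-validation uses 30 replicates by default. The validation
suite runs the generator at fractions of the full design chosen for
desk-scale runtimes (full scale for driver-locus discovery and karyotype
recovery, quarter scale for the admixture K-scan and migrant screen,
fifth scale for the exact-LD pruning comparison); these fractions are
stated in the tests and keep every statistical property at comfortable
power.

## Known limitations

* The admixture sampler uses the independent-frequencies prior; very
  weak structure (θ ≪ 0.01) may need the correlated prior it does not
  implement.
* Haplotype phasing is enumeration-based and capped at 14 loci.
* AMOVA missing-data rescaling assumes calls are missing at random.
* Migrant screening inherits the irreducible assignment error discussed
  above; flags are candidates for inspection, not verdicts.
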