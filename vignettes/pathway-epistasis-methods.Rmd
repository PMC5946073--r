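---
title: "Methods: information-theoretic synergy, MDR, and survival follow-up for SNP panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: information-theoretic synergy, MDR, and survival follow-up for SNP panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(episyn)
```

This vignette is the package's account of the statistical methods it
implements, the modelling choices that were genuinely open, and what the
synthetic-data tests do and do not establish about real cohort data.

## Study design and data model

The target design compares long-lived cases (a nonagenarian birth
cohort) with middle-aged population controls on a candidate-gene panel:
biallelic SNPs coded as minor-allele counts 0/1/2, each SNP annotated to
a gene and one of three candidate pathways (insulin/IGF-1 signalling,
DNA damage signalling and repair, pro/antioxidant response). Cases
additionally carry months of follow-up from recruitment and a death
indicator. A `genotype_study` holds the subjects-by-SNPs matrix plus the
phenotype, sex and survival columns; missing genotypes are an explicit
sentinel (`NA`), never a zero, because conflating missingness with the
reference homozygote silently biases every downstream count.

The minor allele is defined within the full sample at load time, ties at
frequency 0.5 broken by allele name order. All SNPs are treated as
autosomal-diploid: how hemizygous X genotypes in males should be coded
is not derivable from the design, so the package documents the
assumption instead of guessing.

## Marker quality control

Four filters run in a fixed order, each recorded per SNP in the QC
report:

* **call rate** — SNPs missing in more than 10% of subjects are dropped
  (a guard the downstream modal imputation needs; configurable);
* **MAF** — whole-sample minor allele frequency below 0.05. Whether the
  original design filtered on the whole sample or controls only is not
  stated anywhere authoritative; the whole sample is the default and the
  choice is exposed;
* **Hardy–Weinberg** — exact test in *controls only*, cutoff 0.001.
  Testing in cases would discard true association signal. The exact
  test conditions on the observed allele counts and sums the
  probabilities of all heterozygote counts no more probable than the
  observed one (two-sided, probability ordering);
* **tag pruning** — within each chromosome, pairs with genotypic
  r² ≥ 0.8 (squared Pearson correlation of allele counts over
  pairwise-complete subjects — the standard composite surrogate for
  unphased data) or separated by fewer than 60 bp lose the lower-MAF
  member. Candidates are visited in (MAF, identifier) priority order,
  so the retained *set* is invariant to input column order. The
  LOD-score criterion of classical Haploview-style tagging is not
  re-implemented; only r² and distance are enforced.

One interaction worth knowing about: when cases are heavily oversampled
relative to the population (as in a longevity design) a *strongly
epistatic* SNP can distort genotype proportions in the control group
enough to fail the HWE filter. This is visible in simulations with
extreme planted penetrance contrasts and is a property of the design,
not a bug in the filter — but it argues for inspecting the QC report's
HWE column before interpreting a null screen result.

## The synergy screen

For SNPs $G_1, G_2$ and phenotype $Y$, the screen computes plug-in
mutual informations in bits over the pair's complete cases and the
interaction information

$$\mathrm{Syn} = I(G_1, G_2; Y) - I(G_1; Y) - I(G_2; Y),$$

where the joint term treats the 9-level joint genotype as one feature.
Positive synergy means the pair is super-additive on the phenotype;
negative synergy means redundancy, the signature of residual LD.
Choices made here:

* **Base 2 throughout.** The additive identity is base-invariant and
  published tables cannot settle the base without raw data; bits are the
  information-theoretic default and the base is an argument.
* **No small-sample bias correction.** Plug-in estimates are what the
  reference methodology reports; all three terms share one
  complete-case subject set per pair, so the identity
  $\mathrm{Syn} \equiv I - I_1 - I_2$ holds to machine precision and is
  asserted in tests.
* **Permutation statistic is Syn, one-sided.** Selection targets
  synergy, not joint association; redundancy discovery is a flagged
  option. Each permutation replicate shuffles the phenotype once and
  applies the same labels to *every* pair, preserving the inter-pair
  dependence that the Benjamini–Yekutieli FDR (harmonic-factor step-up,
  valid under arbitrary dependence) must survive. p-values use the
  add-one estimator $(b+1)/(B+1)$.
* **Adaptive early release.** A pair whose running p-value exceeds 0.2
  after 200 replicates is released from the loop with its p at that
  point; any pair still in contention receives the full replicate
  budget. Ranking above any synergy cutoff depends only on Syn, so the
  early release cannot change which pairs lead the table.

Significant pairs (defaults FDR < 0.005 and p < 1e-4, the conventions of
the target design) form a network whose edges are classified intra-gene,
intra-pathway, or inter-pathway; intra-gene edges are flagged for
residual-LD review, since sub-threshold correlation can masquerade as
synergy between markers of one gene.

The plug-in estimator of Syn is positively biased at finite $n$ (the
9-cell joint term accumulates more bias than the two marginal terms), so
under the null most pairs show small positive Syn. The permutation test
is what calibrates significance; raw Syn values should be compared only
between pairs within one dataset.

## Multifactor dimensionality reduction

For a locus set of size $k \in \{2, 3\}$, the 3^k genotype cells are
labelled high-risk when their case:control ratio reaches the overall
ratio $T$ (cells with cases but no controls are high-risk; ratio exactly
$T$ is high-risk, the reference convention), low-risk otherwise, and
empty when unpopulated. The labelling is the training-balanced-accuracy
optimum among all 2^9 labelings — a property the test suite brute-forces
on toy tables.

The search is exhaustive over k-subsets inside a stratified seeded
10-fold cross-validation: fold winners are chosen by *training* balanced
accuracy, the final ranking is CV consistency with mean *testing*
balanced accuracy as tie-breaker, and the permutation test reruns the
entire search on shuffled phenotypes, comparing the best model's mean
testing balanced accuracy against its null distribution. The
selection metric and the permutation statistic are not fully pinned down
by the classical software descriptions; training-BA selection with a
testing-BA statistic is the conventional reading and both are stated
here as the package's choice. Cells empty in training are excluded from
testing evaluation (an "assign low-risk" policy is available). Missing
genotypes are imputed once, globally, by the per-SNP mode (ties to the
lower code) before any split — matching the global-replacement behaviour
of the classical MDR data tool.

Models are reported when CVC ≥ 2 and training balanced accuracy exceeds
0.5. The best model's high-risk cells are distilled into a compact
carrier-style combination when they form a per-locus Cartesian product
(e.g. "hom-minor at SNP1 and minor-carrier at SNP2"); otherwise the
explicit cell list is kept. The carrier odds ratio is the 2×2
cross-product with a Woolf log-scale interval (identical to the
univariate logistic estimate), Haldane-corrected on zero cells.

Exhaustive 3-locus search is refused above 150 SNPs: at that size the
cell-index precomputation alone is no longer desk-tractable, and
candidate lists (e.g. from the synergy screen) are the intended route.

Interaction graphs express each SNP's main effect
$100 \cdot I(G;Y)/H(Y)$ and each pair's synergy
$100 \cdot \mathrm{Syn}/H(Y)$ as percentages of the phenotype entropy;
the dendrogram clusters loci by average linkage on the distance
$\max_{\text{pairs}}(\mathrm{Syn}) - \mathrm{Syn}$, so the most
synergistic pair joins at height zero and redundant pairs join last.

## Survival follow-up

Candidate combinations from MDR are evaluated in the case cohort only:
subjects are carriers or noncarriers (missing genotypes at combination
loci exclude the subject, with the count logged), separately by sex.
The comparison uses the Kaplan–Meier product-limit estimator, the
Mantel–Cox log-rank test, and a Cox proportional-hazards model with a
single binary covariate. Implementation rides on the `survival`
package; the test suite checks it against hand-computed product-limit
tables, the observed-minus-expected log-rank form, a permutation
log-rank, and a brute-force partial-likelihood grid search.

Choices: time origin is recruitment in months; zero follow-up times get
a half-month offset (the product limit is undefined for an event at
$t = 0$); ties are handled by Breslow (months-resolution follow-up makes
ties frequent; Efron is a flag); p-values across combinations are
reported unadjusted — matching the candidate-follow-up convention of the
target design — with an optional BY column and an explicit multiplicity
caveat in the documentation.

## The synthetic-data generator

`simulate_study()` exists so every stage is testable without any
download. It emulates the target design's structure: two phenotype
groups filled to quota by rejection sampling from a superpopulation
(draw HWE genotypes, assign case probability from the planted model,
keep until quotas fill — mirroring case-control ascertainment), a
pathway-structured panel (defaults scaled to 20 SNPs per pathway, 400
cases / 300 controls so the full pipeline runs in a test suite), MAFs
uniform on [0.10, 0.45] (common variants comfortably above the QC
threshold), sex ratios of 71% female in cases and 50% in controls
(the demographic signature of a nonagenarian cohort vs population
controls), optional LD blocks by conditional copying (member equals
block head with probability $r$, else an independent draw, giving
genotypic correlation $\approx r$), and exponential or Weibull survival
with a planted carrier hazard ratio under uniform administrative
censoring (defaults: median 40 months, censoring window 60–144 months —
plausible for nonagenarians followed to a register cutoff). Effects are
either explicit penetrance tables over genotype cells or additive
logistic models with an optional product-interaction term; multiple
effects combine on the log-odds scale.

`analytic_decomposition()` returns the exact population information
decomposition implied by HWE frequencies and a penetrance table, with an
optional re-weighting to case-control sampling at a given case share —
the form against which empirical plug-in estimates are shown to converge
(the suite checks monotone error decrease over $n \in \{500, 4000,
32000\}$ and agreement within 0.005 bits at $n = 50{,}000$).

What the generator does *not* emulate: haplotype-level ancestry
(coalescent realism), genotyping batch effects, population
stratification, relatedness, or age structure within groups. Passing
tests therefore demonstrate correctness of the estimators and
calibration of the permutation machinery under the stated model — not
robustness to confounding that real cohort data may carry.

## Numerical and degenerate-input conventions

* Entropy uses $0 \log 0 = 0$; information estimates are clipped at 0
  against floating-point undershoot.
* The HWE exact test works on log-probabilities (stable to $n \sim 10^4$)
  with a $10^{-10}$ slack when comparing table probabilities, and is
  verified against an independent recurrence oracle to $10^{-12}$.
* Pairs with fewer than 30 complete cases (configurable) are excluded
  from the screen with a warning; a direct `synergy()` call on such a
  pair is an error naming the pair.
* Permutation p-values use add-one counts and can never be zero;
  one-sided comparisons use a $10^{-12}$ tolerance so ties count as
  exceedances.
* MDR fold assignment is stratified by phenotype and fully determined by
  the seed; rerunning with the same seed is bit-reproducible.
* QC tie-breaks (equal MAF in pruning, modal-genotype ties in
  imputation) resolve by identifier order and lower code respectively,
  and are documented rather than incidental.

## Problem sizes used in the checks

The acceptance-style checks run at sizes chosen to make their targets
statistically meaningful on one CPU: null calibration uses 40 seeded
runs of 200 permutations each (synergy on 6-SNP panels at $n = 300$;
MDR on 20-SNP panels at $n = 600$); planted-pair recovery uses 25
replicates of a 30-SNP panel at $n = 2000$ with a pure-parity penetrance
(0.35/0.65); survival recovery uses 100 replicates of a 700-case cohort
with carrier hazard ratio 0.7. These sizes are the package's definition
of "desk scale" for a candidate-panel method.

## Known limitations

* The synergy screen's exhaustive engine targets candidate panels
  (≤ ~10⁴–10⁵ pairs); it is not a genome-wide scan and has no
  SIMD/GPU path.
* No covariate adjustment anywhere: SNPsyn-style screening and classical
  MDR are covariate-free by construction, and the Cox follow-up fits a
  single binary covariate. Age and cohort effects within groups are
  assumed handled by the design.
* Plug-in information estimates are biased upward at small $n$; only
  permutation p-values, not raw Syn magnitudes, are comparable across
  datasets.
* X-chromosome coding, genotype calling, and VCF ingestion are out of
  scope (panel data of this design predates VCF); readers exist for a
  genotype TSV and the PLINK `.raw` additive dialect.
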