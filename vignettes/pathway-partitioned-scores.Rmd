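---
title: "Pathway-partitioned polygenic risk scores: models and design choices"
author: "pathpgs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-partitioned polygenic risk scores: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Genetic overlap between two traits is usually sought either one variant at
a time (pleiotropy) or genome-wide (genetic correlation). Both extremes can
miss real structure: when one biological pathway pushes a secondary trait
up and another pushes it down, the contributions cancel in a genome-wide
polygenic score and the overall genetic correlation is null, even though
each pathway's contribution is individually strong. `pathpgs` implements
the middle ground for a case-control GWAS of a common binary trait
(male-pattern baldness is the motivating application, with its ~59% case
fraction among middle-aged men and very high heritability): polygenic risk
scores are built per locus, summed into pathway scores according to which
loci carry each pathway's genes, and each pathway score is tested against
secondary traits. The package covers the whole chain needed to do this
reproducibly — association scan, locus definition, conditionally distinct
SNP selection, GREML heritability, score construction, trait scans with
q-value control, regional pleiotropy scores, and community detection on
pathway co-membership — plus a synthetic-data generator so that every
stage is testable without any private biobank data.

# Models and procedures

## Two-step association scan

The discovery scan is least squares of the 0/1 phenotype on dosage plus
covariates (equivalent to the Armitage trend test), computed for all SNPs
at once by residualising phenotype and dosages on the covariates
(Frisch–Waugh). SNPs passing a suggestive threshold (default p < 1e-5)
are refitted by logistic regression (IRLS, tolerance 1e-8, 25-iteration
cap) with the same covariates; this mirrors the standard trick of making a
biobank-scale logistic scan tractable, and the suite checks that the two
steps rank strong signals identically (Spearman > 0.99). Separation and
non-convergence are flagged on the affected records, never silently
dropped. P-values are carried alongside -log10(p) so that associations
stronger than the smallest representable double survive.

Replication cohorts are combined by fixed-effect inverse-variance
meta-analysis after allele harmonisation (sign flip for swapped alleles,
strand complements resolved, strand-ambiguous A/T and C/G SNPs passed
through with a warning since no frequency information is assumed).
Genomic control lambda is the median association chi-square over 0.4549.

## Loci and distinct SNPs

Selected SNPs are single-linkage clustered per chromosome: consecutive
SNPs stay in one locus unless strictly more than 500 kb apart (a gap of
exactly 500 kb does not split). Within each locus, conditionally distinct
SNPs are chosen by stepwise conditional regression on individual-level
genotypes: the top SNP enters as a covariate, all remaining members are
refitted, and the loop continues while any conditional p-value stays below
5e-8. Ties break by smallest p, then position, then id; candidates whose
dosage is predicted from the already-selected set with r-squared above 0.9
are skipped as collinear (the conventional guard; the source analysis does
not state one). Loci that keep no distinct SNP are discarded. Same-
chromosome loci linked by conditional analysis can be merged through an
explicit merge list only — merging is deliberately never inferred.
Replication keeps SNPs below p = 0.05 (strict) in the replication
meta-analysis; sign concordance with discovery is additionally required by
default because a sign-discordant "replication" is spurious, with a flag
to reproduce the literal p-only rule.

## Heritability

The GRM is the standard allele-frequency-standardised cross-product,
`A_jk = mean_i (x_ij - 2p_i)(x_ik - 2p_i) / (2 p_i (1 - p_i))`. The X
chromosome in an all-male cohort uses 0/2 dosages (full dosage
compensation) with the same standardisation — which makes the X GRM's mean
diagonal about 2 rather than 1. Heritability fractions are therefore
reported as `sigma2_k * mean(diag A_k)` over their sum, which is invariant
to any rescaling of a GRM and reduces to the usual ratio for a standard
autosomal GRM.

Variance components are estimated by average-information REML: AI updates
with an EM fallback step whenever an AI step would leave the feasible
region, step halving if a step would decrease the restricted likelihood,
convergence when the likelihood improves by less than 1e-6, components
floored at 1e-6 times the phenotypic variance (floor hits are reported as
boundary components, e.g. for the unidentifiable identity-GRM case).
With a single GRM the model is rotated to the GRM eigenbasis once, making
each iteration linear in n. Binary phenotypes are analysed on the observed
0/1 scale and converted with the population-sample liability
transformation `h2_liab = h2_obs * K(1-K)/z^2` at the cohort's own
prevalence (no ascertainment correction — appropriate when the cohort
prevalence is the population prevalence, as for a self-reported common
condition). The variance explained by a polygenic score is the decrease in
the GRM-attributed fraction when the score is added as a fixed effect.

## Scores

Weights are the coefficients of one multivariable logistic regression of
the phenotype on all distinct SNPs simultaneously plus covariates, so LD
between selected SNPs is not double-counted. A locus score is the sum of
dosage times joint beta over the locus's distinct SNPs; the overall score
is the sum of all locus scores; a pathway score is the sum of the locus
scores of the loci containing that pathway's genes. Pathways with
identical locus sets give identical scores; both the curated "explicit"
merge behaviour (only named groups merge — the packaged table merges three
pairs, yielding 25 scores from 28 pathways) and an "all-identical" rule
(which also merges the remaining identical pair, yielding 24) are
provided, because the two disagree on exactly one pair in the packaged
table and neither can be called wrong.

Scores are tested against traits with the family-appropriate model —
logistic for binary, least squares for quantitative, Cox proportional
hazards on (age, status) for parental survival, mother and father as
separate traits — and a scan is corrected by Storey q-values: pi0 from the
smoother over lambda = 0.05...0.95 (fallback to the single point
lambda = 0.5 below 100 tests, where the spline is not trustworthy), then
the step-down minimum of `pi0 * m * p_(j) / j`.

## Regional scores and communities

Trait-associated regions are seeded by SNPs with p < 1e-7 and grown over
SNPs with p < 1e-6, splitting where consecutive such SNPs are 1 Mb or more
apart; where two seeds share extension SNPs without such a gap they merge
into one region (one consistent reading of the seed/extension interplay;
recorded as a choice). Region boundaries are the min/max member positions,
without padding. Regional genotypic scores are dosage-times-effect sums
over the region's SNPs filtered at p < 1e-6, and cross-trait pairs with
squared correlation at least 0.5 are flagged.

Gene co-membership graphs count shared annotation sets as edge weights
(counts rather than a 0/1 indicator preserve structure and reduce ties;
a binarised mode is provided since the source description is ambiguous).
Communities come from the Louvain multilevel heuristic with a seeded sweep
order, so partitions are reproducible; the reported modularity Q is
recomputed directly from the weight matrix rather than taken from the
optimiser, and the suite cross-checks it against an independent
implementation.

# The synthetic world

The generator states the world the tests live in:

* **Genotypes.** Haplotypes from a Gaussian copula: AR(1) latent process
  with parameter `ld_decay` within blocks of `ld_block_size` SNPs
  (independent across blocks), thresholded at Hardy–Weinberg frequencies
  drawn from `maf_range`. The implied adjacent-SNP genotype correlation
  has a closed form (an orthant probability evaluated by quadrature,
  `ld_target_r()`), which the generator is tested against. Male X
  chromosomes are single haplotypes at dosage 0/2.
* **Primary trait.** Liability = autosomal genetic value + X genetic value
  + normal noise; each genetic component is centred and scaled to its
  configured heritability exactly in sample, noise variance is `1 - h2`,
  and cases are liabilities above `qnorm(1 - prevalence)`. Defaults state
  the motivating condition: prevalence 0.59, heritability 0.82 autosomal
  plus 0.12 X-linked at full scale (scaled-down worlds in the tests use
  smaller h2 so that the REML problems stay well-conditioned at small n).
* **Effect sizes.** Default Gaussian per-SNP effects give chi-square
  heavy-tailed locus contributions, as in real architectures — which also
  means some loci are undetectably weak at desk-scale n. The
  `beta_dist = "equal"` option assigns each causal SNP the same variance
  explained (effects proportional to 1 / sd(dosage), random sign); the
  demonstration scenarios use it so that every locus has uniform, high
  detection power and pathway weights are balanced by construction.
* **Secondary traits.** Each configured pathway's genetic value (the
  causal-SNP weighted sum over its loci, standardised) enters each
  secondary trait with a stated per-SD slope, plus unit normal noise.
  Opposite slopes of equal size on two pathways of equal weight cancel in
  the genome-wide genetic value while remaining fully visible within each
  pathway — the package's headline phenomenon, exercised end-to-end in the
  acceptance suite (overall score null in >= 90% of replicates while both
  pathway scores exceed |z| = 3 in opposite directions).

What the generator does **not** emulate: genotype imputation uncertainty,
recombination-map realistic LD, population structure (principal components
are consumed as covariates, not generated as confounders), ascertained
case-control sampling, and missing genotypes. A green test therefore
establishes the statistical machinery, not robustness to those
real-data complications.

# Numerical choices and scaled-down tests

* Logistic IRLS: tolerance 1e-8, 25 iterations for per-SNP refits, 50 for
  the joint model; separation detected via fitted probabilities at the
  0/1 boundary.
* REML: equal-split start values, likelihood-change tolerance 1e-6,
  AI-matrix standard errors, delta-method standard errors for ratios.
* The parameter-recovery suites are scaled down in *replicate count*
  (and, for the two-component problem, in n) from the 100-replicate
  n = 2000 design so the whole suite runs in minutes on one CPU; coverage
  of a 2-SE interval is scale-free, so the check is unchanged in meaning.
* Recovery is judged against the *realised* planted heritability
  (variance of the simulated genetic values in the sample), not the
  nominal target, since the two differ by sampling noise at finite n.
* The demonstration scenarios are powered by design: cancellation uses
  six equal-power loci (per-locus association z well above the
  genome-wide threshold at n = 2500) so pathway composition is recovered
  in essentially every replicate; the diffuse ("pathway-wide") scenario
  sets the pathway slope so each of eight member loci sits near z = 1.4
  (individually sub-threshold) while the pathway score sits near z = 3.9.

# Known limitations

* Conditional SNP selection uses individual-level genotypes; a
  summary-statistic approximation with an external LD reference is out of
  scope.
* REML for several GRMs is dense (O(n^3) per iteration); it is meant for
  the tens-of-thousands scale at most, and the test worlds use n in the
  hundreds to low thousands.
* The liability transformation assumes the analysed cohort's prevalence is
  the population prevalence; ascertained designs need a correction this
  package deliberately does not implement.
* Louvain is a heuristic: partitions are deterministic given the seed but
  not guaranteed optimal; only on well-separated graphs is the partition
  invariant to relabelling.
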