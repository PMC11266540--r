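---
title: "Models and methods in popenrich"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in popenrich}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(popenrich)
```

`popenrich` implements the bespoke computations needed to characterise an
admixed cohort genetically — population-specific allele-frequency
enrichment, IBD-sharing summaries, structure and QC, covariate-adjusted
association scans, and a replication procedure against external biobank
catalogues — together with a simulator that generates cohorts with full
ground truth. This vignette explains each model, its assumptions, the
parameters that matter, and the design choices that were genuinely open.

## The synthetic cohort model

Individual-level genotype data from restricted cohorts cannot be
redistributed, so everything in this package is validated against simulated
cohorts whose generative truth is known exactly.

**Allele frequencies.** Each of `n_sources` ancestral populations drifts
from a shared ancestral frequency `p` under the Balding–Nichols model:

$$p_k \sim \mathrm{Beta}\left(p\frac{1-F_k}{F_k},\ (1-p)\frac{1-F_k}{F_k}\right),$$

so that `E[p_k] = p` and `Var[p_k] = F_k p(1-p)`. This is the standard
drift model in the field precisely because its closed-form moments make
recovery tests exact: two sources drifted at `F` give an expected Hudson
numerator of `2Fp(1-p)` over a denominator of `2p(1-p)`, so the global
ratio-of-averages estimate recovers `F` itself.

**Admixture and genotypes.** Each sample's ancestry vector is Dirichlet
within its cluster (`q_i ~ Dir(alpha)`), and its genotype at variant `j` is
`Binomial(2, q_i' p_j)`. Defaults describe a three-cluster cohort
interpolating between a European-like source (`F = 0.05`) and an
Asian-like source (`F = 0.15`), 120 samples per cluster with concentration
vectors (20,1), (10,4) and (4,10) — a gradient of admixture rather than
discrete islands, which is what biobank PCA plots of admixed cohorts
actually look like. There is deliberately no recombination, phasing or
read-level realism (see Limitations).

**Enriched variants.** A configured fraction of variants (default 5%) is
planted as "bottleneck-enriched": the designated source's frequency is
rejection-sampled into [0.01, 0.1] (capped at 1000 attempts, then an
error), and the reference source's frequency is rejection-sampled below a
quarter of it, so every planted variant strictly satisfies the log2-ratio
> 2 rule. Tests can therefore demand exact recovery of the planted set.

**IBD segments.** Per pair, segment counts are Poisson with rate 2
(same-population pairs) or 0.2 (cross-population), lengths exponential
with mean 3 cM, positions uniform on a single chromosome under a uniform
1 cM/Mb map (a genetic map must be assumed because detector output is
reported in cM; the uniform map is overridable in the segment tables
themselves since all merge logic reads coordinates, not the map). LOD
scores are exponential with mean 4, so a known closed-form fraction
`1 - exp(-3/4) ≈ 0.53` fails the LOD > 3 filter — the truth object records
post-filter totals.

**Phenotypes.** Quantitative traits are linear in the planted causal
dosages plus small sex/age effects, with Gaussian noise scaled so the
genetic variance fraction hits the target heritability. Binary traits use
a logistic liability whose intercept is solved numerically for the target
prevalence. Effect sizes and prevalences have no canonical values for this
kind of cohort; the pipeline defaults (one quantitative trait, beta 0.5,
h² 0.3; one binary trait, log-OR 0.4, prevalence 0.2) are ordinary
single-locus GWAS magnitudes and are fully configurable.

**Seeding.** One global seed fans out to per-component child seeds through
fixed offsets (`derive_seed`), so adding a component to a simulation never
perturbs the draws of existing components, and the whole pipeline is
byte-reproducible under a fixed seed.

## Enrichment scoring

The statistic is `log2(AF_num / AF_den)`. Three conventions matter:

- **Sentinel.** A variant unobserved in the numerator population gets the
  sentinel −5 rather than −Inf; it marks "absent" while keeping the value
  finite and at the bottom of the distribution. The sentinel is
  configurable; −5 is the field's convention.
- **Denominator zeros.** The sentinel is defined only for the numerator
  side; variants with denominator frequency 0 are excluded before scoring,
  with a diagnostic count. This is a genuine asymmetry of the statistic,
  not an implementation shortcut.
- **Strictness.** "Ratio greater than 2" is strict (a ratio of exactly 2.0
  is not enriched) and the Finnish-style frequency band [0.01, 0.1] is
  closed (both endpoints enriched). The plain-language reading was adopted
  and both rules are configurable, since ties at the boundary are
  vanishingly rare in real AF data but matter for tests.

Distribution summaries report the median over *observed* records only
(sentinels would otherwise drag it), but report observed/above-threshold
fractions over all records. The set-level enrichment test is a logistic
regression of population label on `log2(AF)` with two rows per variant
(label 1 with the first population's frequency, label 0 with the second's,
zero-frequency rows dropped). The two-row construction is one faithful
reading of the underspecified model formula "label ~ log2(AF)"; it is
documented as such. Note that a *deterministic* frequency shift between
the populations makes this design perfectly separable, in which case the
fit is flagged and Wald statistics are not meaningful; real AF tables have
overlapping distributions.

## IBD filtering, merging and sharing

Detector output is filtered at LOD strictly greater than 3, then merged
within each (pair, chromosome): segments sorted by start are absorbed
left-to-right whenever the genetic gap is at most 0.6 cM (inclusive — "not
greater than") *and* the gap's physical interval contains at most one
discordant homozygote (one sample dosage 0, the other 2 — impossible on a
truly shared haplotype, so two or more indicate the detector split two
different haplotypes). Choices that were open:

- Greedy left-to-right chaining after sorting: deterministic and
  order-invariant, which the tests verify along with idempotence.
- The gap is measured in cM between the left segment's end and the right
  segment's start; discordance is counted over the corresponding open bp
  interval.
- When a `genotyped` flag is present, only directly genotyped variants
  count toward discordance (imputed calls inflate it).
- Overlapping segments for one pair are detector artifacts; they are
  merged unconditionally with a warning.
- Zero-sharing pairs are *included* when taking medians between
  populations — the median is over "each pair of individuals", not each
  sharing pair.

The sharing matrix is turned into a dendrogram via the distance
`d(P,Q) = max_entry − median_cM(P,Q)` and average-linkage agglomeration.
Both the transform and the linkage are package choices (no canonical
convention exists); they are recorded in the result object, and labels are
processed in sorted order so ties resolve deterministically.

## Structure and QC

**HWE exact test.** The conditional exact test enumerates every
heterozygote count compatible with the observed allele counts, computes
configuration probabilities through a log-space expression proportional to
`2^h / (n_AA! n_Aa! n_aa!)`, normalises, and sums probabilities not
exceeding the observed configuration's (two-sided, no mid-p). The test
suite checks it against an independent brute-force enumerator for every
configuration with up to 50 alleles; agreement is at the 1e-12 level.

**Variant QC.** MAF > 0.01 and HWE p > 1e-4, both strict, with MAF from
non-missing dosages. LD pruning is greedy and windowed (defaults 50
variants, step 5 — common practice values, configurable), removing the
later-positioned variant of any pair at r² ≥ the threshold so retained LD
is strictly below it.

**PCA.** Variants are centered at `2p` and scaled by `sqrt(2p(1-p))`;
missing dosages are mean-imputed (zero after centering) inside PCA only —
everywhere else the package uses pairwise deletion, since imputation is
harmless for a rotation but would bias count-based statistics. Scores are
`U·D` from the SVD; monomorphic variants are skipped with a warning.

**Outliers and clusters.** Outlier removal iteratively deletes the sample
with maximum Euclidean distance from the current centroid in the top PCs,
recomputing the centroid each time, under either a fixed-count rule or an
adaptive `mean + 6·SD` stopping rule — both provided because published
analyses typically report only a removed count. Cluster assignment uses
k-means on the top two PCs with 100 random restarts (best within-cluster
sum of squares kept), deterministic under the seed; restarts substitute
for k-means++ seeding, which base R's `kmeans` does not implement, and at
these separations the best solution is stable. Cluster ids are relabelled
by ascending mean PC1, so labels are initialization-invariant whenever the
optimum is unique.

**F_ST and kinship.** Hudson's estimator is the default (per-variant
numerator `(p_a-p_b)² − p_a(1-p_a)/(n_a-1) − p_b(1-p_b)/(n_b-1)`,
denominator `p_a(1-p_b)+p_b(1-p_a)`, global = ratio of sums) for its
stability as a ratio of averages; Weir–Cockerham is available because
widely used tools report it. Kinship is the within-pair robust estimator
`(N_het,het − 2·N_opp) / (N_het,i + N_het,j)` with conventional duplicate
(> 0.354) and degree-3 (> 0.0884) flags, both configurable since the
relatedness cutoffs used in any given study are rarely stated.

## Association scans

Phenotype QC keeps phenotypes observed in strictly more than 200
individuals; trim-flagged quantitative phenotypes have values strictly
outside their empirical 5th–95th quantiles (type-7) set to missing; every
quantitative phenotype also gets an *untrimmed* IRNT version
`qnorm((rank − 0.5)/n)` with ties averaged — the rank transform already
neutralises outliers, so trimming it would discard information twice.
Boundary values at exactly the quantiles survive trimming; the convention
is documented and configurable because "filtering out the 5th and 95th
quantiles" does not pin down the endpoint behaviour.

Associations are ordinary least squares (quantitative and
integer-coded categorical phenotypes) or maximum-likelihood logistic
regression (binary), per variant, adjusted for sex, age and the leading
PCs, with listwise deletion of missing values and no covariate
imputation. Wald p-values use the t distribution (linear) or normal
(logistic). Logistic fits that fail to converge or separate return a
flagged row with missing SE/p rather than aborting a scan. The driver
re-applies variant QC on each phenotype's analysis subsample — a variant
can pass cohort-wide QC yet be too rare among the subset with a given lab
measurement. Reference-solver agreement (against `lm`/`glm` on random
designs) is enforced at 1e-6 in the test suite.

## Replication

Candidates are enriched variants that are testable locally (MAF > 0.01)
and whose enrichment is not better explained by the second continental
source (`log2(AF_EAS/AF_NFE) < 2`, strict; sentinel ratios pass, since a
variant absent from EAS cannot be EAS-driven). Candidates with external
associations at p < 5e-8 (the conventional genome-wide constant,
configurable) are grouped by phenotype similarity and LD-clumped greedily
and *independently per group* at r² < 0.1, best p first, ties broken by
position. The replication threshold is
`alpha / (n_independent × n_groups)`; each clumped variant's best local
p-value over the group's phenotypes is compared against it. Matching a
variant to a *different* local phenotype within the group is permitted and
flagged (`cross_phenotype`), because replication through a comorbid
phenotype is epidemiologically meaningful. Report tiers are nested by
construction: replicated ⊆ clumped ⊆ matched ⊆ candidates. Clumping uses
local genotypes as the LD reference by default; an external reference can
be substituted by passing a different genotype matrix.

## The pipeline

`run_pipeline()` chains simulate → structure → enrich → ibd → gwas →
replicate from one validated config (YAML-serialisable; unknown keys are
errors). Each stage writes plain-text outputs plus a manifest row with md5
checksums, the seed and wall time; two runs with the same config produce
byte-identical outputs. In the pipeline's AF table the two simulated
sources play the enriched-source and reference roles, per-cluster realized
frequencies give the cluster columns, and a synthetic outgroup column is
constructed so that most planted enriched variants pass the outgroup
filter, a tenth are unobserved there (exercising the sentinel path) and a
tenth are planted common (exercising the filter). The external catalogue
is likewise synthetic: planted causal variants appear as strong external
hits, plus null candidates whose local signals are noise.

## Problem sizes and numerical choices

Validation uses cohorts of 100–400 samples and 1,500–5,000 variants —
large enough that the closed-form checks (binomial standard errors, F_ST
moments, type-I error bands) have power, small enough to run in minutes on
one CPU. Tolerances: HWE vs enumeration at 1e-12 (both exact, differing
only in floating-point path); regression vs reference solver at 1e-6;
F_ST recovery at ±0.02 around the configured F; k-means restarts 100;
logistic IRLS tolerance 1e-8, 50 iterations. Ties: p-value ties in
clumping break by position; k-means label ties by mean-PC1 rank with
`ties.method = "first"`; dendrogram label ties by sorted label order.

## Limitations

The simulator has no linkage disequilibrium (variants are independent
given ancestry), no phased haplotypes, no recombination maps beyond the
uniform 1 cM/Mb default, and no genotyping/imputation error model beyond
uniform missingness. Consequently, passing tests demonstrate the
*rule-level* correctness of each computation and the statistical
calibration of the models under the stated generative assumptions — not
robustness to LD structure, imputation artifacts or batch effects in real
array data. IBD segments are simulated directly rather than detected from
haplotypes, so detector biases are out of scope, as are ADMIXTURE-style
model fitting, effective-population-size estimation, heritability and
genetic-correlation estimation, and annotation.
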