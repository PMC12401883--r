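---
title: "Clonality and ancestry inference in mixed-ploidy hybrid complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clonality and ancestry inference in mixed-ploidy hybrid complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cloneploid)
```

`cloneploid` chains the analyses needed to characterise a hybrid,
partly clonal, mixed-ploidy plant complex from called SNP genotypes:
variant QC, clonemate detection, population structure, ploidy and cross
arithmetic, and maternal-lineage assignment. This vignette documents
the models behind each stage, the parameters that matter, the numerical
choices, and what the packaged simulations do and do not establish
about real data.

## The variant QC cascade

Inputs are biallelic SNP calls with GATK-style site annotations and
per-genotype quality fields. The cascade runs in a fixed order, each
stage only removing information:

1. **Proximity/biallelic filter.** SNPs within 20 bp (inclusive, per
   contig) of an indel or other variant type are removed, as are all
   non-biallelic-SNP records. Alignment artefacts concentrate around
   indels, and identity statistics downstream assume two alleles.
2. **Site hard filters.** A site fails if any of: QD < 10, FS > 60,
   SOR > 3, MQ < 40, |MQRankSum| > 2.5, DP > 2 × mean depth,
   ReadPosRankSum > 2.5. The depth cutoff is parameterised as a
   multiple of the dataset mean depth rather than an absolute value,
   since total depth scales with cohort size. The rank-sum criterion is
   two-sided: a strong skew in either direction indicates
   reference/alternate asymmetry in mapping or read position. Sites
   lacking an annotation cannot be evaluated and are allowed to pass —
   rejecting them would silently discard most herbarium-grade records,
   and the genotype-level mask still protects the calls.
3. **Genotype masking.** An individual call becomes missing when
   GQ < 30 *or* DP < 10. The disjunction matches the per-flag semantics
   of the standard VCF tools these thresholds come from; applying the
   two flags jointly means either failure masks.

The **diploidized ("non-ploidy") coding** collapses a dosage g in
`0..m` to 0/1/2 (homozygous reference, any heterozygote, homozygous
alternate). It discards dosage information but makes samples of
different ploidy directly comparable, which is what the identity
statistics below require. The map is idempotent on diploid input and
surjective onto {0, 1, 2}.

## Clonemate detection

Two complementary pairwise statistics are computed on diploidized
genotypes, excluding sites missing in either member of a pair.

**Shared heterozygosity.** SH = (number of jointly heterozygous
sites) / max(per-individual heterozygous counts), defined as 0 when
neither individual is heterozygous anywhere. Clonemates share their
heterozygous sites up to genotyping error, so SH sits near 1 for
clones; unrelated individuals share heterozygosity only as far as
allele frequencies force them to. The literature describes this index
in words rather than as a formula; the numerator is parameterised
(`"joint"`, default, or `"union"`) so the alternative reading can be
swapped in. SH is computed on the full filtered site set.

**Method-of-moments IBD.** For each pair, identity-by-state counts
(IBS 0/1/2 per site) are compared with their expectations under the
sample allele frequencies to estimate the probabilities Z0, Z1, Z2 of
sharing 0, 1, 2 alleles identical by descent, and π̂ = Z2 + Z1/2.
Expectations use unbiased falling-factorial estimators of the frequency
monomials (the finite-sample corrections of the classic PLINK
estimator); frequencies come from all retained samples, and sites with
minor allele count < 2 are dropped as uninformative. Negative moment
estimates are truncated to [0, 1] and renormalised — standard practice
for this estimator. Pairs with fewer than 100 informative sites are
flagged low-confidence rather than silently returned. IBD runs on the
LD-pruned subset, since the estimator assumes independent sites.

Clone groups are the connected components of the graph linking pairs
with π̂ above the threshold (default 0.95; SH > 0.90 is reported
alongside). The component closure makes clonality transitive, which is
what "same genet" means. The estimator is calibrated for diploidized
data: identical vectors give π̂ ≈ 1, Hardy–Weinberg unrelated pairs
≈ 0, parent–offspring diploid pairs ≈ 0.5; triploid full sibs fall
well below the 0.95 threshold, so close relatives are not mistaken for
clonemates. Note that diploidized *polyploid* non-relatives show excess
heterozygosity relative to the diploid model; the clonality decision is
driven by near-total IBS2 sharing and is insensitive to this, but π̂
for unrelated polyploid pairs should not be over-interpreted.

## Population structure

**LD pruning** follows the `--indep-pairwise 50 5 0.7` semantics:
within a 50-site window sliding by 5 sites, whenever the squared
Pearson correlation of a still-retained pair exceeds 0.7 the later site
is dropped. The procedure is deterministic for a fixed column order and
invariant to adding constants (correlation invariance). Windows are
site-count based, matching the stated flag form.

**PCA** mean-imputes missing calls per site, centres by the mean
dosage, scales by the binomial standard deviation at the estimated
allele frequency (so high- and low-frequency sites contribute
comparably), and eigendecomposes the sample covariance. Monomorphic
sites are dropped; variance-explained percentages are reported per
axis.

**Admixture.** The dosage of sample *i* at site *j* is modelled as

g_ij ~ Binomial(m_i, Σ_k q_ik f_kj)

with m_i the sample's ploidy — so a triploid F1 contributes three
copies per site, and allele dosage informs ancestry fractions exactly
as the gamete arithmetic predicts. Priors are Dirichlet(1) on each q
row and Beta(1,1) on each cluster frequency. Sampling is Gibbs with
per-copy ancestry augmentation: conditional on (q, f), the g_ij
alternate copies split multinomially over clusters with weights
q_ik f_kj (reference copies with weights q_ik (1 − f_kj)); conditional
on the assignments, f and q have conjugate Beta/Dirichlet updates.
Missing dosages contribute no copies — they are marginalised, not
imputed. Three chains are run by default (2000 iterations, 50 %
burn-in, thinning 5); chain count follows standard practice for this
model class, chain length is the package's own choice sized to the
desk-scale problems below. Cluster labels are aligned across chains by
matching posterior-mean frequency vectors over all permutations
(feasible for K ≤ 6); convergence is monitored by split-R̂ on q, with
values above 1.1 producing a warning, not an error — the augmented
chain mixes slowly on large site counts and the posterior-mean q is
typically stable well before R̂ tightens. Frequencies are clamped to
[10⁻⁶, 1 − 10⁻⁶] to keep the likelihood finite.

Model fit is summarised by DIC (mean posterior deviance plus effective
parameter count p_D = mean deviance − deviance at the posterior mean)
and by lppd (pointwise log of the mean posterior likelihood over
retained draws); `select_K()` takes the DIC-minimising K, breaking ties
toward the smaller K (parsimony).

This sampler is a deliberate simplification of the mixed-ploidy
genotype-likelihood models in the literature: it operates on called
integer dosages rather than genotype likelihoods, because at package
scale no read-level uncertainty is available. Two consequences are
worth knowing. First, posterior ancestry for a *pure* parental sample
concentrates at the simplex vertex only as markers and cohort size
grow; with a handful of parents and a few hundred sites the posterior
mean sits near 0.95–0.97 rather than 0.99 — the package's tests
demonstrate vertex concentration on a 24-sample, 4000-site panel.
Second, DIC for this family favours the true cluster number clearly in
separable simulations, but as with any deviance-based criterion it
should be read jointly with lppd and the q matrices.

## Ploidy classification and cross arithmetic

Flow cytometry yields a 2C DNA amount per accession. Given a monoploid
genome size 1Cx — calibrated as half the mean 2C of accessions known to
be diploid (e.g. from chromosome counts) — the ploidy call is the
nearest integer to 2C / 1Cx; only the ratio matters, so the call is
scale-invariant. Calls farther than the acceptance band from an
integer are flagged ambiguous; with the default band (±0.5) only exact
half-integer ties are flagged, since the empirical 2C ranges of
distinct cytotypes are well separated. Endopolyploidy, common in
succulent tissue, affects which nuclei dominate a histogram but is not
modelled here: classification starts from the reported 2C value.

Cross arithmetic works in chromosome sets: a reduced gamete from a
ploidy-m parent carries m/2 sets (requiring even m), an unreduced
(non-disjunct) gamete all m. With base number x = 17, the canonical
crosses give: diploid × tetraploid (both reduced) → 2n = 3x = 51, a
triploid; diploid contributing an unreduced gamete × tetraploid
(reduced) → 2n = 4x = 68, a tetraploid — the only route to a
tetraploid F1 from these parents, which is why a tetraploid hybrid
cytotype implies a non-disjunct gamete from the diploid donor. The
expected genome fraction of each parent is its gamete copy number over
the offspring ploidy — (1/3, 2/3) for the triploid, (1/2, 1/2) for the
unreduced-gamete tetraploid — and `compare_ancestry()` checks fitted
admixture proportions against these expectations within a tolerance
(default 0.10, reflecting the spread of posterior means around the
truth at desk scale).

## Maternal lineage and the integrated report

Plastomes are uniparentally (maternally) inherited, so the parental
reference haplotype nearest to a sample's plastome identifies its
maternal species. Distance is Hamming over aligned columns, excluding
gaps and Ns; assignment requires a unique minimum below a ceiling
(default 10 % of the alignment). This nearest-haplotype rule replaces
full phylogenetic tree inference; when the parental haplotypes are
distinct, the decision it makes is the same as reading the clade
membership off a plastome tree, at a fraction of the machinery.

`morphotype_report()` is a pure join of the evidence lines (ploidy,
ancestry fraction, clone group, maternal parent) plus a verdict rule:
tetraploid with q_A ≈ 1/2 → unreduced-gamete F1; triploid with
q_A ≈ 1/3 → F1; diploid with intermediate q_A → introgressant;
samples loading fully on one pool → parental-like. Missing evidence
propagates as `NA` and restricts the verdict to "insufficient
evidence"; nothing is imputed.

## The synthetic-data generator

The generator produces cohorts with the statistical structure the
pipeline assumes, so every stage can be validated offline.

* **Parental divergence** uses the Balding–Nichols construction: per
  site an ancestral frequency p ~ Uniform(0.05, 0.95), and each pool
  draws its frequency from Beta(p(1−F)/F, (1−p)(1−F)/F). The drift
  parameter F equals the expected Fst between pools; the default
  F = 0.3 emulates two well-separated congeneric species, strong
  enough that PCA separates the pools and admixture resolves parental
  clusters. The package's tests recover F within ±0.05 with an
  independent Hudson-type estimator at 10 000 sites.
* **Genotypes** are Binomial(ploidy, pool frequency) — exchangeable
  sites, no linkage. LD, where a test needs it, is induced by
  duplicating or perturbing columns in dedicated fixtures.
* **Hybrids**: reduced gametes sample m/2 of the parent's m allele
  copies without replacement per site (random bivalent pairing — the
  hypergeometric draw on the dosage); unreduced gametes copy all m.
  Triploid F1s take a 1-copy gamete from a diploid pool-A mother and a
  2-copy gamete from a tetraploid pool-B father; tetraploid F1s take
  the mother's gamete unreduced. The diploid introgressant class takes
  a single-copy gamete from a triploid F1 mother (carrying the pool-B
  plastome) and a reduced gamete from a diploid pool-A father, giving
  an expected pool-A fraction of 2/3 — the natural-introgression
  scenario in which the diploid morphotype differs from a parental
  diploid both in ancestry and in plastome.
* **Clonal replicates** copy a founder, resampling each dosage
  uniformly among the other legal values with probability ε
  (default 0.005) and masking calls with probability μ (default 0.02).
  ε is a free parameter standing in for sequencing error plus somatic
  mutation — real clonemate pairs show IBD slightly below 1 — and is
  not an inferred quantity; uniform resampling is used because no
  error-spectrum model is available for dosage calls.
* **Annotations** for passing sites are drawn from ranges safely inside
  the filter thresholds (QD 15–35, FS 0–20, SOR 0.5–2.5, MQ 50–60,
  rank sums ±1.5, DP within 20 % of the nominal mean); a configurable
  fraction of SNP sites (default 0.1) receives exactly one annotation
  beyond its threshold, with the violated criterion recorded as truth.
  Indel records are interleaved at uniform positions to exercise the
  proximity filter; SNP positions are spaced ≥ 30 bp so SNPs never
  disturb each other. Coordinates are 1-based on one synthetic contig,
  per the VCF standard.
* **Plastomes**: two references (2000 bp, 40 diagnostic differences)
  and per-sample maternal copies with 10⁻³ per-base error. With error
  ≪ diagnostic density, a sample's distance to its maternal pool is
  strictly smaller than to the other pool.
* **Determinism**: a fixed seed makes the full dataset — including the
  emitted VCF bytes — identical across runs; the VCF header carries no
  timestamp.

**What passing tests do and do not show.** The simulations establish
that each statistic does what it claims under its own assumptions
(exchangeable sites, binomial dosages, known ploidy, unstructured
error). Real data add linkage, depth-dependent genotyping error
correlated across clonemates, reference bias, herbarium DNA
degradation, and ploidy heterogeneity within taxa — none of which the
generator emulates. Published cohort-scale numbers (tens of thousands
of retained SNPs, specific PCA axis percentages, per-morphotype
cluster contributions) depend on the archived sequencing data and are
*not* reproduced at package scale; what the tests mirror are the
structural properties those numbers instantiate: monotone filter
attrition, pool separation on PC1, clone-pair IBD above 0.95 with
relatives below it, and ancestry fractions at the gamete-arithmetic
expectations.

## Problem sizes and tolerances

The test suite and the acceptance script run at desk scale, chosen so
the full suite completes in minutes: clonality checks use 10 000-site
cohorts over 50 seeded replicates (clone-pair π̂ ≥ 0.95 and SH > 0.90,
sibs and parent–offspring below threshold in ≥ 95 % of replicates);
admixture recovery uses 400-site cohorts with 6 + 6 parents and 6 + 6
hybrids (mean q within ±0.05 of 1/3 and 1/2; DIC selects K = 2 from
K ∈ 1..4); the vertex-concentration check uses 12 + 12 parents at
4000 sites; oracle-equivalence checks (brute-force LD pruning, naive
SH counting, hand-enumerated filter fixtures) are exact.

## Known limitations

* The admixture sampler consumes called dosages, not genotype
  likelihoods; low-coverage uncertainty is invisible to it.
* IBD moments assume diploid coding; there is no polysomic-dosage IBD.
* The SH numerator is reconstructed from a verbal description; both
  readings are implemented, the joint-count being the default.
* Flow-cytometry classification starts from reported 2C values;
  histogram peak calling and endopolyploidy are out of scope.
* No tree inference: maternal assignment is nearest-haplotype only.
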