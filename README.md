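# cloneploid

Clonality detection and mixed-ploidy hybrid ancestry analysis from
biallelic SNP genotypes.

## The problem

Invasive plant complexes that arise from interploidy hybridization — the
*Kalanchoe × houghtonii* "mother of millions" complex is the motivating
case, a cross between diploid *K. daigremontiana* (2n = 2x = 34) and
tetraploid *K. delagoensis* (2n = 4x = 68) — pose a chain of linked
questions: Which cytotypes exist, and how did each arise from the
parental gametes? Which accessions are clonemates of a single genet?
What fraction of each hybrid genome derives from each parental species,
and which parent was the maternal (plastome) donor? `cloneploid`
implements that chain of inference as a tested, reusable pipeline
operating on called genotypes, for population geneticists working on
mixed-ploidy or clonal plant systems.

## What it computes

* **SNP hard-filter cascade** — removal of SNPs within 20 bp of an
  indel or other variant type and of non-biallelic records, followed by
  site exclusion on GATK-style annotations (QD < 10, FS > 60, SOR > 3,
  MQ < 40, |MQRankSum| > 2.5, DP > 2 × mean depth,
  ReadPosRankSum > 2.5) and per-genotype masking (GQ < 30 or DP < 10),
  with a per-stage retention report.
* **Diploidized ("non-ploidy") coding** — a polyploid dosage g in
  0..m collapses to 0 (g = 0), 2 (g = m) or 1 (otherwise), making
  mixed-ploidy samples comparable for identity statistics.
* **Clonemate detection** — the shared-heterozygosity index
  SH = |het(A) ∩ het(B)| / max(|het(A)|, |het(B)|), and
  method-of-moments identity by descent: identity-by-state counts
  corrected by their allele-frequency expectations give (Z0, Z1, Z2)
  and the IBD proportion π̂ = Z2 + Z1/2. Pairs with π̂ > 0.95 are
  linked and connected components define clone groups; SH > 0.90 is
  flagged alongside.
* **LD pruning and PCA** — sliding-window r² pruning
  (50-site window, step 5, r² > 0.7 drops the later site) and genotype
  PCA with allele-frequency (binomial-variance) scaling.
* **Mixed-ploidy admixture** — a Bayesian model with
  g_ij ~ Binomial(m_i, Σ_k q_ik f_kj), Dirichlet(1) prior on the
  ancestry proportions q_i and Beta(1,1) on cluster frequencies f_k,
  fitted by Gibbs sampling over multiple chains; the number of clusters
  K is selected by DIC, with lppd reported alongside.
* **Ploidy and cross arithmetic** — flow-cytometry 2C values classified
  by the nearest-integer ratio to a calibrated monoploid genome size
  1Cx; interploidy crosses predicted from gamete chromosome numbers
  (x·m/2 reduced, x·m unreduced), giving the offspring 2n, cytotype
  and expected parental genome fractions (gamete copies / offspring
  ploidy).
* **Maternal-parent assignment** — nearest parental plastome haplotype
  by gap-excluded Hamming distance, exploiting uniparental plastome
  inheritance; plus an integrated per-sample morphotype report.
* **Synthetic cohorts** — a generator producing diverged parental pools
  (Balding–Nichols divergence), interploidy F1s (reduced and unreduced
  gametes), clonal replicates with genotyping error and missingness,
  annotated VCF output and maternally inherited plastomes, so the whole
  pipeline is testable offline.

## Worked example

```r
library(cloneploid)

cfg <- sim_config(n_sites = 3000, n_parents_A = 4, n_parents_B = 4,
                  hybrids = c(triploid_F1 = 2, tetraploid_unreduced_F1 = 1),
                  clones = c(H3 = 3), seed = 7)
sim <- simulate_dataset(cfg)
sim$genotypes
#> <dosage_matrix: 14 samples x 3000 sites>
#>   ploidy: 2x:4 3x:2 4x:8
#>   missing: 0.43%

dd <- diploidize(sim$genotypes$dosage, sim$genotypes$ploidy)
pruned <- dd[, ld_prune(dd), drop = FALSE]
rel <- relatedness_table(dd, pruned)
subset(rel, clonal_by_IBD, c(id1, id2, SH, PI_HAT))
#>    id1   id2        SH    PI_HAT
#> 86  H3 H3_c1 0.9976331 0.9685975
#> 87  H3 H3_c2 0.9976359 0.9808128
#> 88  H3 H3_c3 0.9941072 0.9683216
```

The three noisy clonal replicates of the tetraploid F1 founder `H3` —
and only they — exceed both clonality thresholds (SH > 0.90,
π̂ > 0.95); `call_clones(rel)` places the four samples in one clone
group. Ancestry fractions recover the gamete arithmetic:

```r
fit <- admixture_fit(sim$genotypes$dosage[, 1:500], sim$genotypes$ploidy,
                     K = 2, chains = 3, iter = 3000, seed = 2)
fit
#> Mixed-ploidy admixture fit: K = 2, 14 samples, 500 sites
#>   DIC = 11715.2  lppd = -5319.9  p_D = 585.2  draws = 900
#>   max split-R-hat(q) = 1.061
cm <- map_clusters_to_parents(fit, paste0("A", 1:4), paste0("B", 1:4))
round(fit$q[c("A1", "B1", "H1", "H3"), cm[["A"]]], 3)
#>    A1    B1    H1    H3
#> 0.933 0.023 0.321 0.525
```

A diploid pool-A parent loads ~1 on its own cluster, a triploid F1
(`H1`) carries about one third pool-A ancestry (one of three genome
copies from the diploid parent) and the unreduced-gamete tetraploid F1
(`H3`) about one half. The corresponding cross prediction:

```r
predict_offspring(cross_spec(2, 4, "reduced", "reduced", x = 17))
#> $ploidy   [1] 3
#> $two_n    [1] 51
#> $cytotype [1] "triploid"
```

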