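Package: cloneploid
Title: Clonality and Mixed-Ploidy Ancestry Analysis from SNP Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for detecting clonal lineages and dissecting hybrid
    ancestry in mixed-ploidy plant complexes from biallelic SNP genotype
    calls.  Implements a GATK-style hard-filter cascade with genotype-level
    masking and diploidized ("non-ploidy") recoding of polyploid calls,
    shared-heterozygosity and method-of-moments identity-by-descent
    clonemate detection, sliding-window linkage-disequilibrium pruning,
    genotype principal component analysis with allele-frequency scaling,
    a dosage-aware Bayesian admixture model for autopolyploid and
    mixed-ploidy samples with DIC-based selection of the number of
    clusters, flow-cytometry ploidy classification, interploidy-cross
    arithmetic (offspring cytotype, chromosome number and expected
    parental genome fractions), and maternal-parent assignment from
    plastome haplotypes.  A synthetic-data generator produces
    mixed-ploidy cohorts (diverged parental pools, interploidy F1
    hybrids, clonal replicates with genotyping error, maternally
    inherited plastomes) so the whole chain of inference can be
    exercised and validated offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    vcfR,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
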