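Package: runscan
Title: Sliding-Window Detection of Runs of Homozygosity and
    Heterozygosity-Rich Regions from SNP-Array Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for genomic characterization of populations genotyped on
    dense SNP arrays: PLINK text (PED/MAP) input and output, quality control
    and linkage-disequilibrium pruning, per-breed diversity indices
    (observed and expected heterozygosity, inbreeding coefficient F_IS,
    minor allele frequency), identity-by-state distance matrices and
    classical multidimensional scaling, sliding-window detection of runs of
    homozygosity (ROH) and heterozygosity-rich regions (HRR) with
    per-individual and per-breed summaries (N, L, S, F_ROH, D_HRR) and
    length-class tables, ROH/HRR island calling from per-SNP run-occurrence
    frequencies with gene-interval annotation, and a synthetic genotype
    simulator with planted homozygous or heterozygous tracts for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
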