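Package: lineagetrace
Title: Lineage Frequency Inference from Clonal Genomes and Metagenomic Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tracks asexual, mixed-ploidy yeast lineages through an industrial
    fermentation season by combining whole-genome genotypes of clonal isolates,
    organized on a phylogeny into clades with synapomorphic markers, with
    whole-population metagenomic allele counts sampled over time. Clone ploidy
    (diploid or triploid) is classified from the genome-wide allele-frequency
    spectrum, per-site allele copy numbers are called with a binomial genotype
    posterior, clade-defining markers are selected from the clonal phylogeny,
    and per-timepoint lineage frequencies are then jointly estimated by
    constrained maximum likelihood under nested clade-sum constraints. A
    synthetic fermentation-season simulator provides ground truth for
    end-to-end validation, including clone-rarefaction experiments, and a set
    of back-of-envelope population-genetic calculators summarizes mutation
    supply and clonal diversity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
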