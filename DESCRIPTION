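Package: islandpopgen
Title: Fine-Scale Island Demography from SNP Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale population-genetic inference chain for fine-scale
    island demography: declarative multi-deme demographic models with size
    epochs, splits and migration; a structured-coalescent simulator for
    SNP-array-like genotype panels, joint site-frequency spectra and
    ground-truth identity-by-descent (IBD) segments; genotype and sample
    quality control (call rates, exact Hardy-Weinberg test, relatedness
    pruning); Hudson's F_ST and Patterson's D with weighted block-jackknife
    standard errors; runs of homozygosity; PCA; seed-and-extend IBD segment
    detection with gap merging and a haplotype-sharing index; IBDNe-style
    recent effective population size estimation from IBD length spectra; and
    fastsimcoal2-style SFS composite-likelihood demographic parameter fitting
    with parametric-bootstrap confidence intervals. Ships the fitted
    five-population Ryukyu-islands (Okinawa/Miyako) model as a worked,
    simulable example.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    GenomicRanges,
    IRanges,
    S4Vectors,
    optparse
Config/testthat/edition: 3
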