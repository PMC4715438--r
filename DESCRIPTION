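Package: hummintro
Title: Phylogeography and Introgression Toolkit for a Mesoamerican
    Hummingbird Species Complex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale population-genetic and ecological analyses for a
    three-species hummingbird complex separated by two lowland barriers:
    sequence diversity summaries (haplotypes, segregating sites, haplotype
    and nucleotide diversity), neutrality tests (Tajima's D, Fu's Fs) with
    coalescent p-values, mismatch distributions with sudden-expansion model
    fits (SSD, Harpending's raggedness, parametric bootstrap),
    median-joining haplotype networks, conversions of coalescent-scaled
    parameters to demographic units (generation time, effective sizes,
    divergence in years, migrants per generation), Mantel comparison of
    contemporary and historical migration matrices, Evanno DeltaK
    post-processing of Bayesian assignment runs, mean-centred genotype PCA,
    a background-vs-occupied niche divergence/conservatism jackknife test,
    a ten-character plumage colour index, reproducible synthetic-data
    generators for every stage, and a config-driven pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    MASS,
    stats,
    utils,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
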