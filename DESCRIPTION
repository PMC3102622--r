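Package: pedhap
Title: Pedigree Likelihoods and Recombination Inference from Haplotype and
    Genotype Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact pedigree analysis for multilocus marker data observed
    either as genotypes (unordered allele pairs) or as haplotypes (allele
    sequences of unknown parental origin). Implements inheritance-vector
    hidden Markov models for the likelihood, the posterior distribution of
    per-interval recombination counts, exhaustive maximum-probability
    phasing, and min-sum minimum-recombination phasing; the proxy-family
    construction that embeds any genotype problem in a haplotype problem
    together with its recombination-count offset and 16-state transmission
    chain; linear-time trio-decomposition algorithms for pedigrees in which
    every individual is haplotyped; and a gene-dropping simulator with an
    l1-based accuracy score for comparing recombination estimates from
    haplotype versus genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
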