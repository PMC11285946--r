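Package: selfpoly
Title: Polygenic Adaptation to a Shifting Optimum under Partial Self-Fertilisation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analytic models and forward-time simulation of polygenic
    adaptation under partial self-fertilisation. Provides an exact
    deterministic two-locus genotype recursion under selfing and Gaussian
    stabilising selection together with its closed-form approximations for
    linkage-disequilibrium and allele-frequency dynamics; multi-locus
    equilibrium theory with background-association coefficients (equilibrium
    frequencies and the decomposition of genetic variance into genic,
    inbreeding and linkage-disequilibrium components); a Wright-Fisher
    forward simulator with linked loci, partial selfing, pleiotropic
    Gaussian stabilising selection, recessive deleterious mutations and
    burn-in/optimum-shift scheduling; downstream statistics (variance
    decomposition, inbreeding depression, linkage-disequilibrium matrices
    and decay curves, haplotype sampling, allele trajectories); and
    effective-rate rescaling formulas for comparing high selfing with
    low-recombination outcrossing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
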