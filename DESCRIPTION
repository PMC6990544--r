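Package: rohcov
Title: Runs of Homozygosity Detection and Genome-Coverage Validation for
    SNP Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects runs of homozygosity (ROH) in diploid autosomal
    SNP-array genotypes with the three-step scanning-window algorithm
    (window hit rates, hit-rate thresholding, segment splitting and
    filtering) used by PLINK's --homozyg family, and validates any
    parameterization through the genome-coverage statistic: the fraction
    of the autosomal genome on which ROH detection is possible at the
    chosen settings, measured by running detection on a simulated fully
    homozygous individual. Provides the two genomic inbreeding
    estimators F_ROH,aut and F_ROH,cov, minor-allele-frequency and
    windowed pairwise linkage-disequilibrium pruning, per-SNP ROH
    incidence, the Lencz minimum-SNP formula, a window-threshold
    calculator, parameter-sensitivity sweeps, PLINK text (.ped/.map)
    input and output, and a synthetic genotype generator with planted
    homozygous segments of known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
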