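Package: rohfst
Title: Runs-of-Homozygosity and FST Selection-Signature Scans for SNP-Array Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for genome-wide analyses of multi-breed
    SNP-array genotype panels: PLINK binary/text input and output with
    quality-control filtering, per-breed observed and unbiased expected
    heterozygosity and the inbreeding coefficient FIS, scanning-window
    detection of runs of homozygosity (ROH) and the genomic inbreeding
    coefficient FROH, per-breed ROH islands from percentile-thresholded
    per-SNP ROH occurrence, window-based weighted Weir-Cockerham FST
    contrasts between environment-defined metapopulations, Reynolds and
    identity-by-state distance matrices with classical multidimensional
    scaling, and a Balding-Nichols multi-breed simulator with injected
    selective sweeps and homozygous tracts for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
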