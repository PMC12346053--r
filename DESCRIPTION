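Package: hrrscan
Title: Heterozygosity-Rich Regions and Island Significance in Herd-Structured SNP Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection of heterozygosity-rich regions (HRRs) and runs of
    homozygosity (ROHs) in SNP-array genotypes by the consecutive-runs method,
    calling of HRR/ROH islands from per-marker run incidence, a permutation
    null for island significance in herd-structured populations, chromosome
    saturation ranks and the coefficient of extended heterozygosity, windowed
    Tajima's D scanning with SD-based outlier flagging, repeat-element
    coverage comparison between island classes, and a Balding-Nichols style
    herd-genotype simulator with planted heterozygote islands and homozygous
    tracts for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    IRanges,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
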