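Package: methphase
Title: Nucleosome-Phased DNA Methylation Analysis for Whole-Genome
    Bisulfite Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of DNA methylation patterning around constitutively
    occupied CTCF binding sites and of non-CpG (CH) methylation from
    whole-genome bisulfite sequencing cytosine reports. Provides record-level
    quality filters and bisulfite conversion-rate estimation from phage
    spike-in controls, statistical calling of methylated non-CG cytosines
    against the conversion-error background, detection of exon-localised
    non-conversion spikes, orientation-aware aggregated methylation profiles
    around anchor motifs, a maximal-overlap Daubechies-16 wavelet
    multi-resolution decomposition that separates the methylation trend from
    its nucleosome-scale oscillation (period, amplitude, and a
    nucleosome-influence scalar), per-CpG differential methylation with a
    Fisher/chi-square switch and FDR control, enrichment of methylation
    changes by nucleosome/linker phase, and a synthetic methylome generator
    that emulates the statistical structure of these signals for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    IRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
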