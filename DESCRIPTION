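Package: supscan
Title: Identification and Quantification of Spontaneous Suppressor Mutations in Yeast Strain Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for identifying spontaneous suppressor mutations of
    temperature-sensitive alleles in parent/suppressor yeast strain cohorts
    and for quantifying the strength and cross-background conservation of
    the resulting suppression interactions. Implements a parental-subtraction
    variant filter chain with quality and recurrence filters, a minimal
    coding-consequence annotator, read-depth aneuploidy calling with
    flow-cytometry ploidy correction, per-strain explanation classes with
    candidate-gene shortlisting on aneuploid chromosomes, colony-size
    fitness statistics (one-sided Welch tests with Bonferroni correction,
    Tukey HSD for combined overexpression, fold-change conservation
    matrices), and RPKM-based expression comparison. A synthetic-cohort
    generator emulates the breeding design (backcross introgression with
    selection at a temperature-sensitive locus), mutation structure, depth
    tracks, and colony-size distributions of a real screen, with recorded
    ground truth, so the whole pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings,
    vcfR,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
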