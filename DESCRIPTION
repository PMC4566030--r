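Package: semotif
Title: Skipped-Exon Motif Enrichment and Positional RNA Maps for
    Splicing-Factor Targets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising the cis-regulatory architecture of
    cassette (skipped) exons controlled by an RNA binding protein, modelled
    on knockout studies of the epithelial splicing regulators Esrp1/Esrp2.
    Classifies differentially skipped exons from rMATS-style tables into
    enhanced, silenced and control sets; extracts strand-aware exonic and
    250-nt flanking intronic sequences with splice-site exclusions; tests
    region-wise motif enrichment with a right-sided Fisher exact test under
    by-nucleotide and by-sequence counting, with Benjamini-Hochberg
    correction per region; computes positional motif-coverage RNA maps with
    a sliding 50-nt window; applies Cuffdiff-style differential-expression
    and splicing-factor panel filters; and provides PSI, percent-change,
    t-test and concordance statistics. A fully seeded synthetic-data
    generator with planted motif occurrences supports end-to-end testing.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
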