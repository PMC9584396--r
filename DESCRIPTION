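Package: ibstriage
Title: Biomarker Triage for Irritable Bowel Syndrome Expression Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A seedable, fully synthetic re-implementation of a colonic-tissue
    biomarker triage pipeline for irritable bowel syndrome (IBS): microarray
    differential-expression screening with a three-test combination (pooled
    Student t, Mann-Whitney U, and an empirical-Bayes moderated t),
    hypergeometric gene-set over-representation against user-supplied GMT
    annotations, RT-qPCR delta-delta-Ct relative quantification against a
    pooled non-IBS control, a per-gene percent-accuracy statistic measuring
    directional concordance between patient qPCR fold changes and microarray
    fold changes with a 70 percent panel-selection threshold, and a
    1,25-dihydroxyvitamin-D treatment direction-reversal analysis in
    colorectal cells. A synthetic-data generator with known planted truth
    drives every stage, so the whole pipeline is testable without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
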