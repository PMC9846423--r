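Package: bspmeth
Title: Quantify CpG Methylation from Bisulfite Sequencing PCR Chromatograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes per-CpG DNA methylation percentages from Sanger
    bisulfite-sequencing-PCR (BSP) chromatogram trace files (ABIF, *.ab1),
    for both direct-BSP (peak-height ratios of mixed C/T signals) and
    cloning-BSP (binary clone statuses). Includes ABIF trace parsing and
    writing, Mott quality trimming combined with mixed-peak trimming,
    local alignment of reads to in-silico bisulfite-converted templates
    with automatic direction detection, bisulfite-conversion-rate quality
    control, per-sample methylation tables, a grouped comparative layer
    (Student's t and Kruskal-Wallis tests, lollipop / profile / boxplot /
    genomic figures), and a synthetic chromatogram generator with known
    ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
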