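Package: flavodia
Title: Glycosylated Flavonoid Profiling from DIA LC-MS Runs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for annotating glycosylated flavonoids in
    data-independent acquisition (DIA / MSE / all-ion fragmentation) LC-MS
    runs acquired in negative ionization mode. Precursor (MS1) and fragment
    (MS2) channels are feature-detected independently with the same
    chromatographic algorithms (EIC building, local-minimum peak resolving,
    13C deisotoping, join alignment, gap filling); rule-generated aglycone
    fragment databases cover heterolytic and homolytic O-glycoside cleavage
    and partial-sugar C-glycoside residues; precursors and fragments are
    linked by co-elution and peak-shape correlation; glycosyl neutral losses
    are assigned against a sugar dictionary to yield aglycone / bond-type /
    sugar calls such as "Quercetin O-hexoside". Includes a synthetic DIA-run
    generator with ground truth, summary analytics (flavone:flavonol ratio,
    backbone distributions, sample correlation, database-overlap counts) and
    ggplot2 figures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    methods,
    mzR,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
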