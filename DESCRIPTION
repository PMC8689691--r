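Package: mocloforge
Title: Design and In Silico Verification of MoClo Parts and Multiplexed
    gRNA Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design tools for Golden Gate cloning with the yeast MoClo
    standard. Generates type-specific domestication primers for new
    level-0 parts, designs one-step BsmBI primer sets for Csy4-separated
    multiplexed gRNA arrays of 2 to 12 spacers with conflict-free sticky
    ends, and verifies every design with an in silico type-IIS
    digestion/ligation simulator that reconstructs the assembled plasmid.
    Includes seeded synthetic fixtures (entry vectors, scaffold-separator
    templates, random spacers) so designs can be exercised end to end
    without any external sequence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    utils
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
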