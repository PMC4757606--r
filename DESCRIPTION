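Package: triweb
Title: Layout and Rendering of Quantitative Bipartite and Tripartite
    Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds, validates, lays out and renders quantitative bi- and
    tripartite ecological interaction networks (food webs, host-parasitoid
    webs, pollination networks). Taxa are drawn as abundance-scaled bars or
    uniform circles on up to three trophic levels; weighted links between
    adjacent levels are drawn as trapezoid bands or triangles whose base
    width encodes interaction strength. Includes readers and writers for
    semicolon-delimited species and interaction tables, a versioned JSON
    project format, an export to the 'cheddar' community format, automatic
    colour assignment, deterministic PNG/BMP/SVG rendering, and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    tibble
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
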