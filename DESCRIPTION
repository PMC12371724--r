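Package: snapmp
Title: Process Design and Image-Based Sizing for Sequential
    Nanoprecipitation Microparticles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calculators, fitting routines and synthetic-data generators for
    continuous polymeric microparticle manufacture by sequential
    nanoprecipitation (SNaP). Covers polymer solution viscosity
    (Mark-Houwink-Sakurada and Huggins equations), chain dimensions and
    overlap concentration, delay-channel residence time, Smoluchowski
    diffusion-limited growth predictions and throughput; circular Hough
    transform particle sizing of SEM-like micrographs with a polydispersity
    index; log-log growth-law fitting, cube-root scaling collapse and process
    regime classification; drug loading, encapsulation efficiency and
    cumulative release metrics. A seeded synthetic-data module generates
    ground-truthed micrographs, growth datasets and a constant-kernel
    aggregation oracle so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    withr,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
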