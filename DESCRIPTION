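Package: auxmem
Title: Auxiliary-Network Memory Rescue in Hopfield Associative Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates memory retrieval in binary Hopfield associative
    networks coupled to a smaller, pre-trained auxiliary network through
    sparse random interfaces. Provides Hebbian outer-product learning,
    sign-threshold attractor dynamics with energy diagnostics, optimized
    and non-optimized binary memory-set construction, staged calibration
    of the auxiliary network, random connectivity damage (virtual
    lesions), staged memory-recovery protocols, and reproducible
    parameter sweeps over noise, damage, interface density and auxiliary
    size, with tidy results and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
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
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
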