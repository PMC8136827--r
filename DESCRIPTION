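Package: scarcall
Title: Break-Anchored Classification of Cas9 Double-Strand-Break Repair Scars
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Marker-free classification of DNA double-strand-break repair
    outcomes at Cas9-targeted loci from paired-end amplicon sequencing.
    Consensus reads are decomposed at the declared cut site by iterative
    k-mer flank matching into left deletion, right deletion, microhomology
    and insertion, then binned into repair pathways (NHEJ, non-microhomology
    end joining, polymerase-theta-mediated end joining, insertions, and
    donor-templated homologous recombination). Includes frequency
    tabulation, Pol theta-dependency ratios, scar-spectrum plots, droplet
    digital PCR Poisson quantification of signature repair products, and a
    seeded synthetic scarred-read generator with ground-truth manifests.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    Biostrings,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
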