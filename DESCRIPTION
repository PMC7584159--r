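Package: invarch
Title: Reconstruction of Chromosomal Inversion Breakpoint Architecture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates chromosomal inversion formation under mechanistic
    models (non-allelic homologous recombination, clean and staggered-break
    non-homologous end joining, in-trans repair across homologous
    chromosomes, and replication-based repair with microhomology-templated
    filler), and provides the matching inference chain: anchor-based
    conserved-synteny scanning to localize breakpoints as interrupted-synteny
    loci, comparative-alignment demarcation of breakpoint segments,
    reconstruction of junction architecture (duplication pairs,
    microinversions, central deletions, spacer haplotype mosaics, filler DNA
    with microhomology), and classification of the formation mechanism from
    the recovered evidence. Companion scanners cover non-B DNA-forming
    motifs (inverted, mirror and tandem repeats, Z-DNA, G-quadruplex,
    A-phased tracts), position-weight-matrix binding-site prediction with
    exact p-values, and small molecular-evolution statistics (identity
    excluding indels, Tajima's relative-rate test, effective number of
    codons, concerted-evolution patterns).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
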