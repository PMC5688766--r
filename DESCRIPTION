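Package: karyograph
Title: Cancer Karyotype Reconstruction from Copy Number and Breakpoint Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs rearranged cancer karyotypes from segmental
    copy-number profiles and novel adjacencies ("bridges") supported by
    discordant paired-end reads. Builds a directed weighted bridge graph
    over interval extremities, solves an integer linear program that
    minimizes a length-weighted copy-number discordance plus a penalty
    for unused bridges, and decomposes the optimal edge multiplicities
    into alternating telomere-to-telomere paths, i.e. chromosomes of the
    inferred karyotype. Includes a structural-variant simulator
    (deletions, inversions, tandem duplications, translocations with
    Gaussian copy-number noise and exponentially distributed bridge
    support), five solution-quality measures, benchmark drivers for
    simulation studies, plain-text interchange formats (BED/BEDPE-like)
    and Graphviz DOT export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
SystemRequirements: Python (>= 3.8) with scipy (>= 1.9) on the PATH as
    'python' (used by the mixed-integer programming backend)
Config/testthat/edition: 3
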