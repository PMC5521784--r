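Package: anaerobenet
Title: Microbial Interaction Network Inference for Anaerobic Digesters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers signed, confidence-filtered microbial interaction
    networks from family-level 16S rRNA relative-abundance time series of
    anaerobic (biogas) digesters. Provides fold-change differential-abundance
    calling between mesophilic and thermophilic conditions, discrete-time
    generalized Lotka-Volterra interaction inference fitted per target taxon
    by NIPALS partial-least-squares regression, a resampling consensus filter
    that retains only interactions with a coherent sign across networks
    re-inferred under random subsets of non-pathway taxa, directed-network
    topology summaries (in-degree, betweenness, eigenvector centrality), and
    concordance evaluation of inferred interaction strengths against
    metabolic complementarity and competition indices. A generalized
    Lotka-Volterra simulator generates compositional two-condition study
    fixtures with planted differential taxa so the whole pipeline is testable
    without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
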