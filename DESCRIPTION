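Package: ubnexus
Title: Multi-Evidence Nomination of Ubiquitin-Ligase Substrates and
    Downstream Interactome Perturbation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for nominating candidate substrates of an SCF-family
    ubiquitin ligase from three orthogonal evidence streams (diGly
    ubiquitylome fold changes, G-test enrichment of co-immunoprecipitation
    spectral counts, and a context-dependent CRISPR colony screen), and for
    quantifying the perturbation of the resulting protein interaction
    network in a label-free quantitative proteome (differential abundance,
    clustering, network fold-change projection, and permutation-based gene
    set enrichment).  Downstream consequences are quantified through exon
    inclusion (PSI) analysis of junction counts and through nuclear image
    morphometry (object circularity, Feret aspect ratio, compartmental
    colocalization).  Every input stream can be generated synthetically
    with planted ground truth, so the full pipeline is testable end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    jsonlite,
    igraph,
    EBImage,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    fgsea
Config/testthat/edition: 3
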