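Package: spectrotype
Title: Phylotype and Chemotype Analysis of Bacterial Isolates from
    MALDI-TOF Mass Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to analyse culturable-microbiome isolate collections
    profiled by intact-cell MALDI-TOF mass spectrometry in two acquisition
    modes: linear-mode protein spectra (4-20 kDa) and reflectron-mode
    small-molecule spectra (< 2 kDa). Raw spectra are peak-picked
    (Savitzky-Golay smoothing, SNIP baseline, SNR thresholding), merged
    across biological replicates into consensus peak sets, and binned into
    isolate-by-feature matrices. Protein-spectrum cosine similarity feeds
    Ward hierarchical clustering into pseudo-phylogenetic dendrograms;
    a cut-height sweep tallies, per cut, whether each phylotype group
    contains isolates from one source host or both, with the group-level
    "both" proportion equal to the Jaccard index of the two hosts' group
    sets. Small-molecule features build bipartite metabolite association
    networks, and per-group Pearson correlations quantify the
    phylotype-chemotype relationship. A seeded synthetic-spectra generator
    with planted taxonomy supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    igraph,
    signal,
    yaml,
    jsonlite,
    mzR,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    ape,
    vegan,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
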