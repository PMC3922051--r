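Package: brine18s
Title: Eukaryotic 18S rRNA Amplicon Analysis for Brine-Pool and Cold-Seep Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis pipeline for barcoded 454-style 18S rRNA gene amplicon
    surveys of extreme marine habitats (brine pools, brine-seawater interfaces,
    cold-seep sediments and microbial mats). Provides a synthetic amplicon
    generator with per-read ground truth; demultiplexing and quality control
    including a mismatch-tolerant internal-probe screen that removes
    false-positive (non-rRNA) amplicons; greedy centroid OTU clustering at
    arbitrary dissimilarity levels; rarefied diversity summaries (Shannon,
    Chao1, Good's coverage); de novo phylogeny-based clade classification of
    OTU representatives against a kingdom-labelled reference panel via
    progressive alignment, Jukes-Cantor distances, neighbor joining and
    bootstrap supports; and Bray-Curtis ordination of the resulting clade
    abundance profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    cluster,
    phangorn,
    Rcpp,
    stats,
    tools,
    utils,
    vegan
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
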