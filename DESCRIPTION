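Package: ffasc
Title: Proteome-Based Screening of Cyanobacteria for Free-Fatty-Acid Production Potential
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores and ranks bacterial strains (originally cyanobacteria) for
    their natural potential to produce and excrete free fatty acids, based on
    homology hits of their predicted proteomes against a curated catalog of
    orthologous groups (OGs) known to affect fatty-acid production. Parses
    BLAST tabular and HMMER domtblout search output, applies e-value and
    domain-completeness filters, builds species-by-OG hit-count matrices,
    quantifies category-based criteria (negative, positive and required OGs),
    computes weighted scores with criterion weights fitted by a constrained
    generalized pattern search against reference strains, and validates
    rankings with k-means cluster-number selection (silhouette and
    Calinski-Harabasz indices) and rank-correlation heatmap ordering. A
    synthetic-fixture generator with decoy hits supports fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
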