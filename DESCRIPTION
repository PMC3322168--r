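Package: speechgraph
Title: Speech Graph Analysis of Thought Disorder
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Converts annotated speech transcripts into directed word
    multigraphs and quantifies thought disorder through fourteen graph
    measures (node and edge counts, connectivity, recurrence via traces of
    adjacency-matrix powers, topic-deviation counts, density, diameter and
    average shortest path), raw and word-normalized.  Provides nonparametric
    group comparisons (Kruskal-Wallis, Wilcoxon rank-sum, Bonferroni),
    Spearman correlations against psychometric scales, and cross-validated
    naive Bayes classification with ROC/AUC, sensitivity/specificity and
    Cohen's kappa.  A seeded synthetic transcript generator emulates
    group-conditioned speech signatures (logorrhea, poor speech, recurrence,
    flight of thoughts) so the full pipeline is testable without clinical
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    e1071,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
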