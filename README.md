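# speechgraph

Quantitative analysis of thought disorder from speech structure alone.

Psychiatric interviews produce speech whose *organization* — not its
content — carries diagnostic signal: mania brings logorrhea and recurrent,
tangential discourse ("flight of thoughts"), while schizophrenia brings
short, non-recurrent speech. `speechgraph` operationalizes this by turning
a transcript into a directed multigraph **G = (N, E)**: each canonical
word form (lexeme) is a node, and each temporal transition between
consecutive elements is a directed edge, with self-loops and parallel
edges preserved. Elements are annotated as belonging to the *anchor topic*
(e.g. the dream a subject was asked to report) or as *deviations* from it.

From each graph the package computes fourteen measures, raw and divided by
the report's word count:

| class | measures |
|---|---|
| general | N (nodes), E (edges) |
| connectivity | ATD = mean(k_in + k_out) = 2E/N, LCC, LSC |
| recurrence | PE (parallel edges), L1 = tr(A), L2 = tr(A²), L3 = tr(A³) |
| topic deviation | WN, WE (deviation nodes/edges), plus WN/N and WE/E |
| global | D = E′/N² with E′ = E − (L1 + PE), DI (diameter), ASP |

where **A** is the integer multiplicity adjacency matrix, so L1–L3 count
closed walks of length 1–3 exactly. Groups are compared with
Kruskal–Wallis followed by pairwise Wilcoxon rank-sum tests under
Bonferroni correction (three groups: corrected α displayed as 0.0166), and
diagnostic pairs are separated by a cross-validated Gaussian naive Bayes
classifier reported with ROC/AUC, sensitivity/specificity and Cohen's κ.
A seeded generator of group-conditioned synthetic transcripts makes every
stage testable without clinical recordings.

Intended users: researchers in computational psychiatry and quantitative
linguistics working with annotated interview transcripts.

## Worked example

The classic worked example — a dream report whose last clause ("I woke
up") deviates from the anchor topic:

```r
library(speechgraph)
t <- parse_transcript("I walked / I found / I hugged / [ I woke ]")
m <- speech_measures(t)
round(unlist(m[c("N","E","ATD","LCC","LSC","PE","L1","L2","L3","WN","WE","D","DI","ASP")]), 3)
#>    N    E  ATD  LCC  LSC   PE   L1   L2   L3   WN   WE    D   DI  ASP
#> 5.00 7.00 2.80 5.00 4.00 0.00 0.00 6.00 0.00 2.00 2.00 0.28 2.00 1.60
```

Five distinct lexemes joined by seven transitions; ATD = 2·7/5 = 2.8; all
five nodes are mutually linked ignoring direction (LCC = 5) but "woke" has
no outgoing edge (LSC = 4); the three I↔verb round trips give six closed
2-walks (L2 = 6); two nodes and two edges touch the deviation span
(WN = WE = 2); density is 7/25 and the undirected star has diameter 2 with
mean shortest path 1.6.

A full synthetic study, end to end:

```r
corpus <- generate_cohort(n_per_group = 8, seed = 42)   # 24 subjects
tab    <- measure_table(corpus)
run_comparison(tab, "SxM")   # schizophrenic-like vs manic-like
#> <classifier_report> SxM (gaussian_nb, loo CV)
#>   features: N_per_word, E_per_word, ATD_per_word
#>   AUC = 1.000  sensitivity = 1.000  specificity = 1.000  kappa = 1.000
```

The default synthetic profiles are deliberately well separated on the
normalized N/E/ATD features, so the leave-one-out naive Bayes classifier
achieves a perfect ranking here; on uninformative features the same
machinery stays at chance (AUC ≈ 0.5). A command-line interface over the
same functions is installed at `inst/cli/speechgraph.R`
(`simulate` / `measure` / `compare` / `classify` subcommands).

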