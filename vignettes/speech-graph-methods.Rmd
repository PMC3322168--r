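---
title: "Speech graphs as a quantitative measure of thought disorder: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Speech graphs: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speechgraph)
```

## The model

A transcript is an ordered sequence of canonical grammatical elements
(lexemes), each labeled as belonging to the **anchor topic** the speaker
was asked to address, or as a **deviation** from it. The speech graph is
the directed multigraph G = (N, E) with one node per distinct lexeme and
one edge per temporal transition between consecutive elements. Nothing
semantic enters the representation: two transcripts with the same
word-transition structure get the same graph, and every measure is
invariant under renaming lexemes by a bijection.

Keeping the multigraph structure is essential. Self-loops (immediate
repetition) and parallel edges (re-used transitions) are exactly the
recurrence phenomena of disorganized speech, so the adjacency matrix `A`
holds integer multiplicities, and the loop measures are implemented
literally as traces of matrix powers: L1 = tr(A), L2 = tr(A²),
L3 = tr(A³), i.e. counts of closed walks of length 1–3 in which
multiplicities multiply and self-loops contribute at every length.
Whether a binary adjacency would be preferable is not decidable from the
measure definitions alone; the multiplicity reading is the literal one and
is what this package computes (a binary variant is available by building
the graph from the simplified view).

Parallel edges are counted per *ordered* pair: PE = Σ over i ≠ j of
max(0, A[i,j] − 1). This direction-sensitive convention is forced by the
density formula D = E′/N² with E′ = E − (L1 + PE): only then does E′ equal
the edge count of the directed simple graph, keeping D within [0, 1].

The global measures work on simplified views: LCC on the undirected
simple graph, LSC on the directed simple graph, diameter and average
shortest path on the undirected simple graph via breadth-first search.
For disconnected graphs, DI and ASP are taken over node pairs at finite
distance only; when no such pair exists (one node, or self-loops only)
they are reported as missing, never imputed as zero, and excluded
pairwise from downstream statistics. Restricting instead to the largest
component was the other defensible option; finite-pair inclusion uses
more of the data and degrades gracefully as graphs fragment.

### Deviation labeling of edges

An element is anchor or deviation; an edge spans two elements, and the
boundary edge (anchor → deviation) is precisely the moment the speaker
abandons the topic. The package therefore flags an edge as deviation when
**either** endpoint element is a deviation — the flight-of-thought
transition itself counts. This is a documented convention, switchable to
`"source"` or `"target"` via `build_graph(deviation_edges = )`, since the
boundary attribution cannot be pinned down from the measure definitions.
Under `"either"`, the worked example
`"I walked / I found / I hugged / [ I woke ]"` has WN = 2 and WE = 2.

### Words versus elements

Raw word count and element count are different quantities: elements are
parsed lexemes, words are raw tokens of the original report. Word count
supplied in metadata wins over the computed fallback, because counts may
come from the original recording. All fourteen measures are also reported
divided by word count (`_per_word`), which discounts sheer verbosity —
the normalization that separates pathological structure from logorrhea.

## Statistics

Group differences use Kruskal–Wallis across all groups followed by
pairwise two-sided Wilcoxon rank-sum tests; a pairwise difference is
flagged only when the omnibus p < 0.05 and the pairwise p clears the
Bonferroni-corrected threshold α/(number of pairs), displayed truncated
(not rounded) to four decimals — 0.0166 for three groups at α = 0.05.
The rank-sum test uses the exact permutation distribution when both
samples have n ≤ 10 and the pooled data are tie-free — at the study-sized
n = 8 per group the normal approximation is unnecessarily coarse — and
otherwise the tie-corrected normal approximation with continuity
correction; the method used is recorded in the output. P-values from
different tie/approximation conventions agree qualitatively (significant
or not at the stated α) rather than digit-for-digit, and that is the only
level at which they should be compared. Spearman correlations against
psychometric scale totals (BPRS/PANSS) use tie-corrected ranks with the
t-approximation, after pairwise deletion.

## Classification

The native classifier is Gaussian naive Bayes: per class, each feature
gets an independent normal density estimated from the training rows, with
each standard deviation floored at 10⁻⁶ × (global feature sd, or 1 if
that is zero) so a constant feature cannot produce a degenerate density.
Posteriors are computed in log space and normalized over classes.
Features default to the interpretation-free word-normalized subsets that
best separate each pair: N, E, ATD for schizophrenic vs manic; N, L1, L2
for schizophrenic vs control; L1, L2, L3 for manic vs control. WN and WE
are never used as classifier inputs, since labeling deviations requires
interpreting meaning.

Cross-validation defaults to leave-one-out, the scheme that makes full
use of 8-per-group samples; stratified k-fold with a recorded seed is
available. One numerical subtlety matters here: under leave-one-out on a
balanced cohort, class priors estimated per training fold always
disfavour the held-out subject's class (its fold is one subject short),
which drags AUC on label-independent data visibly below 0.5. The default
cross-validated classifier therefore fixes the priors at the whole-cohort
class frequencies, constant across folds; with that choice, chance-level
features yield mean AUC ≈ 0.475 across seeded replicates, within the
expected [0.45, 0.55] band. `nb_fit()` itself keeps training-frequency
priors as its default, and both behaviors are selectable via the `priors`
argument.

ROC curves come from a threshold sweep over the distinct score values
(ties grouped into one step), AUC by the trapezoid rule — provably equal
to the Mann–Whitney pairwise-win fraction, which the test suite checks by
enumeration. Sensitivity and specificity are reported at the posterior
0.5 operating point, a choice the package makes explicit because no
canonical operating point exists for these data. Cohen's κ compares the
thresholded predictions with the clinical labels; κ ≈ 0.6 is conventional
"good" agreement. Any classifier implementing the two-function contract
(`fit(x, labels)`, `score(model, x)` → [0, 1]) can be plugged into the
same battery, which is how external SVM/tree/net implementations are
compared without re-implementing them.

## The synthetic generator

The generator is a lexicon-growing random walk, not a language model: it
controls exactly the graph-level quantities the measures read out, with
no linguistic pretense. Per element it chooses between introducing a
fresh lexeme (probability `p_new`), re-traversing an already-used
outgoing transition of the current lexeme (`p_retrace`, the source of
parallel edges and loops; falls back to a fresh lexeme when none exists),
or jumping to a uniformly chosen known lexeme. Deviation spans open per
element with probability `p_deviate` and have geometric lengths with mean
`deviation_run`. Report length is negative-binomial. In synthetic mode
each element is one word, so `word_count` equals the element count and
normalized measures remain comparable.

The three default profiles encode the qualitative group signatures with
values chosen once:

| profile | mean_words | p_new | p_retrace | p_deviate | deviation_run | subject_sd |
|---|---|---|---|---|---|---|
| schizophrenic-like | 45 | 0.55 | 0.04 | 0.01 | 2 | 0.15 |
| manic-like | 130 | 0.22 | 0.38 | 0.06 | 4 | 0.15 |
| control-like | 85 | 0.38 | 0.18 | 0.03 | 3 | 0.50 |

Short, high-novelty, non-recurrent reports for the schizophrenic-like
profile; long, recurrent, topic-abandoning reports for the manic-like
one; intermediate means with strongly inflated between-subject dispersion
(`subject_sd`, applied on the log/logit scale per subject) for controls,
whose defining feature is wide inter-individual variability. The grand
mean report length (≈ 87 words) matches the ~84 words per report typical
of anchor-topic interviews. With these defaults, manic-like cohorts
exceed schizophrenic-like ones on median PE and WE per word while the
schizophrenic-like exceed on N and ATD per word — the directionality the
acceptance suite verifies over 100 seeded replicates at n = 20 per group.

What the generator does **not** emulate: morphology, semantics, realistic
lexicon sizes, interviewer turns, or the absolute measure values of any
clinical population. Passing tests on synthetic cohorts demonstrate that
the pipeline recovers the structural signatures it was pointed at — they
say nothing about effect sizes in real clinical data, and the
classification AUC on the deliberately well-separated default profiles
(≈ 0.99) should be read as a pipeline check, not a clinical claim.

## Problem sizes and determinism

Every stochastic path is seeded: cohort generation seeds once per cohort,
cross-validation records its seed in the report, and the full
simulate → measure → compare → classify pipeline is reproducible bit for
bit from one seed. Calibration summaries in the test and acceptance
suites use 50 replicate null cohorts and 10–100 synthetic cohorts at 20
subjects per group — sizes at which the binomial noise of an AUC or a
median comparison is comfortably inside the stated bands while the whole
battery runs in seconds.

## Known limitations

- Transcripts must arrive pre-parsed into elements; no speech-to-text,
  grammatical parsing or lemmatization is attempted (lexemization is
  table-driven with a lowercase-identity default).
- Binary comparisons only; no multiclass classification or
  hyperparameter search.
- No weighted or semantic edges, and no moving-window graph analysis.
- The exact-vs-approximate rank-sum switch makes p-values near the n = 10
  boundary method-dependent at the third decimal; conclusions should rest
  on the stated α levels, not digits.
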