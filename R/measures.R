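#' Average total degree
#'
#' Mean over nodes of in-degree plus out-degree with multiplicities
#' counted; equals 2E/N exactly (multigraph handshake lemma).
#'
#' @param g A `speech_graph`.
#' @return Numeric.
#' @export
average_total_degree <- function(g) 2 * nrow(g$edges) / length(g$nodes)

#' Largest connected component (nodes)
#'
#' Node count of the largest component of the undirected simple view.
#' A node whose only edges are self-loops is its own component of size 1.
#'
#' @param g A `speech_graph`.
#' @return Integer.
#' @export
largest_connected_component <- function(g) {
  ig <- as_igraph(g, simple = TRUE, directed = FALSE)
  max(igraph::components(ig)$csize)
}

#' Largest strongly connected component (nodes)
#'
#' Node count of the largest set of mutually reachable nodes in the
#' directed simple view; singleton components allowed.
#'
#' @param g A `speech_graph`.
#' @return Integer.
#' @export
largest_strongly_connected_component <- function(g) {
  ig <- as_igraph(g, simple = TRUE, directed = TRUE)
  max(igraph::components(ig, mode = "strong")$csize)
}

#' Parallel edges
#'
#' Excess multiplicity summed over ordered node pairs i != j:
#' `sum(max(0, A[i,j] - 1))`.  Self-loop multiplicities are excluded (they
#' belong to L1).  Direction-sensitive, so that `E - L1 - PE` equals the
#' edge count of the directed simple view and density stays in \[0, 1\].
#'
#' @param g A `speech_graph`.
#' @return Integer.
#' @export
parallel_edges <- function(g) {
  A <- adjacency_matrix(g)
  diag(A) <- 0L
  sum(pmax(A - 1L, 0L))
}

#' Loops of length 1, 2 or 3
#'
#' Closed walks of length k, computed literally as the trace of the k-th
#' power of the integer multiplicity adjacency matrix.  Multiplicities
#' multiply, and self-loops contribute to all three counts.
#'
#' @param g A `speech_graph`.
#' @param k Walk length: 1, 2 or 3.
#' @return Integer.
#' @export
count_loops <- function(g, k) {
  stopifnot(k %in% 1:3)
  A <- adjacency_matrix(g)
  Ak <- A
  if (k >= 2) Ak <- Ak %*% A
  if (k == 3) Ak <- Ak %*% A
  sum(diag(Ak))
}

#' Deviation (waking) node and edge counts
#'
#' WN = nodes with at least one element instance inside a deviation span;
#' WE = edges flagged as deviation under the graph's edge convention.
#'
#' @param g A `speech_graph`.
#' @return Named numeric vector `c(WN = , WE = )`.
#' @export
waking_counts <- function(g) {
  c(WN = sum(g$node_segments$in_deviation), WE = sum(g$edges$deviation))
}

#' Graph density
#'
#' D = E'/N^2 with E' = E - (L1 + PE).  By the PE and L1 conventions E'
#' equals the edge count of the directed simple view, hence 0 <= D <= 1.
#'
#' @param g A `speech_graph`.
#' @return Numeric in \[0, 1\].
#' @export
graph_density <- function(g) {
  N <- length(g$nodes)
  Ep <- nrow(g$edges) - count_loops(g, 1) - parallel_edges(g)
  Ep / N^2
}

#' Diameter and average shortest path
#'
#' Breadth-first all-pairs shortest paths on the undirected simple view.
#' DI is the longest and ASP the mean shortest path over unordered node
#' pairs at finite distance; pairs in different components are excluded
#' from both.  With a single node or no finite pair both are `NA`
#' (reported as missing, never imputed as zero).
#'
#' @param g A `speech_graph`.
#' @return Named numeric vector `c(DI = , ASP = )`.
#' @export
diameter_asp <- function(g) {
  if (length(g$nodes) < 2L) return(c(DI = NA_real_, ASP = NA_real_))
  ig <- as_igraph(g, simple = TRUE, directed = FALSE)
  d <- igraph::distances(ig)
  d <- d[upper.tri(d)]
  d <- d[is.finite(d)]
  if (!length(d)) return(c(DI = NA_real_, ASP = NA_real_))
  c(DI = max(d), ASP = mean(d))
}

MEASURE_NAMES <- c("N", "E", "ATD", "LCC", "LSC", "PE",
                   "L1", "L2", "L3", "WN", "WE", "D", "DI", "ASP")

#' Compute all speech graph measures for one transcript
#'
#' The 14 measures — N, E, ATD, LCC, LSC, PE, L1, L2, L3, WN, WE, D, DI,
#' ASP — their word-normalized variants (each divided by the raw word
#' count, suffix `_per_word`), and the deviation ratios `wn_ratio` = WN/N
#' and `we_ratio` = WE/E.  Undefined values (DI/ASP on degenerate graphs,
#' `we_ratio` when E = 0) propagate as `NA`.
#'
#' @param t A `speech_transcript` (or a prebuilt `speech_graph`).
#' @param deviation_edges Edge deviation convention, see [build_graph()].
#' @return One-row data.frame: `subject_id`, `group`, `word_count`, 14 raw
#'   measures, 14 `_per_word` columns, `wn_ratio`, `we_ratio`.
#' @examples
#' m <- speech_measures(parse_transcript("I walked / I found / I hugged / [ I woke ]"))
#' m[, c("N", "E", "ATD", "L2", "D", "ASP")]
#' @export
speech_measures <- function(t, deviation_edges = "either") {
  g <- if (inherits(t, "speech_graph")) t else build_graph(t, deviation_edges)
  if (is.null(g$word_count) || g$word_count < 1)
    sg_error("InvalidWordCount", "transcript has no positive word_count")
  wk <- waking_counts(g)
  da <- diameter_asp(g)
  raw <- c(N = length(g$nodes), E = nrow(g$edges),
           ATD = average_total_degree(g),
           LCC = largest_connected_component(g),
           LSC = largest_strongly_connected_component(g),
           PE = parallel_edges(g),
           L1 = count_loops(g, 1), L2 = count_loops(g, 2), L3 = count_loops(g, 3),
           WN = unname(wk["WN"]), WE = unname(wk["WE"]),
           D = graph_density(g), DI = unname(da["DI"]), ASP = unname(da["ASP"]))
  norm <- raw / g$word_count
  names(norm) <- paste0(MEASURE_NAMES, "_per_word")
  out <- data.frame(subject_id = g$subject_id, group = g$group,
                    word_count = g$word_count, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(as.list(c(raw, norm))))
  out$wn_ratio <- unname(raw["WN"] / raw["N"])
  out$we_ratio <- if (raw["E"] > 0) unname(raw["WE"] / raw["E"]) else NA_real_
  rownames(out) <- NULL
  out
}

#' Measure table for a corpus
#'
#' One row per subject in corpus (metadata) order, with the full measure
#' vector of [speech_measures()] per transcript.
#'
#' @param corpus A `speech_corpus`.
#' @param deviation_edges Edge deviation convention, see [build_graph()].
#' @return data.frame, one row per subject.
#' @export
measure_table <- function(corpus, deviation_edges = "either") {
  rows <- lapply(corpus$transcripts, speech_measures, deviation_edges = deviation_edges)
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  for (col in c("bprs", "panss"))
    if (!is.null(corpus$metadata[[col]]) && !all(is.na(corpus$metadata[[col]])))
      tab[[col]] <- corpus$metadata[[col]][match(tab$subject_id, corpus$metadata$subject_id)]
  tab
}
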