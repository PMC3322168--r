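#' Build the directed speech multigraph from a transcript
#'
#' One node per distinct lexeme; for each consecutive pair of elements one
#' directed edge in utterance order, sequence-numbered 1..E.  Self-loops
#' (immediate word repetition) and parallel edges (repeated transitions)
#' are preserved — the graph is a true multigraph.  An edge is flagged as
#' deviation according to `deviation_edges`: with the default `"either"`,
#' an edge is a deviation edge iff at least one endpoint element lies in a
#' deviation span, so the transition out of the anchor topic — the
#' flight-of-thought event itself — counts as deviation.  `"source"` and
#' `"target"` flag by one endpoint only.
#'
#' @param t A `speech_transcript`.
#' @param deviation_edges Edge deviation convention: `"either"` (default),
#'   `"source"` or `"target"`.
#' @return A `speech_graph`: list with `nodes` (lexemes in first-appearance
#'   order), `edges` (data.frame `source`, `target`, `sequence`,
#'   `deviation`), `node_segments` (per node, whether any instance is
#'   anchor / deviation), `word_count`, `subject_id`, `group`.
#' @examples
#' g <- build_graph(parse_transcript("I walked / I found / I hugged / [ I woke ]"))
#' length(g$nodes)   # 5
#' nrow(g$edges)     # 7
#' @export
build_graph <- function(t, deviation_edges = c("either", "source", "target")) {
  deviation_edges <- match.arg(deviation_edges)
  stopifnot(inherits(t, "speech_transcript"))
  lex <- t$elements$lexeme
  dev <- t$elements$segment == "deviation"
  nodes <- unique(lex)

  n <- length(lex)
  if (n >= 2L) {
    src <- lex[-n]
    tgt <- lex[-1L]
    edev <- switch(deviation_edges,
                   either = dev[-n] | dev[-1L],
                   source = dev[-n],
                   target = dev[-1L])
    edges <- data.frame(source = src, target = tgt,
                        sequence = seq_len(n - 1L), deviation = edev,
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(source = character(0), target = character(0),
                        sequence = integer(0), deviation = logical(0))
  }
  node_segments <- data.frame(
    lexeme = nodes,
    in_anchor = vapply(nodes, function(w) any(!dev[lex == w]), logical(1)),
    in_deviation = vapply(nodes, function(w) any(dev[lex == w]), logical(1)),
    row.names = NULL, stringsAsFactors = FALSE)

  structure(list(nodes = nodes, edges = edges, node_segments = node_segments,
                 word_count = t$word_count, subject_id = t$subject_id,
                 group = t$group),
            class = "speech_graph")
}

#' @export
print.speech_graph <- function(x, ...) {
  cat(sprintf("<speech_graph> subject=%s N=%d E=%d (%d deviation edges)\n",
              x$subject_id, length(x$nodes), nrow(x$edges), sum(x$edges$deviation)))
  invisible(x)
}

#' Integer multiplicity adjacency matrix of a speech graph
#'
#' `A[i, j]` is the number of edges i -> j, rows/columns indexed by the
#' nodes in first-appearance order (deterministic, so sequence numbering
#' is reproducible).  The sum of all entries equals E.
#'
#' @param g A `speech_graph`.
#' @return Square integer matrix with node dimnames.
#' @export
adjacency_matrix <- function(g) {
  n <- length(g$nodes)
  A <- matrix(0L, n, n, dimnames = list(g$nodes, g$nodes))
  if (nrow(g$edges)) {
    idx <- cbind(match(g$edges$source, g$nodes), match(g$edges$target, g$nodes))
    for (k in seq_len(nrow(idx)))
      A[idx[k, 1L], idx[k, 2L]] <- A[idx[k, 1L], idx[k, 2L]] + 1L
  }
  A
}

#' Simple view of a speech graph
#'
#' Removes self-loops and collapses multi-edges to one.  With
#' `directed = FALSE` the ordered pairs (i, j) and (j, i) merge into one
#' unordered pair.  Nodes are kept even when all their edges are removed
#' (a node with only self-loops is its own component of size 1).
#'
#' @param g A `speech_graph`.
#' @param directed Keep edge direction?
#' @return List with `nodes` and `edges` (data.frame `source`, `target`).
#' @export
simplify_graph <- function(g, directed = TRUE) {
  e <- g$edges[g$edges$source != g$edges$target, c("source", "target"), drop = FALSE]
  if (!directed && nrow(e)) {
    a <- pmin(e$source, e$target)
    b <- pmax(e$source, e$target)
    e <- data.frame(source = a, target = b, stringsAsFactors = FALSE)
  }
  e <- unique(e)
  rownames(e) <- NULL
  list(nodes = g$nodes, edges = e)
}

#' Convert a speech graph to an igraph object
#'
#' The full multigraph by default (self-loops and parallel edges kept,
#' with `sequence` and `deviation` edge attributes); set `simple = TRUE`
#' for the simple view used by the global measures.
#'
#' @param g A `speech_graph`.
#' @param simple Collapse to the simple view first?
#' @param directed Edge direction (applies to either view).
#' @return An `igraph` graph.
#' @export
as_igraph <- function(g, simple = FALSE, directed = TRUE) {
  if (simple) {
    s <- simplify_graph(g, directed = directed)
    ig <- igraph::graph_from_data_frame(s$edges, directed = directed,
                                        vertices = data.frame(name = s$nodes))
  } else {
    verts <- g$node_segments
    names(verts)[names(verts) == "lexeme"] <- "name"
    ig <- igraph::graph_from_data_frame(g$edges, directed = directed,
                                        vertices = verts)
  }
  ig
}

#' Export a speech graph to GraphML
#'
#' Nodes carry `lexeme` and `appears_in_deviation`; edges carry `sequence`
#' and `deviation`.
#'
#' @param g A `speech_graph`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(g, path) {
  ig <- as_igraph(g)
  igraph::V(ig)$lexeme <- igraph::V(ig)$name
  igraph::V(ig)$appears_in_deviation <- g$node_segments$in_deviation[
    match(igraph::V(ig)$name, g$node_segments$lexeme)]
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

#' Export a speech graph as an edge-list CSV
#'
#' Columns `source`, `target`, `sequence`, `deviation`.
#'
#' @param g A `speech_graph`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(g, path) {
  utils::write.csv(g$edges, path, row.names = FALSE)
  invisible(path)
}
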