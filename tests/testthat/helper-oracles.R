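# Independent brute-force oracles and fixture builders.  Everything here
# works directly on element sequences / edge lists, never through the
# package's adjacency-matrix or igraph paths.

DREAM_EXAMPLE <- "I walked / I found / I hugged / [ I woke ]"

# transcript from a bare element sequence (all anchor unless dev = TRUE)
seq_transcript <- function(lexemes, dev = rep(FALSE, length(lexemes)),
                           word_count = length(lexemes)) {
  n <- length(lexemes)
  t <- parse_transcript(paste(ifelse(dev, paste("[", lexemes, "]"), lexemes),
                              collapse = " / "),
                        word_count = word_count)
  stopifnot(nrow(t$elements) == n)
  t
}

# random element sequence: small alphabet so self-loops / parallels occur
random_sequence <- function(n_nodes, len) {
  letters[sample.int(n_nodes, len, replace = TRUE)]
}

# edge list (from, to) of consecutive pairs in a sequence
seq_edges <- function(lexemes) {
  n <- length(lexemes)
  if (n < 2) return(cbind(from = character(0), to = character(0)))
  cbind(from = lexemes[-n], to = lexemes[-1])
}

# closed k-walk count by explicit enumeration over edge instances
oracle_loops <- function(edges, k) {
  m <- nrow(edges)
  if (m == 0) return(0)
  count <- 0
  if (k == 1) return(sum(edges[, "from"] == edges[, "to"]))
  if (k == 2) {
    for (i in seq_len(m)) for (j in seq_len(m))
      if (edges[i, "to"] == edges[j, "from"] && edges[j, "to"] == edges[i, "from"])
        count <- count + 1
    return(count)
  }
  for (i in seq_len(m)) for (j in seq_len(m)) for (l in seq_len(m))
    if (edges[i, "to"] == edges[j, "from"] && edges[j, "to"] == edges[l, "from"] &&
        edges[l, "to"] == edges[i, "from"])
      count <- count + 1
  count
}

# all-pairs shortest paths on the undirected simple view, Floyd-Warshall
oracle_distances <- function(lexemes) {
  nodes <- unique(lexemes)
  n <- length(nodes)
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(d) <- 0
  e <- seq_edges(lexemes)
  for (i in seq_len(nrow(e))) {
    a <- e[i, "from"]; b <- e[i, "to"]
    if (a != b) d[a, b] <- d[b, a] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# largest component sizes by reachability closure (Warshall)
oracle_components <- function(lexemes, strong = FALSE) {
  nodes <- unique(lexemes)
  n <- length(nodes)
  r <- diag(n) > 0
  dimnames(r) <- list(nodes, nodes)
  e <- seq_edges(lexemes)
  for (i in seq_len(nrow(e))) {
    a <- e[i, "from"]; b <- e[i, "to"]
    if (a != b) {
      r[a, b] <- TRUE
      if (!strong) r[b, a] <- TRUE
    }
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (r[i, k] && r[k, j]) r[i, j] <- TRUE
  same <- r & t(r)
  max(rowSums(same))
}

# AUC as the Mann-Whitney pairwise-win fraction over all (+, -) pairs
oracle_auc <- function(scores, positive) {
  sp <- scores[positive]
  sn <- scores[!positive]
  wins <- 0
  for (a in sp) for (b in sn) wins <- wins + (a > b) + 0.5 * (a == b)
  wins / (length(sp) * length(sn))
}
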