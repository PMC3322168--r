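example_graph <- function() build_graph(parse_transcript(DREAM_EXAMPLE))

test_that("degree, component and recurrence measures match hand-derived values", {
  g <- example_graph()
  expect_equal(average_total_degree(g), 2.8)
  expect_equal(largest_connected_component(g), 5)
  expect_equal(largest_strongly_connected_component(g), 4)
  expect_equal(parallel_edges(g), 0)
  expect_equal(count_loops(g, 1), 0)
  expect_equal(count_loops(g, 2), 6)
  expect_equal(count_loops(g, 3), 0)
  expect_equal(waking_counts(g), c(WN = 2, WE = 2))
  expect_equal(graph_density(g), 0.28)
  expect_equal(diameter_asp(g), c(DI = 2, ASP = 1.6))

  tri <- build_graph(seq_transcript(c("a", "b", "c", "a")))
  expect_equal(average_total_degree(tri), 2)
  expect_equal(largest_strongly_connected_component(tri), 3)
  expect_equal(count_loops(tri, 3), 3)
  expect_equal(graph_density(tri), 3 / 9)
  expect_equal(diameter_asp(tri), c(DI = 1, ASP = 1))

  chain <- build_graph(seq_transcript(c("a", "b", "c")))
  expect_equal(largest_strongly_connected_component(chain), 1)
  expect_equal(diameter_asp(chain), c(DI = 2, ASP = 4 / 3))

  self <- build_graph(seq_transcript(c("a", "a")))
  expect_equal(average_total_degree(self), 2)
  expect_equal(count_loops(self, 1), 1)
  expect_equal(count_loops(self, 2), 1)
  expect_equal(count_loops(self, 3), 1)
  expect_equal(graph_density(self), 0)      # E' = 1 - 1 = 0
  expect_equal(largest_connected_component(self), 1)

  ab <- build_graph(seq_transcript(c("a", "b", "a", "b")))
  expect_equal(parallel_edges(ab), 1)       # one excess a->b
  abc <- build_graph(seq_transcript(c("a", "b", "a", "b", "a", "b")))
  expect_equal(parallel_edges(abc), 3)      # A[a,b]=3, A[b,a]=2
})

test_that("loop counts equal brute-force closed-walk enumeration", {
  set.seed(21)
  for (i in 1:40) {
    lex <- random_sequence(sample(2:6, 1), sample(3:13, 1))  # E <= 12
    g <- build_graph(seq_transcript(lex))
    e <- seq_edges(lex)
    for (k in 1:3)
      expect_equal(count_loops(g, k), oracle_loops(e, k),
                   info = paste(lex, collapse = " "))
  }
})

test_that("component sizes and path measures match reachability oracles", {
  set.seed(22)
  for (i in 1:25) {
    lex <- random_sequence(sample(2:6, 1), sample(2:15, 1))
    g <- build_graph(seq_transcript(lex))
    expect_equal(largest_connected_component(g), oracle_components(lex, strong = FALSE))
    expect_equal(largest_strongly_connected_component(g), oracle_components(lex, strong = TRUE))
    d <- oracle_distances(lex)
    d <- d[upper.tri(d)]
    d <- d[is.finite(d)]
    if (length(d))
      expect_equal(diameter_asp(g), c(DI = max(d), ASP = mean(d)))
  }
})

test_that("measure invariants hold on random transcripts", {
  set.seed(23)
  for (i in 1:30) {
    lex <- random_sequence(sample(2:6, 1), sample(2:25, 1))
    dev <- runif(length(lex)) < 0.25
    m <- speech_measures(seq_transcript(lex, dev))
    expect_equal(m$ATD, 2 * m$E / m$N)                 # handshake lemma
    expect_true(m$LSC <= m$LCC && m$LCC <= m$N)
    expect_true(m$WN <= m$N && m$WE <= m$E)
    expect_true(m$D >= 0 && m$D <= 1)
    expect_true(m$L1 + m$PE <= m$E)
    if (!is.na(m$ASP)) expect_true(m$ASP <= m$DI)
  }
})

test_that("measures are invariant under lexeme renaming", {
  set.seed(24)
  for (i in 1:10) {
    lex <- random_sequence(5, 20)
    dev <- runif(20) < 0.2
    renamed <- setNames(paste0("z", 1:5), letters[1:5])[lex]
    m1 <- speech_measures(seq_transcript(lex, dev))
    m2 <- speech_measures(seq_transcript(renamed, dev))
    cols <- setdiff(names(m1), "subject_id")
    expect_equal(m1[cols], m2[cols])
  }
})

test_that("full measure vector carries normalized columns and ratios", {
  t <- parse_transcript(DREAM_EXAMPLE, word_count = 8)
  m <- speech_measures(t)
  expect_equal(m$N_per_word, 5 / 8)
  expect_equal(m$ATD_per_word, 0.35)
  expect_equal(m$wn_ratio, 2 / 5)
  expect_equal(m$we_ratio, 2 / 7)
  # normalized x word_count recovers raw, for every measure
  for (nm in c("N", "E", "ATD", "LCC", "LSC", "PE", "L1", "L2", "L3",
               "WN", "WE", "D", "DI", "ASP"))
    expect_equal(m[[paste0(nm, "_per_word")]] * m$word_count, m[[nm]])

  # degenerate inputs: undefined values stay missing, never zero
  m1 <- speech_measures(seq_transcript("a"))
  expect_true(is.na(m1$DI) && is.na(m1$ASP) && is.na(m1$we_ratio))
  ml <- speech_measures(seq_transcript(c("a", "a")))
  expect_true(is.na(ml$DI))  # single node after simplification
})

test_that("measure table has one row per subject with group metadata", {
  corpus <- generate_cohort(n_per_group = 3, seed = 5)
  tab <- measure_table(corpus)
  expect_equal(nrow(tab), 9L)
  expect_equal(tab$subject_id, corpus$metadata$subject_id)
  expect_equal(tab$group, corpus$metadata$group)
  expect_false(anyNA(tab$N_per_word))
})
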