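test_that("CoNLL-U parsing validates the tree and round-trips", {
  txt <- c("# sent_id = t1", "1\tHello\t_\t_\t_\t_\t0\troot\t_\t_",
           "2\tworld\t_\t_\t_\t_\t1\tdep\t_\t_", "")
  ps <- read_conllu(text = txt)
  expect_named(ps, "t1")
  expect_equal(ps$t1$heads, c(0L, 1L))

  cyc <- c("1\ta\t_\t_\t_\t_\t2\tdep\t_\t_",
           "2\tb\t_\t_\t_\t_\t1\tdep\t_\t_")
  expect_error(read_conllu(text = cyc), "root")
  tworoots <- c("1\ta\t_\t_\t_\t_\t0\troot\t_\t_",
                "2\tb\t_\t_\t_\t_\t0\troot\t_\t_")
  expect_error(read_conllu(text = tworoots), "exactly one root")
  selfcycle <- c("1\ta\t_\t_\t_\t_\t0\troot\t_\t_",
                 "2\tb\t_\t_\t_\t_\t3\tdep\t_\t_",
                 "3\tc\t_\t_\t_\t_\t2\tdep\t_\t_")
  expect_error(read_conllu(text = selfcycle), "cycle")

  p10 <- generate_random_tree(10, words = sprintf("tok%d", 1:10))
  f <- withr::local_tempfile(fileext = ".conllu")
  write_conllu(list(fix = p10), f)
  back <- read_conllu(f)$fix
  expect_equal(back$words, p10$words)
  expect_equal(back$heads, p10$heads)
})

test_that("word-piece alignment handles splits, identity and errors", {
  al <- align_wordpieces(c("tacrine"), c("tac", "##rine"))
  expect_equal(al$word_of_piece, c(1L, 1L))
  expect_equal(al$first_piece_of_word, 1L)

  al2 <- align_wordpieces(c("a", "b"), c("a", "b"))
  expect_equal(al2$word_of_piece, 1:2)

  expect_error(align_wordpieces(c("abc"), c("ab", "##d")), "unalignable")
  expect_error(align_wordpieces(c("ab"), c("ab", "##c")), "trailing pieces")
})

test_that("random subword splits always produce a valid alignment", {
  set.seed(99)
  for (i in 1:200) {
    words <- replicate(sample(2:5, 1), paste(
      sample(letters, sample(3:8, 1), replace = TRUE), collapse = ""))
    pieces <- unlist(lapply(words, function(w) {
      n <- nchar(w)
      cuts <- sort(sample(seq_len(n - 1), sample(0:min(2, n - 1), 1)))
      starts <- c(1, cuts + 1); ends <- c(cuts, n)
      ps <- substring(w, starts, ends)
      if (length(ps) > 1) ps[-1] <- paste0("##", ps[-1])
      ps
    }))
    al <- align_wordpieces(words, pieces)
    # contiguity + surjectivity
    expect_equal(sort(unique(al$word_of_piece)), seq_along(words))
    expect_true(all(diff(al$word_of_piece) %in% c(0L, 1L)))
    expect_equal(al$pieces[al$first_piece_of_word],
                 pieces[al$first_piece_of_word])
  }
})

test_that("sentence-graph wiring follows the two linking rules", {
  # two single-piece words, one dependency: a single symmetric edge
  p <- dep_parse(c("x", "y"), c(0L, 1L))
  al <- align_wordpieces(p$words, c("x", "y"))
  g <- build_sentence_graph(p, al)
  expect_equal(g$adjacency, matrix(c(0L, 1L, 1L, 0L), 2))

  # 'A tacrine' with A -> tacrine: first-piece rule plus within-word chain
  p2 <- dep_parse(c("A", "tacrine"), c(0L, 1L))
  al2 <- align_wordpieces(p2$words, c("a", "tac", "##rine"))
  g2 <- build_sentence_graph(p2, al2)
  expect_equal(g2$node_count, 3)
  expect_equal(g2$adjacency[1, 2], 1L)  # A - tac (first piece)
  expect_equal(g2$adjacency[2, 3], 1L)  # tac - ##rine (chain)
  expect_equal(g2$adjacency[1, 3], 0L)  # no A - ##rine edge
})

test_that("any tree parse yields a connected piece graph with m-1 edges", {
  set.seed(7)
  for (i in 1:100) {
    n <- sample(2:9, 1)
    p <- generate_random_tree(n, words = replicate(n, paste(
      sample(letters, sample(2:6, 1), replace = TRUE), collapse = "")))
    pieces <- unlist(lapply(p$words, function(w) {
      if (nchar(w) > 3 && stats::runif(1) < 0.4) {
        c(substr(w, 1, 2), paste0("##", substr(w, 3, nchar(w))))
      } else w
    }))
    al <- align_wordpieces(p$words, pieces)
    g <- build_sentence_graph(p, al)
    m <- g$node_count
    expect_identical(g$adjacency, t(g$adjacency))
    expect_true(all(diag(g$adjacency) == 0))
    expect_equal(sum(g$adjacency) / 2, m - 1)
    expect_true(all(is.finite(graph_distances(g, 1))))  # connected
    # deprel labels never influence the graph
    p_shuf <- dep_parse(p$words, p$heads,
                        sample(c("amod", "nsubj", "obj"), n, replace = TRUE))
    expect_identical(build_sentence_graph(p_shuf, al)$adjacency, g$adjacency)
  }
})

test_that("graph distances equal the all-pairs shortest-path oracle", {
  g3 <- path_graph(3)
  expect_equal(graph_distance(g3, 1, 1), 0)
  expect_equal(graph_distance(g3, 1, 3), 2)
  set.seed(13)
  for (i in 1:50) {
    g <- random_tree_graph(sample(2:8, 1))
    D <- fw_distances(g$adjacency)
    for (u in seq_len(g$node_count)) {
      expect_equal(graph_distances(g, u), D[u, ])
    }
  }
})

test_that("graphs export as edge list plus node table", {
  g <- path_graph(4)
  e <- withr::local_tempfile(fileext = ".tsv")
  n <- withr::local_tempfile(fileext = ".tsv")
  write_graph_tsv(g, e, n)
  edges <- utils::read.delim(e)
  nodes <- utils::read.delim(n)
  expect_equal(nrow(edges), 3)
  expect_equal(nrow(nodes), 4)
})
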