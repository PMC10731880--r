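# shared builders for graph/corpus fixtures, all generated in code

# a path graph a-b-c-... over n single-piece words
path_graph <- function(n, reps = NULL) {
  words <- letters[seq_len(n)]
  heads <- c(0L, seq_len(n - 1L))
  p <- dep_parse(words, heads)
  al <- align_wordpieces(words, words)
  build_sentence_graph(p, al, reps)
}

# star: center word with n_leaves dependents, every word one piece
star_graph <- function(n_leaves) {
  n <- n_leaves + 1L
  words <- c("hub", sprintf("l%d", seq_len(n_leaves)))
  heads <- c(0L, rep(1L, n_leaves))
  p <- dep_parse(words, heads)
  al <- align_wordpieces(words, words)
  build_sentence_graph(p, al)
}

# random tree graph on single-piece nodes (structure only)
random_tree_graph <- function(n) {
  p <- generate_random_tree(n, words = sprintf("w%d", seq_len(n)))
  al <- align_wordpieces(p$words, p$words)
  build_sentence_graph(p, al)
}

# brute-force all-pairs shortest paths (Floyd-Warshall), the distance oracle
fw_distances <- function(A) {
  m <- nrow(A)
  D <- matrix(Inf, m, m)
  diag(D) <- 0
  D[A == 1] <- 1
  for (k in seq_len(m)) for (i in seq_len(m)) for (j in seq_len(m)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  D
}

# small strict-equation (tanh cell) GPNN setup with hand-settable weights
strict_cfg <- function(d, L, M, conv_kernel = 1) {
  gpnn_config(d1 = d, d2 = d, L = L, M = M, conv_kernel = conv_kernel,
              activation = "identity", cell = "tanh")
}

zeroed_params <- function(cfg) {
  P <- gpnn_params(cfg, seed = 1)
  lapply(P, function(p) p * 0)
}

# one cached small synthetic corpus shared by the slower tests
synth_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_corpus(synth_spec(n_instances = 80, seed = 303))
    }
    cache
  }
})

tiny_encoder <- function(corp, d1 = 8) {
  toy_encoder(corp$vocab, d1 = d1, max_len = 32)
}
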