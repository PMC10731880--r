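#' Multi-hop neighbor sampler configuration
#'
#' @param k maximum hop depth of the breadth-first sampler. Not a tuned
#'   training hyperparameter: 2 hops nearly saturate typical sentence graphs
#'   once the sequence cap is 32, so 2 is the default; set larger to reach
#'   the whole graph.
#' @param L sequence cap ("GPNN input neighbors"): sampling stops after L
#'   nodes, exhausting lower hops first.
#' @param seed base seed for the per-node counter-based streams.
#' @export
sampler_config <- function(k = 2, L = 32, seed = 1L) {
  stopifnot(k >= 1, L >= 1)
  structure(list(k = as.integer(k), L = as.integer(L), seed = as.integer(seed)),
            class = "sampler_config")
}

# run expr under a derived RNG stream without disturbing the caller's RNG
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic per-(seed, sentence, node) stream key, kept inside 2^31
.stream_seed <- function(seed, sentence_key, node) {
  s <- (as.double(seed) * 2654435761 + as.double(sentence_key) * 40503 +
          as.double(node) * 97) %% 2147483647
  as.integer(s)
}

#' Sample an ordered multi-hop neighbor sequence for one node
#'
#' Breadth-first from the center: all hop-1 nodes, then hop-2, up to hop
#' `k`, with the nodes inside each hop in uniformly random order, truncated
#' at `L` (lower hops are always exhausted before the cap bites). Sequences
#' shorter than `L` record a `pad_count`; padded slots carry the zero vector
#' downstream and are masked out of the pointer encoder.
#'
#' @param graph a [build_sentence_graph()] result.
#' @param center 1-based node index.
#' @param cfg a [sampler_config()].
#' @param sentence_key integer identifying the sentence, mixed into the
#'   per-node RNG stream so batch results are order-independent.
#' @return list of class `neighbor_seq`: `center`, `entries` (data frame of
#'   `node`, `hop`), `pad_count`.
#' @export
sample_neighbor_sequence <- function(graph, center, cfg, sentence_key = 0L) {
  center <- as.integer(center)
  dist <- graph_distances(graph, center)
  nodes <- integer(0); hops <- integer(0)
  .with_seed(.stream_seed(cfg$seed, sentence_key, center), {
    for (h in seq_len(cfg$k)) {
      if (length(nodes) >= cfg$L) break
      ring <- which(dist == h)
      if (length(ring) == 0) next
      ring <- ring[sample.int(length(ring))]
      take <- min(length(ring), cfg$L - length(nodes))
      nodes <- c(nodes, ring[seq_len(take)])
      hops <- c(hops, rep(h, take))
    }
  })
  structure(list(center = center,
                 entries = data.frame(node = nodes, hop = hops),
                 pad_count = cfg$L - length(nodes)),
            class = "neighbor_seq")
}

#' Sample neighbor sequences for every node of a graph
#'
#' Each node draws from its own `(seed, sentence, node)` RNG stream, so the
#' batch is reproducible and independent of iteration order.
#'
#' @inheritParams sample_neighbor_sequence
#' @return list of `neighbor_seq`, one per node.
#' @export
batch_sample <- function(graph, cfg, sentence_key = 0L) {
  lapply(seq_len(graph$node_count), function(u)
    sample_neighbor_sequence(graph, u, cfg, sentence_key))
}

#' Fraction of nodes whose full 2-hop neighborhood fits under the cap
#'
#' Counts nodes with at most `L` other nodes within hop distance 1..2; a
#' coverage of 1 means the sampler never truncates a 2-hop neighborhood.
#'
#' @inheritParams sample_neighbor_sequence
#' @return a fraction in [0, 1]; 1 for a graph with no nodes.
#' @export
two_hop_coverage <- function(graph, cfg) {
  m <- graph$node_count
  if (m == 0) return(1)
  ok <- vapply(seq_len(m), function(u) {
    d <- graph_distances(graph, u)
    sum(d >= 1 & d <= 2) <= cfg$L
  }, logical(1))
  mean(ok)
}

#' Export sampled sequences as TSV for inspection
#'
#' @param seqs result of [batch_sample()].
#' @param sentence_id id string written in the first column.
#' @param path output TSV.
#' @export
write_sequences_tsv <- function(seqs, sentence_id, path) {
  rows <- do.call(rbind, lapply(seqs, function(s) {
    if (nrow(s$entries) == 0) return(NULL)
    data.frame(sentence_id = sentence_id, center = s$center,
               rank = seq_len(nrow(s$entries)),
               node = s$entries$node, hop = s$entries$hop)
  }))
  if (is.null(rows)) {
    rows <- data.frame(sentence_id = character(), center = integer(),
                       rank = integer(), node = integer(), hop = integer())
  }
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
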