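#' Dependency parse of one sentence
#'
#' A rooted tree over surface words: each word has a head index (0 for the
#' root) and a relation label. Relation labels are retained for round-trips
#' but never influence the sentence graph, which uses head structure only.
#'
#' @param words character vector of surface tokens.
#' @param heads integer vector, same length; `heads[i]` is the 1-based index
#'   of word i's head, 0 for the root.
#' @param deprels character vector of relation labels (default `"dep"`).
#' @return object of class `dep_parse`.
#' @export
dep_parse <- function(words, heads, deprels = rep("dep", length(words))) {
  n <- length(words)
  heads <- as.integer(heads)
  if (length(heads) != n || length(deprels) != n) {
    stop("words, heads and deprels must have equal length")
  }
  if (any(heads < 0 | heads > n)) {
    stop("head indices out of range: ",
         paste(which(heads < 0 | heads > n), collapse = ", "))
  }
  roots <- which(heads == 0)
  if (length(roots) != 1) {
    stop("parse must have exactly one root, found roots at: ",
         paste(roots, collapse = ", "))
  }
  # walk each word to the root; revisiting a word on one walk is a cycle
  for (i in seq_len(n)) {
    seen <- logical(n)
    j <- i
    while (j != 0) {
      if (seen[j]) {
        stop("head cycle involving word indices: ",
             paste(which(seen), collapse = ", "))
      }
      seen[j] <- TRUE
      j <- heads[j]
    }
  }
  structure(list(words = words, heads = heads, deprels = deprels),
            class = "dep_parse")
}

#' Read dependency parses from a CoNLL-U file
#'
#' Standard 10-column CoNLL-U: one block per sentence, blocks separated by
#' blank lines, `#` comment lines allowed (a `# sent_id = ...` comment names
#' the sentence). Multi-word token ranges (`1-2`) and empty nodes (`1.1`)
#' are skipped. Every block is validated as a single-rooted tree; cycles or
#' multiple roots are errors naming the offending indices.
#'
#' @param path CoNLL-U file path (or a character vector of lines via
#'   `text =`).
#' @param text optional character vector of lines instead of a file.
#' @return named list of [dep_parse()] objects.
#' @export
read_conllu <- function(path = NULL, text = NULL) {
  lines <- if (is.null(text)) readLines(path, encoding = "UTF-8") else text
  parses <- list()
  cur <- list(id = NULL, rows = list())
  flush <- function(cur, parses) {
    if (length(cur$rows) == 0) return(parses)
    rows <- do.call(rbind, cur$rows)
    p <- dep_parse(rows[, 1], as.integer(rows[, 2]), rows[, 3])
    id <- if (is.null(cur$id)) sprintf("s%d", length(parses) + 1) else cur$id
    parses[[id]] <- p
    parses
  }
  for (ln in lines) {
    if (grepl("^\\s*$", ln)) {
      parses <- flush(cur, parses)
      cur <- list(id = NULL, rows = list())
    } else if (startsWith(ln, "#")) {
      m <- regmatches(ln, regexec("^#\\s*sent_id\\s*=\\s*(\\S+)", ln))[[1]]
      if (length(m) == 2) cur$id <- m[2]
    } else {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(f) < 8) stop("malformed CoNLL-U line: ", ln)
      if (grepl("[-.]", f[1])) next  # multiword ranges / empty nodes
      cur$rows[[length(cur$rows) + 1]] <- c(f[2], f[7], f[8])
    }
  }
  flush(cur, parses)
}

#' @rdname read_conllu
#' @param parses named list of [dep_parse()] objects.
#' @export
write_conllu <- function(parses, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (id in names(parses)) {
    p <- parses[[id]]
    writeLines(sprintf("# sent_id = %s", id), con)
    for (i in seq_along(p$words)) {
      writeLines(paste(i, p$words[i], "_", "_", "_", "_",
                       p$heads[i], p$deprels[i], "_", "_", sep = "\t"), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Align encoder word-pieces with parser words
#'
#' Subword tokenizers split rare words into pieces (`tacrine` becomes
#' `tac`, `##rine`); the dependency parse lives on whole words. The
#' alignment maps every piece to its word, requiring the pieces of a word to
#' be contiguous and, with `##` continuation markers stripped and case
#' folded, to concatenate back to the word's characters.
#'
#' @param words character vector of parser words.
#' @param pieces character vector of word-pieces, continuations prefixed
#'   `##`.
#' @return list of class `wp_alignment` with `pieces`, `word_of_piece`
#'   (1-based word index per piece) and `first_piece_of_word`.
#' @export
align_wordpieces <- function(words, pieces) {
  strip <- function(p) sub("^##", "", p)
  word_of_piece <- integer(length(pieces))
  first_piece <- integer(length(words))
  j <- 1
  for (w in seq_along(words)) {
    target <- tolower(words[w])
    first_piece[w] <- j
    acc <- ""
    while (nchar(acc) < nchar(target)) {
      if (j > length(pieces)) {
        stop("pieces exhausted while aligning word '", words[w], "'")
      }
      acc <- paste0(acc, tolower(strip(pieces[j])))
      word_of_piece[j] <- w
      j <- j + 1
    }
    if (acc != target) {
      stop("unalignable tokenization at word '", words[w],
           "': pieces give '", acc, "'")
    }
  }
  if (j != length(pieces) + 1) {
    stop("trailing pieces not covered by any word: ",
         paste(pieces[j:length(pieces)], collapse = " "))
  }
  structure(list(pieces = pieces, word_of_piece = word_of_piece,
                 first_piece_of_word = first_piece),
            class = "wp_alignment")
}

#' Build the undirected sentence graph over word-pieces
#'
#' Nodes are word-pieces; an edge joins (i) the first pieces of two
#' dependency-linked words and (ii) consecutive pieces of one word. The
#' adjacency matrix is symmetric 0/1 with a zero diagonal, and for a
#' tree-valid parse the graph is itself a tree on the pieces (connected,
#' `m - 1` edges).
#'
#' @param parse a [dep_parse()].
#' @param align a [align_wordpieces()] alignment for the same words.
#' @param reps numeric matrix of per-piece attribute vectors, one row per
#'   piece (may be NULL for structure-only graphs).
#' @return object of class `sentence_graph`: `node_count`, `adjacency`,
#'   `attributes`, `node_labels`, `word_of_piece`.
#' @export
build_sentence_graph <- function(parse, align, reps = NULL) {
  m <- length(align$pieces)
  if (length(parse$words) != length(align$first_piece_of_word)) {
    stop("parse and alignment disagree on word count")
  }
  if (!is.null(reps) && nrow(reps) != m) {
    stop("reps has ", nrow(reps), " rows for ", m, " pieces")
  }
  A <- matrix(0L, m, m)
  fp <- align$first_piece_of_word
  for (w in seq_along(parse$words)) {
    h <- parse$heads[w]
    if (h > 0) {
      u <- fp[w]; v <- fp[h]
      A[u, v] <- 1L; A[v, u] <- 1L
    }
  }
  for (p in seq_len(m - 1)) {
    if (align$word_of_piece[p] == align$word_of_piece[p + 1]) {
      A[p, p + 1] <- 1L; A[p + 1, p] <- 1L
    }
  }
  structure(list(node_count = m, adjacency = A, attributes = reps,
                 node_labels = align$pieces,
                 word_of_piece = align$word_of_piece),
            class = "sentence_graph")
}

#' Shortest-path hop distances in a sentence graph
#'
#' Breadth-first search from `u`; `graph_distance` returns the hop count to
#' `v` (`Inf` when unreachable), `graph_distances` the vector of distances
#' from `u` to every node.
#'
#' @param graph a [build_sentence_graph()] result.
#' @param u,v 1-based node indices.
#' @export
graph_distance <- function(graph, u, v) {
  graph_distances(graph, u)[v]
}

#' @rdname graph_distance
#' @export
graph_distances <- function(graph, u) {
  m <- graph$node_count
  dist <- rep(Inf, m)
  dist[u] <- 0
  frontier <- u
  d <- 0
  while (length(frontier) > 0) {
    d <- d + 1
    nxt <- integer(0)
    for (x in frontier) {
      nb <- which(graph$adjacency[x, ] == 1L)
      nb <- nb[is.infinite(dist[nb])]
      dist[nb] <- d
      nxt <- c(nxt, nb)
    }
    frontier <- unique(nxt)
  }
  dist
}

#' Export a sentence graph as edge-list and node tables
#'
#' @param graph a `sentence_graph`.
#' @param edge_path,node_path output TSV paths.
#' @export
write_graph_tsv <- function(graph, edge_path, node_path) {
  e <- which(upper.tri(graph$adjacency) & graph$adjacency == 1L,
             arr.ind = TRUE)
  utils::write.table(data.frame(node_u = e[, 1], node_v = e[, 2]),
                     edge_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(index = seq_len(graph$node_count),
                                piece = graph$node_labels,
                                word_index = graph$word_of_piece),
                     node_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(edge_path)
}
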