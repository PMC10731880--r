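#' Greedy word-piece tokenization against a subword vocabulary
#'
#' Longest-match-first segmentation: the longest vocabulary piece matching a
#' prefix of the (case-folded) word is taken, then continuation pieces
#' (stored with a `##` prefix) are matched against the remainder. Words that
#' cannot be segmented raise an error, so build vocabularies containing at
#' least the single characters used.
#'
#' @param word a single word (entity markers `@`/`#` should be stripped
#'   first).
#' @param vocab character vector of pieces; continuations carry a `##`
#'   prefix.
#' @return character vector of pieces, e.g. `c("tac", "##rine")`.
#' @export
wordpiece_tokenize <- function(word, vocab) {
  w <- tolower(word)
  out <- character(0)
  pos <- 1L
  n <- nchar(w)
  first <- TRUE
  while (pos <= n) {
    hit <- NULL
    for (len in seq(n - pos + 1L, 1L)) {
      cand <- substr(w, pos, pos + len - 1L)
      key <- if (first) cand else paste0("##", cand)
      if (key %in% vocab) { hit <- key; pos <- pos + len; break }
    }
    if (is.null(hit)) {
      stop("cannot word-piece tokenize '", word, "' at position ", pos)
    }
    out <- c(out, hit)
    first <- FALSE
  }
  out
}

#' Token encoder backends
#'
#' An encoder turns a marked sentence into word-pieces plus one contextual
#' vector per piece (the `X` stream of the model). Two backends honor the
#' same contract: `toy_encoder()` is a trainable embedding table with a
#' one-layer bidirectional tanh recurrence (plus a learned additive marker
#' embedding on the pieces of the marked mentions), small enough that the
#' whole pipeline trains on a CPU in seconds; `precomputed_encoder()` serves
#' fixed vectors produced by any external contextual encoder from a TSV
#' keyed by instance id, so transformer representations can be consumed
#' without running one in-process.
#'
#' @param vocab word-piece vocabulary (see [wordpiece_tokenize()]).
#' @param d1 vector dimension (even; half per recurrence direction).
#' @param seed parameter-initialization seed.
#' @param max_len maximum piece count; longer sentences are right-truncated
#'   when both mentions survive, otherwise rejected.
#' @return object of class `gpnre_encoder`.
#' @export
toy_encoder <- function(vocab, d1 = 32, seed = 1L, max_len = 128L) {
  stopifnot(d1 %% 2 == 0)
  h <- d1 %/% 2
  params <- .with_seed(seed, list(
    enc.emb = .glorot(length(vocab), d1),
    enc.marker = .glorot(1, d1),
    enc.W_f = .glorot(h + d1, h),
    enc.b_f = matrix(0, 1, h),
    enc.W_b = .glorot(h + d1, h),
    enc.b_b = matrix(0, 1, h)))
  structure(list(backend = "toy", vocab = vocab, d1 = d1, seed = seed,
                 max_len = as.integer(max_len), params = params),
            class = "gpnre_encoder")
}

#' @rdname toy_encoder
#' @param path TSV with columns `id`, `piece`, `v1..vd` (one row per piece,
#'   in order).
#' @export
precomputed_encoder <- function(path, max_len = 128L) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  vcols <- grep("^v[0-9]+$", names(df), value = TRUE)
  if (length(vcols) == 0) stop("no v1..vd vector columns in ", path)
  store <- split(df, df$id)
  store <- lapply(store, function(s)
    list(pieces = s$piece, vectors = as.matrix(s[, vcols, drop = FALSE])))
  structure(list(backend = "precomputed", store = store,
                 d1 = length(vcols), max_len = as.integer(max_len)),
            class = "gpnre_encoder")
}

# split a marked sentence into words, flag the marked ones, strip markers
.split_marked <- function(text) {
  words <- strsplit(trimws(text), "[ \t]+")[[1]]
  marked <- grepl("@[^@#]+#", words)
  clean <- gsub("[@#]", "", words)
  if (sum(marked) != 2) {
    stop("sentence must contain exactly two @...# mentions: ", text)
  }
  list(words = clean, marked = marked)
}

# static per-instance encoder input: piece ids, marker flags, segmentation
.encoder_input <- function(text, encoder) {
  sm <- .split_marked(text)
  pieces <- character(0); word_of_piece <- integer(0); flags <- numeric(0)
  for (w in seq_along(sm$words)) {
    pw <- wordpiece_tokenize(sm$words[w], encoder$vocab)
    pieces <- c(pieces, pw)
    word_of_piece <- c(word_of_piece, rep(w, length(pw)))
    flags <- c(flags, rep(as.numeric(sm$marked[w]), length(pw)))
  }
  m <- length(pieces)
  if (m > encoder$max_len) {
    keep <- seq_len(encoder$max_len)
    if (any(flags[-keep] > 0)) {
      stop("truncation to ", encoder$max_len,
           " pieces would drop an entity mention")
    }
    pieces <- pieces[keep]; word_of_piece <- word_of_piece[keep]
    flags <- flags[keep]
  }
  list(pieces = pieces, word_of_piece = word_of_piece, flags = flags,
       ids = match(pieces, encoder$vocab), words = sm$words,
       marked = sm$marked)
}

# tape forward of the toy encoder: returns node id of the m x d1 matrix
.encode_toy_t <- function(tp, pids, input, d1) {
  m <- length(input$ids)
  h <- d1 %/% 2
  emb <- ad_rows(tp, pids[["enc.emb"]], input$ids)
  fl <- ad_const(tp, matrix(input$flags, ncol = 1))
  emb <- ad_add(tp, emb, ad_matmul(tp, fl, pids[["enc.marker"]]))
  fwd <- ad_rnn_tanh(tp, emb, pids[["enc.W_f"]], pids[["enc.b_f"]])
  bwd <- ad_rnn_tanh(tp, emb, pids[["enc.W_b"]], pids[["enc.b_b"]],
                     reverse = TRUE)
  ad_cbind(tp, c(fwd, bwd))
}

#' Encode a marked sentence into word-pieces and contextual vectors
#'
#' @param text marked sentence (exactly two `@...#` mentions).
#' @param encoder a [toy_encoder()] or [precomputed_encoder()].
#' @param id instance id; required by the precomputed backend.
#' @return list of class `encoded_sentence`: `pieces`, `vectors` (m x d1),
#'   `word_segmentation` (unmarked words), `word_of_piece`, `entity_mask`.
#' @export
encode <- function(text, encoder, id = NULL) {
  if (!nzchar(trimws(text))) stop("empty sentence")
  if (encoder$backend == "toy") {
    input <- .encoder_input(text, encoder)
    tp <- ad_tape()
    pids <- .inject_params(tp, encoder$params)
    vid <- .encode_toy_t(tp, pids, input, encoder$d1)
    vectors <- ad_val(tp, vid)
  } else {
    if (is.null(id) || !id %in% names(encoder$store)) {
      stop("precomputed backend needs a known instance id, got: ",
           if (is.null(id)) "NULL" else id)
    }
    rec <- encoder$store[[id]]
    sm <- .split_marked(text)
    input <- list(pieces = rec$pieces,
                  word_of_piece = .pieces_to_words(rec$pieces, sm$words),
                  flags = numeric(length(rec$pieces)),
                  words = sm$words, marked = sm$marked)
    vectors <- rec$vectors
  }
  structure(list(pieces = input$pieces, vectors = vectors,
                 word_segmentation = input$words,
                 word_of_piece = input$word_of_piece,
                 entity_mask = input$flags),
            class = "encoded_sentence")
}

# align stored pieces back onto words by character consumption
.pieces_to_words <- function(pieces, words) {
  align_wordpieces(words, pieces)$word_of_piece
}
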