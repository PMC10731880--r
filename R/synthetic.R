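#' Specification of a synthetic planted-signal relation corpus
#'
#' The generator emulates the shape of a sentence-level relation-extraction
#' corpus without any real text: sentences are random projective-free
#' dependency trees over a small vocabulary (a configurable fraction of
#' words split into word-pieces), each instance has two marked entity
#' mentions, and the gold label is a deterministic function of graph
#' topology: the trigger word graph-nearest to the entity pair decides the
#' class, and only triggers within 2 hops in the dependency tree count.
#' Trigger words are planted graph-near but sequence-far from the entities,
#' with sequence-near but graph-far distractor triggers of other classes,
#' so a bag-of-tokens model cannot recover the rule while a
#' topology-aware model can. Labels are then flipped with probability
#' `noise`, making `1 - noise` the Bayes-optimal accuracy by construction.
#'
#' @param n_instances number of instances.
#' @param len_range integer range of sentence lengths (words).
#' @param noise label-flip probability in `[0, 0.5)`.
#' @param multipiece_frac fraction of filler draws using two-piece words.
#' @param p_negative probability of a no-near-trigger (negative) instance.
#' @param seq_gap minimum linear distance between a planted trigger and its
#'   entity.
#' @param n_fillers size of the single-piece filler lexicon.
#' @param seed RNG seed; generation is byte-reproducible given the spec.
#' @return list of class `synth_spec`.
#' @export
synth_spec <- function(n_instances = 2000, len_range = c(9, 14),
                       noise = 0.05, multipiece_frac = 0.3,
                       p_negative = 1 / 3, seq_gap = 4, n_fillers = 40,
                       seed = 1L) {
  stopifnot(noise >= 0, noise < 0.5, len_range[1] >= 6)
  structure(list(n_instances = n_instances, len_range = len_range,
                 noise = noise, multipiece_frac = multipiece_frac,
                 p_negative = p_negative, seq_gap = seq_gap,
                 n_fillers = n_fillers, seed = as.integer(seed)),
            class = "synth_spec")
}

#' Label scheme of the synthetic corpus: two positive relation classes
#' decided by trigger identity, plus the catch-all negative.
#' @export
synth_scheme <- function() {
  label_scheme(c("REL:A", "REL:B"), "False",
               c("REL:A" = "REL:A", "REL:B" = "REL:B",
                 unannotated = "False", False = "False"))
}

#' Trigger lexicon of the synthetic corpus, named by relation class.
#' @export
synth_triggers <- function() c("REL:A" = "activin", "REL:B" = "blocor")

# word-piece building blocks for two-piece filler words
.synth_parts <- list(base = c("mide", "tac", "glu", "fera", "zopi", "cort"),
                     cont = c("##rol", "##rine", "##max", "##din", "##vex"))

#' Vocabulary of the synthetic corpus (word pieces)
#' @param spec a [synth_spec()].
#' @export
synth_vocab <- function(spec = synth_spec()) {
  fillers <- sprintf("fill%02d", seq_len(spec$n_fillers))
  entities <- c(sprintf("chem%02d", 1:8), sprintf("prot%02d", 1:8))
  c(fillers, entities, unname(synth_triggers()),
    .synth_parts$base, .synth_parts$cont, paste0("##", letters), letters)
}

#' Uniform random rooted dependency tree by random attachment
#'
#' Word 1..n in a shuffled order: the first becomes the root, each later
#' word attaches to a uniformly chosen earlier one.
#'
#' @param n_words number of words.
#' @param words optional surface forms (placeholders by default).
#' @return a [dep_parse()].
#' @export
generate_random_tree <- function(n_words, words = sprintf("w%d", seq_len(n_words))) {
  heads <- integer(n_words)
  if (n_words > 1) {
    ord <- sample.int(n_words)
    for (k in seq_along(ord)[-1]) {
      heads[ord[k]] <- ord[sample.int(k - 1, 1)]
    }
  }
  dep_parse(words, heads)
}

# undirected hop distances between words of a parse tree
.tree_dists <- function(heads, from) {
  n <- length(heads)
  adj <- vector("list", n)
  for (i in seq_len(n)) {
    if (heads[i] > 0) {
      adj[[i]] <- c(adj[[i]], heads[i])
      adj[[heads[i]]] <- c(adj[[heads[i]]], i)
    }
  }
  dist <- rep(Inf, n); dist[from] <- 0
  frontier <- from
  d <- 0
  while (length(frontier) > 0) {
    d <- d + 1
    nxt <- integer(0)
    for (x in frontier) {
      nb <- adj[[x]][is.infinite(dist[adj[[x]]])]
      dist[nb] <- d
      nxt <- c(nxt, nb)
    }
    frontier <- unique(nxt)
  }
  dist
}

# interior nodes of the tree path between e1 and e2 (endpoints excluded)
.path_interior <- function(heads, e1, e2) {
  n <- length(heads)
  adj <- vector("list", n)
  for (i in seq_len(n)) if (heads[i] > 0) {
    adj[[i]] <- c(adj[[i]], heads[i])
    adj[[heads[i]]] <- c(adj[[heads[i]]], i)
  }
  parent <- rep(NA_integer_, n)
  parent[e1] <- 0L
  frontier <- e1
  while (length(frontier) > 0 && is.na(parent[e2])) {
    nxt <- integer(0)
    for (x in frontier) for (y in adj[[x]]) if (is.na(parent[y])) {
      parent[y] <- x
      nxt <- c(nxt, y)
    }
    frontier <- nxt
  }
  path <- e2
  while (path[1] != e1) path <- c(parent[path[1]], path)
  if (length(path) <= 2) integer(0) else path[-c(1, length(path))]
}

#' The deterministic labelling rule of the synthetic corpus
#'
#' A trigger word is decisive when it lies within one hop of the interior
#' of the dependency path joining the two entity words — i.e. it hangs off
#' the syntactic route connecting the pair. The decisive trigger nearest
#' to the path interior (ties: earliest position) names the label; with no
#' decisive trigger the instance is negative. Path membership is not a
#' local property of any single node, which is what makes the rule
#' genuinely multi-hop: a one-hop neighborhood never reveals whether a
#' node sits between the marked entities.
#'
#' @param heads head vector of the word-level parse.
#' @param words surface words (unmarked).
#' @param e1,e2 entity word positions.
#' @return a label of [synth_scheme()].
#' @export
synth_label_rule <- function(heads, words, e1, e2) {
  trig <- synth_triggers()
  pos <- which(words %in% trig)
  if (length(pos) == 0) return("False")
  interior <- .path_interior(heads, e1, e2)
  if (length(interior) == 0) return("False")
  d <- vapply(pos, function(t)
    min(.tree_dists(heads, t)[interior]), numeric(1))
  best <- which(d == min(d))[1]
  if (d[best] <= 1) names(trig)[match(words[pos[best]], trig)] else "False"
}

# sample one element of x (safe for length-1 vectors)
.pick1 <- function(x) x[sample.int(length(x), 1)]

# try once to build a sentence satisfying the planted-topology constraints:
# a 4-edge backbone e1-a-w-b-e2 and exactly one trigger of each class, both
# sequence-far from both entities. For a positive instance one trigger
# hangs off the middle interior node w (decisive) and the other attaches
# >= 2 hops away from the interior; for a negative both do. The token
# multiset and the linear trigger placement are therefore identically
# distributed across classes: only the tree topology carries the label.
.try_sentence <- function(spec, want_class) {
  n <- sample(seq(spec$len_range[1], spec$len_range[2]), 1)
  roles <- sample.int(n, 7)
  e1 <- roles[1]; e2 <- roles[2]
  a <- roles[3]; w <- roles[4]; b <- roles[5]
  t1 <- roles[6]; t2 <- roles[7]
  for (t in c(t1, t2)) {
    if (abs(t - e1) < spec$seq_gap || abs(t - e2) < spec$seq_gap) {
      return(NULL)
    }
  }
  heads <- rep(0L, n)
  heads[a] <- e1; heads[w] <- a; heads[b] <- w; heads[e2] <- b
  attached <- c(e1, a, w, b, e2)
  rest <- setdiff(seq_len(n), c(attached, t1, t2))
  for (x in rest[sample.int(length(rest))]) {
    heads[x] <- .pick1(attached)
    attached <- c(attached, x)
  }
  # off-path attachment points: >= 2 hops from every interior node, so a
  # trigger hung there is >= 3 hops from the path and never decisive
  dint <- pmin(.tree_dists(heads, a), .tree_dists(heads, w),
               .tree_dists(heads, b))
  dint[c(t1, t2)] <- -Inf
  far <- which(dint >= 2)
  trig <- synth_triggers()
  words <- rep(NA_character_, n)
  if (want_class != "False") {
    if (length(far) < 1) return(NULL)
    other <- if (want_class == "REL:A") "REL:B" else "REL:A"
    planted <- .pick1(c(t1, t2))
    dodger <- setdiff(c(t1, t2), planted)
    heads[planted] <- w
    heads[dodger] <- .pick1(far)
    words[planted] <- trig[[want_class]]
    words[dodger] <- trig[[other]]
  } else {
    if (length(far) < 2) return(NULL)
    z <- sample(far, 2)
    heads[t1] <- z[1]; heads[t2] <- z[2]
    words[t1] <- trig[["REL:A"]]; words[t2] <- trig[["REL:B"]]
  }
  probe <- words; probe[is.na(probe)] <- "f"
  if (synth_label_rule(heads, probe, e1, e2) != want_class) return(NULL)
  list(n = n, heads = heads, words = words, e1 = e1, e2 = e2)
}

#' Generate a synthetic planted-signal corpus
#'
#' @param spec a [synth_spec()].
#' @param dir optional directory: writes `instances.tsv`,
#'   `parses.conllu`, `vocab.txt` and a `manifest.json` recording the spec.
#' @return list with `instances` (data frame), `parses` (named list of
#'   [dep_parse()]), `vocab`, `scheme` and `gold_rule_labels` (pre-noise
#'   labels).
#' @export
generate_corpus <- function(spec = synth_spec(), dir = NULL) {
  vocab <- synth_vocab(spec)
  fillers <- sprintf("fill%02d", seq_len(spec$n_fillers))
  scheme <- synth_scheme()
  classes <- scheme$evaluated_labels
  inst <- vector("list", spec$n_instances)
  parses <- list()
  rule_labels <- character(spec$n_instances)
  .with_seed(spec$seed, {
    for (i in seq_len(spec$n_instances)) {
      want <- if (stats::runif(1) < spec$p_negative) "False" else
        .pick1(classes)
      s <- NULL
      tries <- 0
      while (is.null(s)) {
        tries <- tries + 1
        if (tries > 10000) stop("cannot satisfy the sentence constraints; ",
                                "widen len_range or relax seq_gap")
        s <- .try_sentence(spec, want)
      }
      words <- s$words
      # entities: a chemical-like and a protein-like surface form
      words[s$e1] <- sprintf("chem%02d", sample.int(8, 1))
      words[s$e2] <- sprintf("prot%02d", sample.int(8, 1))
      open <- which(is.na(words))
      multi <- stats::runif(length(open)) < spec$multipiece_frac
      words[open[multi]] <- paste0(
        sample(.synth_parts$base, sum(multi), replace = TRUE),
        sub("^##", "", sample(.synth_parts$cont, sum(multi), replace = TRUE)))
      words[open[!multi]] <- sample(fillers, sum(!multi), replace = TRUE)
      label <- synth_label_rule(s$heads, words, s$e1, s$e2)
      rule_labels[i] <- label
      if (stats::runif(1) < spec$noise) {
        label <- .pick1(setdiff(scheme_labels(scheme), label))
      }
      marked <- words
      marked[s$e1] <- paste0("@", words[s$e1], "#")
      marked[s$e2] <- paste0("@", words[s$e2], "#")
      id <- sprintf("syn%05d", i)
      inst[[i]] <- data.frame(instance_id = id,
                              text = paste(marked, collapse = " "),
                              label = label, stringsAsFactors = FALSE)
      parses[[id]] <- dep_parse(words, s$heads)
    }
  })
  instances <- do.call(rbind, inst)
  out <- list(instances = instances, parses = parses, vocab = vocab,
              scheme = scheme, gold_rule_labels = rule_labels)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_instances(instances, file.path(dir, "instances.tsv"))
    write_conllu(parses, file.path(dir, "parses.conllu"))
    writeLines(vocab, file.path(dir, "vocab.txt"))
    writeLines(jsonlite::toJSON(unclass(spec), auto_unbox = TRUE),
               file.path(dir, "manifest.json"))
  }
  out
}

#' Bag-of-tokens baseline classifier
#'
#' Multinomial logistic regression on word-presence features (markers
#' stripped). On the planted-topology corpus its accuracy is capped well
#' below the Bayes rate because trigger identity alone does not determine
#' the label; it is provided as the sequence-blind reference point.
#'
#' @param train_instances,test_instances instance data frames.
#' @param scheme a [label_scheme()].
#' @return list with `predictions` and `accuracy` on the test instances.
#' @export
bow_baseline <- function(train_instances, test_instances,
                         scheme = synth_scheme()) {
  if (!requireNamespace("nnet", quietly = TRUE)) {
    stop("the bag-of-tokens baseline needs the 'nnet' package")
  }
  vocab_of <- function(inst) unique(unlist(strsplit(gsub("[@#]", "",
                                                         inst$text), " ")))
  voc <- vocab_of(train_instances)
  feat <- function(inst) {
    t(vapply(strsplit(gsub("[@#]", "", inst$text), " "), function(w)
      as.numeric(voc %in% w), numeric(length(voc))))
  }
  xtr <- feat(train_instances)
  xte <- feat(test_instances)
  ytr <- factor(train_instances$label, levels = scheme_labels(scheme))
  fit <- nnet::multinom(ytr ~ ., data = data.frame(ytr, xtr), trace = FALSE,
                        MaxNWts = 1e6)
  pred <- as.character(stats::predict(fit, newdata = data.frame(xte)))
  list(predictions = pred,
       accuracy = mean(pred == test_instances$label))
}
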