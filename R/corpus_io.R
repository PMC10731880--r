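#' Label schemes for relation classification
#'
#' A label scheme names the evaluated (positive) relation labels, the
#' catch-all negative label, and the mapping from raw annotation groups onto
#' that set. [chemprot_scheme()] is the CHEMPROT chemical-protein relation
#' scheme: of the ten CPR groups, five (CPR:3, CPR:4, CPR:5, CPR:6, CPR:9)
#' are evaluated; CPR:1, CPR:2, CPR:7, CPR:8, CPR:10 and unannotated pairs
#' all collapse to `False`. [binary_scheme()] is the two-label scheme used
#' for gene-disease style binary tasks.
#'
#' @param evaluated_labels ordered character vector of positive labels.
#' @param negative_label the catch-all negative label.
#' @param raw_to_evaluated named character vector mapping raw annotation
#'   groups to members of `c(negative_label, evaluated_labels)`.
#' @return a list of class `label_scheme`.
#' @export
label_scheme <- function(evaluated_labels, negative_label, raw_to_evaluated) {
  bad <- setdiff(unname(raw_to_evaluated),
                 c(negative_label, evaluated_labels))
  if (length(bad) > 0) {
    stop("raw_to_evaluated maps onto unknown labels: ",
         paste(bad, collapse = ", "))
  }
  structure(list(evaluated_labels = evaluated_labels,
                 negative_label = negative_label,
                 raw_to_evaluated = raw_to_evaluated),
            class = "label_scheme")
}

#' @rdname label_scheme
#' @export
chemprot_scheme <- function() {
  pos <- c("CPR:3", "CPR:4", "CPR:5", "CPR:6", "CPR:9")
  neg <- c("CPR:1", "CPR:2", "CPR:7", "CPR:8", "CPR:10")
  map <- c(stats::setNames(pos, pos),
           stats::setNames(rep("False", length(neg)), neg),
           unannotated = "False", False = "False")
  label_scheme(pos, "False", map)
}

#' @rdname label_scheme
#' @export
binary_scheme <- function() {
  label_scheme("positive", "negative",
               c(positive = "positive", negative = "negative",
                 unannotated = "negative"))
}

#' All labels of a scheme, negative first
#' @param scheme a [label_scheme()].
#' @export
scheme_labels <- function(scheme) {
  c(scheme$negative_label, scheme$evaluated_labels)
}

#' Map a raw annotation group to its evaluated label
#'
#' @param raw raw group string (e.g. `"CPR:7"`) or `"unannotated"`.
#' @param scheme a [label_scheme()].
#' @return the evaluated label, e.g. `"CPR:3"` stays `CPR:3` while `"CPR:10"`
#'   maps to `False` under [chemprot_scheme()].
#' @export
map_label <- function(raw, scheme) {
  out <- unname(scheme$raw_to_evaluated[raw])
  if (anyNA(out)) {
    stop("unknown raw label group: ",
         paste(unique(raw[is.na(out)]), collapse = ", "))
  }
  out
}

#' Mark an entity pair in a sentence
#'
#' Wraps each mention as `@mention#`, the convention used to tell the encoder
#' where the candidate pair sits. Character intervals are 0-based half-open
#' over the original sentence; the second mention's insertion point is
#' adjusted for the two marker characters inserted before it.
#'
#' @param sentence sentence string.
#' @param span1,span2 integer pairs `c(start, end)`, 0-based half-open,
#'   non-overlapping and within the sentence.
#' @return the marked sentence string.
#' @export
mark_entities <- function(sentence, span1, span2) {
  n <- nchar(sentence)
  .check_span(span1, n)
  .check_span(span2, n)
  if (max(span1[1], span2[1]) < min(span1[2], span2[2])) {
    stop(sprintf("overlapping entity spans [%d,%d) and [%d,%d)",
                 span1[1], span1[2], span2[1], span2[2]))
  }
  spans <- if (span1[1] <= span2[1]) list(span1, span2) else list(span2, span1)
  a <- spans[[1]]; b <- spans[[2]]
  paste0(substr(sentence, 1, a[1]),
         "@", substr(sentence, a[1] + 1, a[2]), "#",
         substr(sentence, a[2] + 1, b[1]),
         "@", substr(sentence, b[1] + 1, b[2]), "#",
         substr(sentence, b[2] + 1, n))
}

.check_span <- function(span, n) {
  if (length(span) != 2 || span[1] < 0 || span[2] > n || span[1] >= span[2]) {
    stop(sprintf("invalid span [%s,%s) for sentence of %d characters",
                 span[1], span[2], n))
  }
}

.count_marked_mentions <- function(text) {
  hits <- gregexpr("@[^@#]+#", text)[[1]]
  n_at <- lengths(regmatches(text, gregexpr("@", text, fixed = TRUE)))
  n_hash <- lengths(regmatches(text, gregexpr("#", text, fixed = TRUE)))
  n_pairs <- if (hits[1] == -1) 0L else length(hits)
  if (n_at != n_pairs || n_hash != n_pairs) return(-1L)
  n_pairs
}

#' Expand a multi-mention sentence into single-pair relation instances
#'
#' A sentence holding several candidate entity pairs becomes one instance per
#' pair, each with exactly one pair marked; pairs without an annotated
#' relation get the scheme's negative label. In `"cross_type"` mode (the
#' chemical-protein setting) valid pairs are chemical x protein/gene; in
#' `"all_pairs"` mode every unordered mention pair is a candidate. Pairs of
#' an entity with itself (duplicate mentions of one entity) are excluded.
#'
#' @param sentence unmarked sentence string.
#' @param entities data frame with columns `start`, `end` (0-based half-open
#'   character spans) and `type` (e.g. `"chemical"`, `"protein"`/`"gene"`).
#' @param gold_relations data frame with columns `e1`, `e2` (row indices into
#'   `entities`, chemical first in cross-type mode) and `label` (raw group);
#'   may be empty or NULL.
#' @param scheme a [label_scheme()].
#' @param instance_id base identifier; pair instances get `<id>.<k>` suffixes.
#' @param mode `"cross_type"` or `"all_pairs"`.
#' @return data frame of instances with columns `instance_id`, `text`
#'   (marked), `label`, and the two original spans
#'   (`e1_start`,`e1_end`,`e2_start`,`e2_end`); zero rows when no valid pair
#'   exists.
#' @export
expand_pairs <- function(sentence, entities, gold_relations = NULL,
                         scheme = chemprot_scheme(), instance_id = "s1",
                         mode = c("cross_type", "all_pairs")) {
  mode <- match.arg(mode)
  type <- tolower(as.character(entities$type))
  if (mode == "cross_type") {
    chems <- which(type == "chemical")
    prots <- which(type %in% c("protein", "gene"))
    pairs <- expand.grid(e1 = chems, e2 = prots)
  } else {
    idx <- seq_len(nrow(entities))
    pairs <- if (length(idx) < 2) {
      data.frame(e1 = integer(), e2 = integer())
    } else {
      as.data.frame(t(utils::combn(idx, 2)), col.names = c("e1", "e2")) |>
        stats::setNames(c("e1", "e2"))
    }
  }
  # drop self-pairs: identical spans are duplicate mentions of one entity
  if (nrow(pairs) > 0) {
    same <- entities$start[pairs$e1] == entities$start[pairs$e2] &
      entities$end[pairs$e1] == entities$end[pairs$e2]
    pairs <- pairs[!same, , drop = FALSE]
  }
  out <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$e1[k]; j <- pairs$e2[k]
    raw <- "unannotated"
    if (!is.null(gold_relations) && nrow(gold_relations) > 0) {
      hit <- which((gold_relations$e1 == i & gold_relations$e2 == j) |
                     (gold_relations$e1 == j & gold_relations$e2 == i))
      if (length(hit) > 0) raw <- gold_relations$label[hit[1]]
    }
    marked <- mark_entities(sentence,
                            c(entities$start[i], entities$end[i]),
                            c(entities$start[j], entities$end[j]))
    out[[k]] <- data.frame(
      instance_id = sprintf("%s.%d", instance_id, k),
      text = marked,
      label = map_label(raw, scheme),
      e1_start = entities$start[i], e1_end = entities$end[i],
      e2_start = entities$start[j], e2_end = entities$end[j],
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(instance_id = character(), text = character(),
                      label = character(), e1_start = integer(),
                      e1_end = integer(), e2_start = integer(),
                      e2_end = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Read and write relation-instance TSV files
#'
#' The on-disk dialect is a 3-column UTF-8 TSV with header
#' `index<TAB>sentence<TAB>label`; the sentence carries the literal `@...#`
#' entity markers. Marker characters are not escaped, so sentences containing
#' literal `@` or `#` outside the mentions are rejected (a known limitation
#' of the dialect). Malformed rows are collected, not fatal: the returned
#' data frame carries an attribute `"errors"`, a data frame of
#' `(line_no, reason)`, and `write_error_report()` serializes it as JSON
#' lines.
#'
#' @param path TSV file path.
#' @param scheme a [label_scheme()]; labels outside it are rejected rows.
#' @return data frame with columns `instance_id`, `text`, `label` and an
#'   `"errors"` attribute.
#' @export
read_instances <- function(path, scheme = chemprot_scheme()) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0) stop("empty instance file: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(header) < 3) {
    stop("instance TSV needs 3 columns (index, sentence, label), got: ",
         lines[1])
  }
  labels <- scheme_labels(scheme)
  rows <- vector("list", length(lines) - 1)
  errors <- list()
  for (i in seq_along(lines)[-1]) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    reason <- NULL
    if (length(f) != 3) {
      reason <- sprintf("expected 3 fields, got %d", length(f))
    } else if (!(f[3] %in% labels)) {
      reason <- sprintf("label '%s' not in scheme", f[3])
    } else if (.count_marked_mentions(f[2]) != 2L) {
      reason <- "sentence does not contain exactly two @...# mentions"
    }
    if (is.null(reason)) {
      rows[[i - 1]] <- data.frame(instance_id = f[1], text = f[2],
                                  label = f[3], stringsAsFactors = FALSE)
    } else {
      errors[[length(errors) + 1]] <-
        data.frame(line_no = i, reason = reason, stringsAsFactors = FALSE)
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(instance_id = character(), text = character(),
               label = character(), stringsAsFactors = FALSE)
  attr(out, "errors") <- if (length(errors) > 0) do.call(rbind, errors) else
    data.frame(line_no = integer(), reason = character())
  out
}

#' @rdname read_instances
#' @param instances data frame with `instance_id`, `text`, `label`.
#' @export
write_instances <- function(instances, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("index\tsentence\tlabel", con)
  if (nrow(instances) > 0) {
    writeLines(paste(instances$instance_id, instances$text, instances$label,
                     sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname read_instances
#' @param errors the `"errors"` attribute of [read_instances()].
#' @export
write_error_report <- function(errors, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(errors))) {
    writeLines(jsonlite::toJSON(list(line_no = errors$line_no[i],
                                     reason = errors$reason[i]),
                                auto_unbox = TRUE), con)
  }
  invisible(path)
}
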