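#' Construct a sentence with (possibly nested) entity mentions
#'
#' A sentence is the unit of encoding and decoding: a character vector of
#' tokens plus a tibble of entity mentions. Mention coordinates are 0-based
#' token indices with inclusive ends, the convention of the span-JSONL
#' interchange format, so a mention over tokens `t_s .. t_e` of an N-token
#' sentence satisfies `0 <= start <= end < N`. Mentions may nest (one span
#' properly contained in another) and may share boundaries; crossing
#' mentions (partial overlap without containment) are legal in gold data
#' but flagged with a warning, since they are annotation noise for this
#' model family.
#'
#' @param tokens character vector of tokens.
#' @param mentions a data frame with columns `start`, `end`, `label`
#'   (optionally `score`), or `NULL` for no mentions.
#' @return an object of class `nner_sentence`: a list with elements
#'   `tokens` and `mentions` (a tibble).
#' @export
sentence <- function(tokens, mentions = NULL) {
  if (!is.character(tokens)) abort("`tokens` must be a character vector")
  m <- as_mentions(mentions)
  validate_mentions(m, length(tokens))
  structure(list(tokens = tokens, mentions = m), class = "nner_sentence")
}

as_mentions <- function(x) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0)) {
    return(tibble(start = integer(), end = integer(), label = character()))
  }
  x <- as_tibble(x)
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  x$label <- as.character(x$label)
  x
}

validate_mentions <- function(m, n_tokens, where = NULL) {
  ctx <- if (is.null(where)) "" else paste0(" (", where, ")")
  if (nrow(m) == 0) return(invisible(m))
  if (any(m$end < m$start)) {
    abort(paste0("mention with end < start", ctx))
  }
  if (any(m$start < 0L) || any(m$end >= n_tokens)) {
    abort(paste0("mention outside the 0-based token range 0..", n_tokens - 1, ctx))
  }
  key <- paste(m$start, m$end, m$label)
  if (anyDuplicated(key)) {
    abort(paste0("duplicate (start, end, label) gold mention", ctx))
  }
  cr <- find_crossings(m)
  if (nrow(cr) > 0) {
    warn(paste0("corpus contains ", nrow(cr), " crossing mention pair(s)", ctx,
                "; kept as-is"))
  }
  invisible(m)
}

# pairs (a, b) with a.start < b.start <= a.end < b.end (partial overlap,
# no containment); containment and disjointness are not crossings
find_crossings <- function(m) {
  if (nrow(m) < 2) return(tibble(a = integer(), b = integer()))
  idx <- which(
    outer(m$start, m$start, `<`) &
      outer(m$end, m$start, `>=`) &
      outer(m$end, m$end, `<`),
    arr.ind = TRUE
  )
  tibble(a = idx[, 1], b = idx[, 2])
}

#' @export
print.nner_sentence <- function(x, ...) {
  cat("<sentence> ", paste(x$tokens, collapse = " "), "\n", sep = "")
  if (nrow(x$mentions) > 0) print(x$mentions) else cat("  (no mentions)\n")
  invisible(x)
}

new_corpus <- function(sentences) {
  structure(sentences, class = "nner_corpus")
}

#' @export
print.nner_corpus <- function(x, ...) {
  nm <- sum(vapply(x, function(s) nrow(s$mentions), integer(1)))
  cat("<corpus> ", length(x), " sentences, ", nm, " mentions\n", sep = "")
  invisible(x)
}

#' @export
`[.nner_corpus` <- function(x, i) new_corpus(unclass(x)[i])

#' Define the entity label set
#'
#' The classifier scores `C + 1` classes per span: the `C` entity types plus
#' a reserved non-entity class, which is never a legal mention label.
#'
#' @param entity_types character vector of entity type names.
#' @param non_entity name of the reserved non-entity class.
#' @return object of class `nner_label_set`.
#' @export
label_set <- function(entity_types, non_entity = "NONE") {
  entity_types <- as.character(entity_types)
  if (length(entity_types) < 1) abort("need at least one entity type")
  if (anyDuplicated(entity_types)) abort("duplicate entity types")
  if (non_entity %in% entity_types) {
    abort("the non-entity class name must not be an entity type")
  }
  structure(list(entity_types = entity_types, non_entity = non_entity),
            class = "nner_label_set")
}

corpus_label_set <- function(corpus) {
  labs <- sort(unique(unlist(lapply(corpus, function(s) s$mentions$label))))
  if (length(labs) == 0) abort("corpus has no gold mentions; cannot derive a label set")
  label_set(labs)
}
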