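#' Read a corpus in CoNLL-2003 column format
#'
#' Expects the token in the first whitespace-separated column and a BIO tag
#' in the last, with blank lines separating sentences. `-DOCSTART-` records
#' are dropped. Each maximal `B-X I-X ...` run becomes one mention (flat
#' corpora only). Malformed transitions (`I-X` after `O`, or after a run of
#' a different type) are repaired by promoting the `I-X` to `B-X`, the
#' lenient policy of standard CoNLL tooling; a warning reports how many
#' repairs were applied.
#'
#' @param path path to a CoNLL-format file.
#' @return a list of [sentence()] objects (class `nner_corpus`).
#' @export
read_conll <- function(path) {
  lines <- tryCatch(readLines(path, warn = FALSE),
                    error = function(e) abort(paste0("cannot read ", path, ": ",
                                                     conditionMessage(e))))
  sentences <- list()
  toks <- character()
  tags <- character()
  n_repair <- 0L
  flush <- function() {
    if (length(toks) == 0) return()
    parsed <- parse_bio(tags)
    n_repair <<- n_repair + parsed$repairs
    sentences[[length(sentences) + 1L]] <<- sentence(toks, parsed$mentions)
    toks <<- character(); tags <<- character()
  }
  for (ln in lines) {
    if (!nzchar(trimws(ln))) { flush(); next }
    fields <- strsplit(trimws(ln), "\\s+")[[1]]
    if (fields[1] == "-DOCSTART-") next
    toks <- c(toks, fields[1])
    tags <- c(tags, fields[length(fields)])
  }
  flush()
  if (n_repair > 0) {
    warn(paste0("repaired ", n_repair, " dangling I- tag(s) by promotion to B-"))
  }
  new_corpus(sentences)
}

# BIO/BIO2 run extraction with lenient I -> B promotion; 0-based coordinates
parse_bio <- function(tags) {
  starts <- integer(); ends <- integer(); labels <- character()
  cur_start <- NA_integer_; cur_type <- NA_character_
  repairs <- 0L
  close_run <- function(t) {
    if (!is.na(cur_start)) {
      starts <<- c(starts, cur_start); ends <<- c(ends, t - 1L)
      labels <<- c(labels, cur_type)
      cur_start <<- NA_integer_; cur_type <<- NA_character_
    }
  }
  for (t in seq_along(tags)) {
    tag <- tags[t]
    if (tag == "O") { close_run(t - 1L) ; next }
    kind <- substr(tag, 1, 1)
    type <- sub("^[BI]-", "", tag)
    if (kind == "I" && !is.na(cur_type) && type == cur_type) next
    if (kind == "I") repairs <- repairs + 1L  # dangling I- treated as B-
    close_run(t - 1L)
    cur_start <- t - 1L  # 0-based
    cur_type <- type
  }
  close_run(length(tags))
  list(mentions = tibble(start = starts, end = ends, label = labels),
       repairs = repairs)
}

#' Read a nested-annotation corpus in span-JSONL format
#'
#' One JSON record per line:
#' `{"tokens": ["..."], "mentions": [{"start": i, "end": j, "label": "X"}]}`
#' with 0-based token indices and inclusive ends. Mentions may nest; a
#' crossing pair triggers a warning, out-of-range or inverted spans are
#' fatal with the offending line number.
#'
#' @param path path to a JSON-lines file.
#' @return a list of [sentence()] objects (class `nner_corpus`).
#' @export
read_jsonl_spans <- function(path) {
  lines <- tryCatch(readLines(path, warn = FALSE),
                    error = function(e) abort(paste0("cannot read ", path, ": ",
                                                     conditionMessage(e))))
  lines <- lines[nzchar(trimws(lines))]
  sentences <- vector("list", length(lines))
  for (k in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[k], simplifyVector = TRUE),
                    error = function(e) abort(paste0("line ", k, ": not valid JSON")))
    toks <- as.character(rec$tokens)
    m <- rec$mentions
    if (is.null(m) || length(m) == 0) m <- NULL
    sentences[[k]] <- withCallingHandlers(
      tryCatch(sentence(toks, m),
               error = function(e) abort(paste0("line ", k, ": ", conditionMessage(e)))),
      warning = function(w) {
        warn(paste0("line ", k, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      }
    )
  }
  new_corpus(sentences)
}

#' Write a corpus in span-JSONL format
#'
#' Inverse of [read_jsonl_spans()]. Mentions are serialized sorted by
#' `(start, end, label)` and fields appear in a fixed order, so output is
#' byte-deterministic; `write_jsonl_spans()` then [read_jsonl_spans()] is
#' the identity on any valid corpus. A `score` column, when present, is
#' carried along.
#'
#' @param sentences a corpus (list of [sentence()] objects).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_jsonl_spans <- function(sentences, path) {
  con <- tryCatch(file(path, open = "w"),
                  error = function(e) abort(paste0("cannot write ", path, ": ",
                                                   conditionMessage(e))))
  on.exit(close(con))
  for (s in sentences) {
    m <- s$mentions
    ord <- order(m$start, m$end, m$label)
    m <- m[ord, , drop = FALSE]
    ments <- lapply(seq_len(nrow(m)), function(i) {
      rec <- list(start = m$start[i], end = m$end[i], label = m$label[i])
      if ("score" %in% names(m) && !is.na(m$score[i])) rec$score <- m$score[i]
      rec
    })
    rec <- list(tokens = s$tokens, mentions = ments)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Derive per-token boundary labels from gold mentions
#'
#' The auxiliary boundary-detection task is a two-class per-token tagging
#' problem over `{O, I}`. Under the default `"inside"` scheme a token is
#' `I` iff it lies inside any gold mention (IO tagging over the union of
#' mention intervals). Under `"endpoints"` a token is `I` iff it is the
#' start or the end of some mention.
#'
#' @param sentence a [sentence()].
#' @param scheme `"inside"` or `"endpoints"`.
#' @return character vector of `"O"`/`"I"`, one per token.
#' @export
make_boundary_labels <- function(sentence, scheme = c("inside", "endpoints")) {
  scheme <- match.arg(scheme)
  n <- length(sentence$tokens)
  lab <- rep("O", n)
  m <- sentence$mentions
  if (nrow(m) > 0) {
    if (scheme == "inside") {
      for (i in seq_len(nrow(m))) lab[(m$start[i] + 1):(m$end[i] + 1)] <- "I"
    } else {
      lab[unique(c(m$start, m$end)) + 1] <- "I"
    }
  }
  lab
}

#' Build a vocabulary from a corpus
#'
#' Word, character and label index maps with reserved indices 1 (`<pad>`)
#' and 2 (`<unk>`). Words are ordered by frequency then lexicographically,
#' so two runs over the same corpus assign identical indices; words seen
#' fewer than `min_count` times map to `<unk>` at lookup time.
#'
#' @param sentences a corpus.
#' @param min_count minimum token frequency for a dedicated word index.
#' @return object of class `nner_vocab`.
#' @export
build_vocab <- function(sentences, min_count = 1) {
  if (length(sentences) == 0) abort("cannot build a vocabulary from an empty corpus")
  toks <- unlist(lapply(sentences, `[[`, "tokens"))
  tab <- table(toks)
  tab <- tab[tab >= min_count]
  ord <- order(-as.integer(tab), names(tab))
  words <- c("<pad>", "<unk>", names(tab)[ord])
  chars <- sort(unique(unlist(strsplit(unique(toks), ""))))
  chars <- c("<pad>", "<unk>", chars)
  labs <- corpus_label_set(sentences)
  structure(list(
    words = words,
    word_ids = setNames(seq_along(words), words),
    chars = chars,
    char_ids = setNames(seq_along(chars), chars),
    label_set = labs
  ), class = "nner_vocab")
}

#' @export
print.nner_vocab <- function(x, ...) {
  cat("<vocabulary> ", length(x$words) - 2, " words, ", length(x$chars) - 2,
      " characters, ", length(x$label_set$entity_types), " entity types\n", sep = "")
  invisible(x)
}

# 1-based ids for the C++ core; unknown word/char -> index 2
word_indices <- function(tokens, vocab) {
  i <- vocab$word_ids[tokens]
  i[is.na(i)] <- 2L
  unname(i)
}

char_indices <- function(tokens, vocab) {
  lapply(strsplit(tokens, ""), function(cs) {
    i <- vocab$char_ids[cs]
    i[is.na(i)] <- 2L
    as.integer(unname(i))
  })
}

#' Load pretrained word vectors from a text file
#'
#' Standard text format: one entry per line, the token followed by its
#' vector components, whitespace separated. Lines whose component count
#' disagrees with the first line are fatal.
#'
#' @param path path to the vector file.
#' @return numeric matrix with one row per token, row names the tokens.
#' @export
read_word_vectors <- function(path) {
  lines <- tryCatch(readLines(path, warn = FALSE),
                    error = function(e) abort(paste0("cannot read ", path, ": ",
                                                     conditionMessage(e))))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) abort("empty word-vector file")
  parts <- strsplit(lines, "\\s+")
  d <- length(parts[[1]]) - 1L
  bad <- which(lengths(parts) != d + 1L)
  if (length(bad) > 0) abort(paste0("line ", bad[1], ": expected ", d, " components"))
  mat <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(d)))
  rownames(mat) <- vapply(parts, `[[`, character(1), 1)
  mat
}
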