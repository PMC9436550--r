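#' Configuration for the synthetic nested-corpus generator
#'
#' The generator emits sentences over a closed vocabulary in which the
#' mention set is decodable from the surface form alone: every mention
#' begins with a trigger token of its type, its remaining tokens come from
#' a type-specific content vocabulary, a nested child mention uses a
#' different type (hence disjoint trigger and content vocabularies), and
#' non-mention positions use a separate filler vocabulary. A word-level
#' model without any pretrained embeddings can therefore reach
#' near-perfect F1, so end-to-end tests measure the architecture rather
#' than world knowledge.
#'
#' @param n_sentences number of sentences to generate.
#' @param n_types number of entity types `K` (at least 2 when `p_nest > 0`).
#' @param sentence_length inclusive range of sentence lengths in tokens.
#' @param mention_length inclusive range of mention lengths in tokens; the
#'   maximum must be at least 3 when nesting is enabled so a proper child
#'   fits.
#' @param p_mention probability of opening a top-level mention at an
#'   eligible position during the left-to-right generation sweep.
#' @param p_nest probability that a mention receives a properly contained
#'   child mention (recursing to `max_depth`).
#' @param max_depth maximum nesting depth `D` (1 = flat).
#' @param n_triggers trigger tokens per type.
#' @param content_size content tokens per type.
#' @param filler_size size of the filler vocabulary.
#' @param seed RNG seed; generation is deterministic given the seed.
#' @return object of class `nner_synth_config`.
#' @export
synth_config <- function(n_sentences = 2000,
                         n_types = 3,
                         sentence_length = c(6, 14),
                         mention_length = c(2, 5),
                         p_mention = 0.35,
                         p_nest = 0.3,
                         max_depth = 2,
                         n_triggers = 3,
                         content_size = 8,
                         filler_size = 40,
                         seed = 1) {
  if (max_depth < 1) abort("max_depth must be >= 1")
  if (p_nest < 0 || p_nest > 1) abort("p_nest must lie in [0, 1]")
  if (p_nest > 0 && max_depth > 1 && n_types < 2) {
    abort("nesting requires at least 2 entity types (a child takes a different type)")
  }
  if (p_nest > 0 && max_depth > 1 && mention_length[2] < 3) {
    abort("nesting requires mention_length[2] >= 3")
  }
  if (mention_length[1] < 2) abort("mentions need at least 2 tokens (trigger + content)")
  if (mention_length[1] > sentence_length[1]) {
    abort("infeasible config: minimum mention length exceeds minimum sentence length")
  }
  structure(list(
    n_sentences = n_sentences, n_types = n_types,
    sentence_length = sentence_length, mention_length = mention_length,
    p_mention = p_mention, p_nest = p_nest, max_depth = max_depth,
    n_triggers = n_triggers, content_size = content_size,
    filler_size = filler_size, seed = seed
  ), class = "nner_synth_config")
}

synth_types <- function(config) sprintf("TYPE%d", seq_len(config$n_types))

# recursive mention builder; returns tokens plus mentions with 0-based
# offsets relative to the mention start
build_mention <- function(type_i, avail, depth, config) {
  types <- synth_types(config)
  will_nest <- depth < config$max_depth && avail >= 3 && runif(1) < config$p_nest
  min_len <- if (will_nest) 3L else config$mention_length[1]
  max_len <- min(avail, config$mention_length[2])
  len <- if (min_len >= max_len) max_len else sample(min_len:max_len, 1)
  trig <- sprintf("trg%d_%d", type_i, sample.int(config$n_triggers, 1))
  content <- sprintf("cnt%d_%d", type_i,
                     sample.int(config$content_size, len - 1, replace = TRUE))
  toks <- c(trig, content)
  ments <- tibble(start = 0L, end = len - 1L, label = types[type_i])
  if (will_nest) {
    child_type <- sample(setdiff(seq_len(config$n_types), type_i), 1)
    child <- build_mention(child_type, avail = len - 1L, depth = depth + 1L, config)
    clen <- length(child$tokens)
    off <- if (len - clen == 1L) 1L else sample(1:(len - clen), 1)
    toks[(off + 1):(off + clen)] <- child$tokens
    cm <- child$mentions
    cm$start <- cm$start + off
    cm$end <- cm$end + off
    ments <- dplyr::bind_rows(ments, cm)
  }
  list(tokens = toks, mentions = ments)
}

#' Generate a synthetic nested-entity corpus
#'
#' Sentences are built left to right: at each eligible position a top-level
#' mention opens with probability `p_mention`, otherwise a filler token is
#' emitted. Whether a mention nests is decided by an independent
#' `p_nest` coin, and eligibility always leaves room for a child, so the
#' fraction of top-level mentions carrying a child is an unbiased Bernoulli
#' estimate of `p_nest`. Generated mentions never cross.
#'
#' @param config a [synth_config()].
#' @return a corpus (list of [sentence()]) with the label set attached as
#'   attribute `label_set`.
#' @export
generate_corpus <- function(config = synth_config()) {
  set.seed(config$seed)
  # eligibility leaves room for a nested child whenever nesting is possible
  place_min <- if (config$max_depth > 1 && config$p_nest > 0) {
    max(3L, config$mention_length[1])
  } else {
    config$mention_length[1]
  }
  sentences <- vector("list", config$n_sentences)
  for (si in seq_len(config$n_sentences)) {
    n <- sample(config$sentence_length[1]:config$sentence_length[2], 1)
    toks <- character(n)
    ments <- list()
    pos <- 1L
    while (pos <= n) {
      remain <- n - pos + 1L
      if (remain >= place_min && runif(1) < config$p_mention) {
        m <- build_mention(sample.int(config$n_types, 1), avail = remain,
                           depth = 1L, config = config)
        len <- length(m$tokens)
        toks[pos:(pos + len - 1L)] <- m$tokens
        mm <- m$mentions
        mm$start <- mm$start + pos - 1L
        mm$end <- mm$end + pos - 1L
        ments[[length(ments) + 1L]] <- mm
        pos <- pos + len
      } else {
        toks[pos] <- sprintf("w%d", sample.int(config$filler_size, 1))
        pos <- pos + 1L
      }
    }
    sentences[[si]] <- sentence(toks, if (length(ments)) dplyr::bind_rows(ments))
  }
  out <- new_corpus(sentences)
  attr(out, "label_set") <- label_set(synth_types(config))
  out
}

#' Summary statistics of a corpus
#'
#' @param sentences a corpus.
#' @return a list: `n_sentences`, `n_tokens`, `n_mentions`, `types` (tibble
#'   of per-type mention counts), `depth` (tibble histogram of nesting
#'   depths, depth 1 = not contained in any other mention), and
#'   `nesting_rate` (fraction of depth-1 mentions properly containing
#'   another mention).
#' @export
corpus_stats <- function(sentences) {
  all_m <- purrr::map_dfr(seq_along(sentences), function(i) {
    m <- sentences[[i]]$mentions
    if (nrow(m) == 0) return(NULL)
    m$sentence <- i
    m$depth <- mention_depths(m)
    m$has_child <- mention_has_child(m)
    m
  })
  n_tok <- sum(vapply(sentences, function(s) length(s$tokens), integer(1)))
  if (nrow(all_m) == 0) {
    return(list(n_sentences = length(sentences), n_tokens = n_tok,
                n_mentions = 0L,
                types = tibble(label = character(), n = integer()),
                depth = tibble(depth = integer(), n = integer()),
                nesting_rate = NA_real_))
  }
  top <- all_m[all_m$depth == 1L, ]
  list(
    n_sentences = length(sentences),
    n_tokens = n_tok,
    n_mentions = nrow(all_m),
    types = dplyr::count(all_m, .data$label),
    depth = dplyr::count(all_m, .data$depth),
    nesting_rate = mean(top$has_child)
  )
}

# depth = 1 + number of mentions properly containing the mention
mention_depths <- function(m) {
  n <- nrow(m)
  vapply(seq_len(n), function(i) {
    1L + sum(m$start <= m$start[i] & m$end >= m$end[i] &
               (m$end - m$start > m$end[i] - m$start[i]))
  }, integer(1))
}

mention_has_child <- function(m) {
  n <- nrow(m)
  vapply(seq_len(n), function(i) {
    any(m$start >= m$start[i] & m$end <= m$end[i] &
          (m$end - m$start < m$end[i] - m$start[i]))
  }, logical(1))
}
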