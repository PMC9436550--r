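# Independent brute-force oracles used across the suite. These are written
# from the mathematical definitions, not from the package internals.

`%||%` <- function(a, b) if (is.null(a)) b else a

# biaffine score, term by term: s_i' U1_c e_j + U2 [s_i; e_j] + b_c
oracle_biaffine <- function(s, e, U1, U2, b, maxlen, bias_aug) {
  n <- ncol(s)
  n_class <- dim(U1)[3]
  out <- array(NA_real_, dim = c(n, n, n_class))
  for (i in seq_len(n)) for (j in i:n) {
    if (j - i + 1 > maxlen) next
    si <- s[, i]; ej <- e[, j]
    if (bias_aug) { si <- c(si, 1); ej <- c(ej, 1) }
    for (cc in seq_len(n_class)) {
      bil <- 0
      for (a in seq_along(si)) for (bb in seq_along(ej)) {
        bil <- bil + si[a] * U1[a, bb, cc] * ej[bb]
      }
      lin <- sum(U2[cc, ] * c(s[, i], e[, j]))
      out[i, j, cc] <- bil + lin + b[cc]
    }
  }
  out
}

# overlap-without-containment predicate from interval arithmetic
oracle_crossing <- function(s1, e1, s2, e2) {
  overlap <- min(e1, e2) - max(s1, s2) >= 0
  contains_12 <- s1 <= s2 && e2 <= e1
  contains_21 <- s2 <= s1 && e1 <= e2
  overlap && !contains_12 && !contains_21
}

# descending-order keep rule, simulated literally
oracle_resolve <- function(cand) {
  ord <- order(-cand$score, cand$start, cand$end, cand$label)
  cand <- cand[ord, , drop = FALSE]
  kept <- cand[0, , drop = FALSE]
  for (k in seq_len(nrow(cand))) {
    blocked <- FALSE
    for (q in seq_len(nrow(kept))) {
      if (oracle_crossing(cand$start[k], cand$end[k], kept$start[q], kept$end[q])) {
        blocked <- TRUE
        break
      }
    }
    if (!blocked) kept <- rbind(kept, cand[k, , drop = FALSE])
  }
  kept
}

# token membership in the union of mention intervals
oracle_inside_labels <- function(n, mentions) {
  covered <- rep(FALSE, n)
  for (i in seq_len(nrow(mentions))) {
    for (t in mentions$start[i]:mentions$end[i]) covered[t + 1] <- TRUE
  }
  ifelse(covered, "I", "O")
}

# set-algebra match counts by explicit pairwise comparison
oracle_match <- function(pred, gold) {
  tp <- 0
  for (i in seq_len(nrow(pred))) {
    hit <- FALSE
    for (j in seq_len(nrow(gold))) {
      if (pred$start[i] == gold$start[j] && pred$end[i] == gold$end[j] &&
          pred$label[i] == gold$label[j]) hit <- TRUE
    }
    if (hit) tp <- tp + 1
  }
  c(tp = tp, fp = nrow(pred) - tp, fn = nrow(gold) - tp)
}

# random non-crossing mention set over n tokens (for boundary-label tests)
random_mentions <- function(n, n_mentions = sample(0:4, 1), labels = c("A", "B")) {
  rows <- list()
  for (k in seq_len(n_mentions)) {
    s <- sample.int(n, 1) - 1L
    e <- min(n - 1L, s + sample.int(4, 1) - 1L)
    rows[[k]] <- tibble::tibble(start = s, end = e, label = sample(labels, 1))
  }
  if (length(rows) == 0) return(NULL)
  m <- dplyr::bind_rows(rows)
  m[!duplicated(paste(m$start, m$end, m$label)), , drop = FALSE]
}

# tiny deterministic model fixture shared by encoder/biaffine/decoder tests
tiny_setup <- function(seed = 5, n_sentences = 6, ...) {
  cfg <- model_config(word_dim = 5, use_char = TRUE, char_dim = 3,
                      char_widths = c(2, 3), char_filters = 2,
                      lstm_size = 6, lstm_layers = 2, mlp_size = 4,
                      emb_dropout = 0, lstm_dropout = 0, mlp_dropout = 0,
                      seed = seed, ...)
  corp <- generate_corpus(synth_config(n_sentences = n_sentences, seed = seed + 1))
  vocab <- build_vocab(corp)
  params <- init_model(cfg, vocab)
  list(cfg = cfg, corpus = corp, vocab = vocab, params = params,
       lab_set = vocab$label_set)
}

# per-sentence loss/grad through the training core, defaults to eval mode
sent_grad <- function(s, setup, training = FALSE, alpha = 1, mask = NULL) {
  cfg <- setup$cfg
  cfg$alpha <- alpha
  prep <- nestner:::prepare_sentence(s, setup$vocab, cfg, setup$lab_set)
  ccfg <- nestner:::cfg_for_cpp(cfg, length(setup$lab_set$entity_types) + 1L,
                                prep$n, training = training)
  nestner:::cpp_sentence_grad(prep$word, prep$chars, NULL, prep$gold,
                              prep$boundary, mask %||% prep$mask, setup$params, ccfg)
}
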