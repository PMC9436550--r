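glorot <- function(nr, nc) {
  s <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -s, s), nr, nc)
}

#' Initialize model parameters
#'
#' Draws all trainable parameters for the given configuration and
#' vocabulary: embedding tables, character-CNN filters, the BiLSTM stack,
#' the head/tail MLPs, the biaffine tensor `U1` (bias-augmented to
#' `(m+1) x (m+1) x C'` when `bias_aug` is on), the linear map `U2`, and
#' the boundary head. Weight matrices use Glorot-uniform draws, biases are
#' zero except LSTM forget gates (initialized to 1), and `set.seed` is
#' called with `config$seed` so initialization is reproducible.
#'
#' @param config a [model_config()].
#' @param vocab a [build_vocab()] vocabulary.
#' @param pretrained optional word-vector matrix (row names = tokens) used
#'   to seed matching rows of the word table; its width must equal
#'   `config$word_dim`.
#' @return named list of parameter arrays (class `nner_params`).
#' @export
init_model <- function(config, vocab, pretrained = NULL) {
  set.seed(config$seed)
  C <- length(vocab$label_set$entity_types)
  n_class <- C + 1L
  m <- config$mlp_size
  h <- config$lstm_size %/% 2L
  p <- list()
  p$E_word <- matrix(runif(length(vocab$words) * config$word_dim, -0.1, 0.1),
                     length(vocab$words), config$word_dim)
  if (!is.null(pretrained)) {
    if (ncol(pretrained) != config$word_dim) {
      abort("pretrained vector width does not match word_dim")
    }
    hit <- intersect(rownames(pretrained), vocab$words)
    p$E_word[match(hit, vocab$words), ] <- pretrained[hit, , drop = FALSE]
  }
  char_block <- 0L
  if (config$use_char) {
    p$E_char <- matrix(runif(length(vocab$chars) * config$char_dim, -0.1, 0.1),
                       length(vocab$chars), config$char_dim)
    for (k in config$char_widths) {
      p[[paste0("conv_W", k)]] <- glorot(config$char_filters, config$char_dim * k)
      p[[paste0("conv_b", k)]] <- rep(0, config$char_filters)
    }
    char_block <- config$char_filters * length(config$char_widths)
  }
  d_in <- config$lm_dim + char_block + config$word_dim
  for (l in seq_len(config$lstm_layers)) {
    din_l <- if (l == 1) d_in else config$lstm_size
    for (dir in c("f", "b")) {
      b <- rep(0, 4 * h)
      b[(h + 1):(2 * h)] <- 1  # forget-gate bias
      p[[sprintf("lstm_W_%s_%d", dir, l)]] <- glorot(4 * h, din_l)
      p[[sprintf("lstm_R_%s_%d", dir, l)]] <- glorot(4 * h, h)
      p[[sprintf("lstm_b_%s_%d", dir, l)]] <- b
    }
  }
  p$mlp_s_W <- glorot(m, config$lstm_size)
  p$mlp_s_b <- rep(0, m)
  p$mlp_e_W <- glorot(m, config$lstm_size)
  p$mlp_e_b <- rep(0, m)
  m1 <- m + as.integer(config$bias_aug)
  s1 <- sqrt(6 / (m1 + m1))
  p$U1 <- array(runif(m1 * m1 * n_class, -s1, s1), dim = c(m1, m1, n_class))
  p$U2 <- glorot(n_class, 2 * m)
  p$b_span <- rep(0, n_class)
  p$U_bnd <- glorot(2, 2 * m)
  p$b_bnd <- rep(0, 2)
  structure(p, class = "nner_params")
}

label_index <- function(labels, lab_set) {
  i <- match(labels, lab_set$entity_types)
  if (anyNA(i)) abort(paste0("label(s) outside the label set: ",
                             paste(unique(labels[is.na(i)]), collapse = ", ")))
  i
}

# N x N integer matrix of 1-based gold class indices for enumerated spans
# (n_class = non-entity); gold mentions longer than the span limit are
# excluded with a warning
gold_span_matrix <- function(sentence, lab_set, limit = Inf) {
  n <- length(sentence$tokens)
  n_class <- length(lab_set$entity_types) + 1L
  g <- matrix(n_class, n, n)
  m <- sentence$mentions
  if (nrow(m) > 0) {
    too_long <- (m$end - m$start + 1L) > limit
    if (any(too_long)) {
      warn(paste0(sum(too_long), " gold mention(s) exceed the span limit ",
                  limit, " and are excluded from the span loss"))
      m <- m[!too_long, , drop = FALSE]
    }
    ci <- label_index(m$label, lab_set)
    for (i in seq_len(nrow(m))) {
      if (g[m$start[i] + 1L, m$end[i] + 1L] != n_class) next  # first label wins
      g[m$start[i] + 1L, m$end[i] + 1L] <- ci[i]
    }
  }
  g
}

# ---------------------------------------------------------------------------
# Encoder operations
# ---------------------------------------------------------------------------

#' Character-CNN vector for one word
#'
#' Embeds the characters of `word`, runs one 1-D convolution per filter
#' width over the character sequence (words shorter than a width are
#' zero-padded), max-pools each filter over positions and concatenates
#' across widths.
#'
#' @param word a single character string (non-empty).
#' @param params model parameters ([init_model()]).
#' @param config the model configuration.
#' @param vocab the vocabulary (characters outside it use the unknown
#'   index).
#' @return numeric vector of width `char_filters * length(char_widths)`.
#' @export
char_cnn <- function(word, params, config, vocab) {
  if (!nzchar(word)) abort("char_cnn needs a non-empty word")
  ch <- char_indices(word, vocab)[[1]]
  cw <- lapply(config$char_widths, function(k) params[[paste0("conv_W", k)]])
  cb <- lapply(config$char_widths, function(k) params[[paste0("conv_b", k)]])
  drop(cpp_char_cnn(ch, params$E_char, cw, cb, config$char_widths))
}

#' Concatenated token embeddings for a sentence
#'
#' Builds `X_t = [X_t^lm ; X_t^char ; X_t^word]` (contextual block first,
#' then character CNN, then word lookup). When no contextual embedder is
#' supplied the `lm` block is omitted entirely.
#'
#' @param sentence a [sentence()].
#' @param params,config,vocab model parameters, configuration, vocabulary.
#' @param lm optional contextual embedding matrix (`lm_dim` rows, one
#'   column per token); its column count must equal the sentence length.
#' @return numeric matrix, features in rows and tokens in columns.
#' @export
embed_tokens <- function(sentence, params, config, vocab, lm = NULL) {
  lm <- check_lm(lm, length(sentence$tokens))
  enc <- cpp_encode(word_indices(sentence$tokens, vocab),
                    char_indices(sentence$tokens, vocab), lm,
                    params, cfg_for_cpp(config, n_class_of(params), length(sentence$tokens)))
  enc$X
}

check_lm <- function(lm, n_tokens) {
  if (is.null(lm)) return(NULL)
  if (ncol(lm) != n_tokens) {
    abort("contextual embedder returned the wrong sequence length")
  }
  lm
}

n_class_of <- function(params) dim(params$U1)[3]

#' BiLSTM encoding of an embedded sentence
#'
#' Runs the stacked bidirectional LSTM over an input matrix and returns
#' per-token hidden states `h_t`, the concatenation of the forward and
#' backward states (evaluation mode: no dropout, so repeated calls are
#' bit-identical).
#'
#' @param X input matrix, features in rows and tokens in columns.
#' @param params,config model parameters and configuration.
#' @return matrix of size `lstm_size` x N.
#' @export
bilstm_encode <- function(X, params, config) {
  cpp_bilstm(X, params, config$lstm_layers, config$lstm_size %/% 2L)
}

#' Head and tail span projections
#'
#' Projects each hidden state through two independent MLPs into the head
#' representation `s(t)` and tail representation `e(t)` (width
#' `mlp_size`, ReLU activation). The per-token softmax of the literal
#' formulation is exposed as the auxiliary outputs `s_prob`, `e_prob`;
#' the representations fed onward are governed by `config$span_repr`.
#'
#' @param H BiLSTM output matrix (`lstm_size` x N).
#' @param params,config model parameters and configuration.
#' @return list with `s`, `e` (the span representations) and `s_prob`,
#'   `e_prob` (per-token softmax over the projection units).
#' @export
head_tail_project <- function(H, params, config) {
  pr <- cpp_project(H, params$mlp_s_W, params$mlp_s_b,
                    params$mlp_e_W, params$mlp_e_b,
                    identical(config$span_repr, "post_softmax"))
  act <- cpp_project(H, params$mlp_s_W, params$mlp_s_b,
                     params$mlp_e_W, params$mlp_e_b, FALSE)
  list(s = pr$s, e = pr$e,
       s_prob = apply(act$s, 2, softmax), e_prob = apply(act$e, 2, softmax))
}

softmax <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

# ---------------------------------------------------------------------------
# Biaffine span classification
# ---------------------------------------------------------------------------

#' Biaffine span scores
#'
#' Scores every candidate span `(i, j)` with `i <= j` (and span length up
#' to the configured limit) for every class:
#' `r_m(i, j, .) = s(i)' U1 e(j) + U2 [s(i) ; e(j)] + b`.
#' With `bias_aug` the representations are extended by a constant-1
#' coordinate inside the bilinear term.
#'
#' @param s,e head/tail representation matrices (`mlp_size` x N).
#' @param params,config model parameters and configuration.
#' @return array `N x N x C'` of scores (1-based: `[i, j, c]` scores the
#'   0-based span `(i-1, j-1)`); entries outside the enumeration are `NA`.
#' @export
score_spans <- function(s, e, params, config) {
  n <- ncol(s)
  out <- cpp_score_spans(s, e, params$U1, params$U2, params$b_span,
                         min(effective_span_limit(config, n), n), config$bias_aug)
  array(out, dim = c(n, n, n_class_of(params)))
}

#' Per-span class distributions
#'
#' Softmax over classes for every enumerated span of a score tensor.
#'
#' @param scores array from [score_spans()].
#' @return array of the same shape; each valid `[i, j, ]` slice sums to 1.
#' @export
span_class_probs <- function(scores) {
  out <- scores
  n <- dim(scores)[1]
  for (i in seq_len(n)) for (j in i:n) {
    v <- scores[i, j, ]
    if (!anyNA(v)) out[i, j, ] <- softmax(v)
  }
  out
}

#' Span-classification loss
#'
#' Softmax cross-entropy of the gold class over enumerated spans, where
#' every span not covered by a gold mention takes the non-entity class.
#' Reduction is the mean over enumerated spans by default (`"sum"` gives
#' the literal summed objective).
#'
#' @param probs array from [span_class_probs()].
#' @param gold integer matrix of 1-based gold class indices (see
#'   `gold_span_matrix`); entries at non-enumerated spans are ignored.
#' @param reduction `"mean"` or `"sum"`.
#' @return scalar loss.
#' @export
span_classification_loss <- function(probs, gold, reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  n <- dim(probs)[1]
  terms <- c()
  for (i in seq_len(n)) for (j in i:n) {
    v <- probs[i, j, ]
    if (anyNA(v)) next
    terms <- c(terms, -log(v[gold[i, j]]))
  }
  if (reduction == "mean") mean(terms) else sum(terms)
}

# ---------------------------------------------------------------------------
# Boundary detection head
# ---------------------------------------------------------------------------

#' Boundary-detection logits
#'
#' Per-token logits `O_t = U g([s(t) ; e(t)]) + b` over the two boundary
#' classes, where `g` is ReLU under the default activation setting and the
#' identity otherwise. Class order is fixed as (O, I).
#'
#' @param s,e head/tail representation matrices.
#' @param params,config model parameters and configuration.
#' @return 2 x N matrix of logits, rows (O, I).
#' @export
boundary_logits <- function(s, e, params, config) {
  out <- cpp_boundary_logits(s, e, params$U_bnd, params$b_bnd,
                             identical(config$boundary_activation, "relu"))
  rownames(out) <- c("O", "I")
  out
}

#' Boundary probabilities
#'
#' Per-token softmax of the boundary logits.
#'
#' @param logits 2 x N matrix from [boundary_logits()].
#' @return N x 2 matrix with columns `O` and `I`; rows sum to 1.
#' @export
boundary_probs <- function(logits) {
  out <- t(apply(logits, 2, softmax))
  colnames(out) <- c("O", "I")
  out
}

#' Boundary-detection loss
#'
#' Cross-entropy between predicted per-token boundary distributions and
#' gold `{O, I}` labels, averaged over tokens (or summed).
#'
#' @param d N x 2 probability matrix from [boundary_probs()].
#' @param gold character vector of gold labels (`"O"`/`"I"`), same length.
#' @param reduction `"mean"` or `"sum"`.
#' @return scalar loss.
#' @export
boundary_loss <- function(d, gold, reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  if (nrow(d) != length(gold)) abort("boundary prediction/gold length mismatch")
  p <- ifelse(gold == "I", d[, "I"], d[, "O"])
  if (reduction == "mean") mean(-log(p)) else sum(-log(p))
}

#' Multi-task loss
#'
#' `Multi_Loss = loss_b + alpha * loss_d`: the span-classification loss
#' plus the boundary-detection loss at mixing ratio `alpha >= 0`. With
#' `alpha = 0` the objective is exactly the single-task biaffine baseline.
#'
#' @param loss_b span-classification loss.
#' @param loss_d boundary-detection loss.
#' @param alpha mixing ratio (>= 0).
#' @return scalar total loss.
#' @export
multi_task_loss <- function(loss_b, loss_d, alpha) {
  if (alpha < 0) abort("alpha must be >= 0")
  loss_b + alpha * loss_d
}

# full evaluation-mode forward pass for one sentence
nner_forward <- function(sentence, params, config, vocab, lm = NULL) {
  lm <- check_lm(lm, length(sentence$tokens))
  n <- length(sentence$tokens)
  out <- cpp_sentence_forward(word_indices(sentence$tokens, vocab),
                              char_indices(sentence$tokens, vocab), lm, params,
                              cfg_for_cpp(config, n_class_of(params), n))
  scores <- array(out$scores, dim = c(n, n, n_class_of(params)))
  boundary <- out$boundary
  colnames(boundary) <- c("O", "I")
  list(scores = scores, boundary = boundary)
}
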