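#' Model and training configuration
#'
#' Defaults follow the reference hyperparameter setting of the method:
#' 3-layer BiLSTM of total output width 200 (100 per direction) with
#' dropout 0.4, head/tail MLPs of width 150 with dropout 0.2, character
#' CNN with filter widths 3-5 over 50-dimensional character embeddings,
#' 300-dimensional word embeddings, dropout 0.5 on the concatenated
#' embedding, and Adam at learning rate 0.001. The optional external
#' contextual-embedding block (width `lm_dim`, conventionally 1024) is
#' disabled by default; when disabled the block is omitted from the
#' concatenation, not zero-filled.
#'
#' @param word_dim word-embedding width.
#' @param use_char whether to include the character-CNN block.
#' @param char_dim character-embedding width.
#' @param char_widths integer vector of CNN filter widths.
#' @param char_filters filters per width (the character block is
#'   `char_filters * length(char_widths)` wide).
#' @param lm_dim width of the optional external contextual embedding block;
#'   0 disables it.
#' @param lstm_size total BiLSTM output width (split evenly across the two
#'   directions).
#' @param lstm_layers number of stacked BiLSTM layers.
#' @param lstm_dropout dropout between BiLSTM layers (training only).
#' @param mlp_size width of the head and tail projections `s(t)`, `e(t)`.
#' @param mlp_dropout dropout on the projections (training only).
#' @param emb_dropout dropout on the concatenated embedding (training only).
#' @param learning_rate Adam learning rate.
#' @param alpha mixing ratio of the boundary loss in
#'   `Multi_Loss = loss_b + alpha * loss_d`; must be >= 0. `alpha = 0` is
#'   the single-task biaffine baseline.
#' @param batch_size sentences per optimizer step (gradients are averaged).
#' @param epochs maximum training epochs.
#' @param patience early-stopping patience on held-out F1.
#' @param seed RNG seed for initialization, shuffling and dropout.
#' @param max_span_length maximum candidate span length `L`; `NA` means
#'   unbounded for sentences up to 64 tokens and 16 beyond that (the
#'   enumeration is O(N^2)).
#' @param gate_threshold boundary-gate probability threshold at test time.
#' @param boundary_scheme `"inside"` (IO tagging over mention intervals) or
#'   `"endpoints"` (I marks mention starts/ends).
#' @param use_gate whether decoding filters candidates through the boundary
#'   gate.
#' @param bias_aug augment `s` and `e` with a constant-1 coordinate inside
#'   the bilinear term (standard biaffine practice); `FALSE` gives the
#'   strict bilinear reading.
#' @param span_repr `"pre_softmax"` uses the raw MLP outputs as span
#'   representations; `"post_softmax"` applies the literal per-token
#'   softmax first.
#' @param boundary_activation `"relu"` applies ReLU to `[s(t), e(t)]`
#'   before the boundary linear map; `"none"` is the plain affine form.
#' @param loss_reduction `"mean"` (per enumerated span / per token, so
#'   `alpha` is length-independent) or `"sum"` (the literal summed form).
#' @param rank_by overlap resolution ranks candidates by raw winning-class
#'   `"score"` or softmax `"probability"`.
#' @param train_gate `"decode"` trains the span loss over all enumerated
#'   spans and uses gold boundaries only for decoding-time gating;
#'   `"loss"` additionally restricts the span loss to gold-gated spans.
#' @param min_count vocabulary frequency cutoff.
#' @return object of class `nner_config` (a validated list).
#' @export
model_config <- function(word_dim = 300,
                         use_char = TRUE,
                         char_dim = 50,
                         char_widths = c(3, 4, 5),
                         char_filters = 50,
                         lm_dim = 0,
                         lstm_size = 200,
                         lstm_layers = 3,
                         lstm_dropout = 0.4,
                         mlp_size = 150,
                         mlp_dropout = 0.2,
                         emb_dropout = 0.5,
                         learning_rate = 0.001,
                         alpha = 1,
                         batch_size = 16,
                         epochs = 20,
                         patience = 5,
                         seed = 42,
                         max_span_length = NA,
                         gate_threshold = 0.5,
                         boundary_scheme = c("inside", "endpoints"),
                         use_gate = TRUE,
                         bias_aug = TRUE,
                         span_repr = c("pre_softmax", "post_softmax"),
                         boundary_activation = c("relu", "none"),
                         loss_reduction = c("mean", "sum"),
                         rank_by = c("score", "probability"),
                         train_gate = c("decode", "loss"),
                         min_count = 1) {
  if (alpha < 0) abort("alpha must be >= 0")
  if (lstm_size %% 2 != 0) abort("lstm_size must be even (two directions)")
  cfg <- list(
    word_dim = as.integer(word_dim), use_char = isTRUE(use_char),
    char_dim = as.integer(char_dim), char_widths = as.integer(char_widths),
    char_filters = as.integer(char_filters), lm_dim = as.integer(lm_dim),
    lstm_size = as.integer(lstm_size), lstm_layers = as.integer(lstm_layers),
    lstm_dropout = lstm_dropout, mlp_size = as.integer(mlp_size),
    mlp_dropout = mlp_dropout, emb_dropout = emb_dropout,
    learning_rate = learning_rate, alpha = alpha,
    batch_size = as.integer(batch_size), epochs = as.integer(epochs),
    patience = as.integer(patience), seed = as.integer(seed),
    max_span_length = if (is.na(max_span_length)) NA_integer_ else as.integer(max_span_length),
    gate_threshold = gate_threshold,
    boundary_scheme = match.arg(boundary_scheme),
    use_gate = isTRUE(use_gate), bias_aug = isTRUE(bias_aug),
    span_repr = match.arg(span_repr),
    boundary_activation = match.arg(boundary_activation),
    loss_reduction = match.arg(loss_reduction),
    rank_by = match.arg(rank_by),
    train_gate = match.arg(train_gate),
    min_count = as.integer(min_count)
  )
  structure(cfg, class = "nner_config")
}

#' Reduced-width configuration for CPU-scale experiments
#'
#' The reference widths (BiLSTM 200 x 3 layers, MLP 150, 300-wide word
#' vectors plus a character CNN) are sized for GPU training on large
#' benchmark corpora. For synthetic-corpus experiments on one CPU the
#' package uses this preset: a single BiLSTM layer of width 64, MLP width
#' 32, 32-wide trainable word embeddings and no character CNN (the
#' synthetic vocabulary carries its type signal at the word level), with
#' correspondingly lighter dropout. All other semantics are identical.
#'
#' @param ... overrides passed on to [model_config()].
#' @return an `nner_config`.
#' @export
small_model_config <- function(...) {
  defaults <- list(word_dim = 32, use_char = FALSE, lstm_size = 64,
                   lstm_layers = 1, mlp_size = 32, emb_dropout = 0.2,
                   lstm_dropout = 0, mlp_dropout = 0.1)
  args <- utils::modifyList(defaults, list(...))
  do.call(model_config, args)
}

#' Read / write a configuration as YAML
#'
#' Round-trips exactly: `read_model_config(write_model_config(cfg, path))`
#' equals `cfg`.
#'
#' @param config an [model_config()] object.
#' @param path file path.
#' @return the configuration (read) or `path` invisibly (write).
#' @export
write_model_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$max_span_length <- raw$max_span_length %||% NA
  do.call(model_config, raw)
}

# span length cap for a sentence of length n
effective_span_limit <- function(config, n) {
  if (!is.na(config$max_span_length)) return(config$max_span_length)
  if (n <= 64) n else 16L
}

# flag list consumed by the C++ core
cfg_for_cpp <- function(config, n_class, n_tokens, training = FALSE) {
  list(
    lstm_layers = config$lstm_layers,
    hidden_per_dir = config$lstm_size %/% 2L,
    mlp_size = config$mlp_size,
    n_class = as.integer(n_class),
    max_span_length = as.integer(effective_span_limit(config, n_tokens)),
    use_char = config$use_char,
    bias_aug = config$bias_aug,
    post_softmax = identical(config$span_repr, "post_softmax"),
    boundary_relu = identical(config$boundary_activation, "relu"),
    loss_sum = identical(config$loss_reduction, "sum"),
    training = isTRUE(training),
    alpha = config$alpha,
    emb_dropout = config$emb_dropout,
    lstm_dropout = config$lstm_dropout,
    mlp_dropout = config$mlp_dropout,
    char_widths = config$char_widths
  )
}
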