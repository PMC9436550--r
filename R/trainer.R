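new_adam_state <- function(params) {
  zero_like <- lapply(params, function(p) array(0, dim = dim(p) %||% length(p)))
  list(m = zero_like, v = zero_like, t = 0L)
}

# one Adam update from (already averaged) gradients, with global-norm
# clipping at 5 for stability
adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8, clip = 5) {
  gnorm <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  scale <- if (is.finite(gnorm) && gnorm > clip) clip / gnorm else 1
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]] * scale
    if (is.null(dim(params[[nm]]))) dim(g) <- NULL
    dim(state$m[[nm]]) <- dim(g); dim(state$v[[nm]]) <- dim(g)
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# tokenized + indexed view of a sentence plus its training targets
prepare_sentence <- function(sentence, vocab, config, lab_set) {
  n <- length(sentence$tokens)
  limit <- effective_span_limit(config, n)
  blab <- make_boundary_labels(sentence, config$boundary_scheme)
  mask <- NULL
  if (identical(config$train_gate, "loss")) {
    inside <- as.integer(blab == "I")
    mask <- outer(inside, inside, function(a, b) as.integer(a & b))
  }
  list(
    word = word_indices(sentence$tokens, vocab),
    chars = char_indices(sentence$tokens, vocab),
    gold = gold_span_matrix(sentence, lab_set, limit) - 1L,  # 0-based for C++
    boundary = as.integer(blab == "I"),
    mask = mask,
    n = n
  )
}

#' Train the joint span-classification + boundary-detection model
#'
#' Joint optimization of the biaffine span classifier and the auxiliary
#' boundary detector under `Multi_Loss = loss_b + alpha * loss_d`. Each
#' epoch shuffles the corpus, accumulates per-sentence gradients over
#' batches of `batch_size` and takes one Adam step per batch. The span
#' loss covers every enumerated span (gold assignment from the gold
#' mentions, non-entity elsewhere); the boundary loss targets gold labels
#' derived by [make_boundary_labels()]. Boundary gating during held-out
#' evaluation uses the *predicted* boundary probabilities — gold
#' boundaries are only ever used for the training targets, so the
#' train/test regime matches deployment.
#'
#' With a held-out corpus, entity-level micro P/R/F1 is computed each
#' epoch and training stops early when F1 has not improved for
#' `patience` epochs (the best parameters are kept).
#'
#' @param corpus training corpus with gold mentions.
#' @param config a [model_config()].
#' @param heldout optional held-out corpus for per-epoch evaluation and
#'   early stopping.
#' @param vocab optional pre-built vocabulary (built from `corpus`
#'   otherwise).
#' @param pretrained optional pretrained word-vector matrix passed to
#'   [init_model()].
#' @param verbose print per-epoch progress.
#' @return object of class `nner_fit`: parameters, config, vocabulary,
#'   label set, and a per-epoch `log` tibble (losses and held-out
#'   metrics).
#' @export
ner_train <- function(corpus, config = model_config(), heldout = NULL,
                      vocab = NULL, pretrained = NULL, verbose = FALSE) {
  vocab <- vocab %||% build_vocab(corpus, config$min_count)
  lab_set <- vocab$label_set
  n_class <- length(lab_set$entity_types) + 1L
  params <- init_model(config, vocab, pretrained)  # seeds the RNG stream
  state <- new_adam_state(params)
  prep <- suppressWarnings(
    lapply(corpus, prepare_sentence, vocab = vocab, config = config, lab_set = lab_set)
  )
  log_rows <- list()
  best <- list(f1 = -Inf, params = params, epoch = 0L)
  stale <- 0L
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(length(prep))
    sum_b <- 0; sum_d <- 0; nb <- 0L
    for (b0 in seq(1, length(ord), by = config$batch_size)) {
      batch <- ord[b0:min(b0 + config$batch_size - 1L, length(ord))]
      acc <- NULL
      for (si in batch) {
        ps <- prep[[si]]
        cfg <- cfg_for_cpp(config, n_class, ps$n, training = TRUE)
        out <- cpp_sentence_grad(ps$word, ps$chars, NULL, ps$gold, ps$boundary,
                                 ps$mask, params, cfg)
        if (!is.finite(out$loss_b) || !is.finite(out$loss_d)) {
          abort(paste0("non-finite loss at epoch ", epoch, ", sentence ", si,
                       " (loss_b = ", out$loss_b, ", loss_d = ", out$loss_d, ")"))
        }
        sum_b <- sum_b + out$loss_b; sum_d <- sum_d + out$loss_d; nb <- nb + 1L
        acc <- if (is.null(acc)) out$grads else {
          for (nm in names(out$grads)) acc[[nm]] <- acc[[nm]] + out$grads[[nm]]
          acc
        }
      }
      for (nm in names(acc)) acc[[nm]] <- acc[[nm]] / length(batch)
      upd <- adam_step(params, acc, state, config$learning_rate)
      params <- upd$params; state <- upd$state
    }
    row <- tibble(epoch = epoch, loss_b = sum_b / nb, loss_d = sum_d / nb,
                  multi_loss = sum_b / nb + config$alpha * sum_d / nb,
                  precision = NA_real_, recall = NA_real_, f1 = NA_real_)
    if (!is.null(heldout)) {
      preds <- predict_corpus(params, config, vocab, heldout)
      ev <- ner_evaluate(preds, heldout)
      row$precision <- ev$overall$precision
      row$recall <- ev$overall$recall
      row$f1 <- ev$overall$f1
      if (row$f1 > best$f1) {
        best <- list(f1 = row$f1, params = params, epoch = epoch)
        stale <- 0L
      } else {
        stale <- stale + 1L
      }
    }
    log_rows[[epoch]] <- row
    if (verbose) {
      message(sprintf("epoch %d  loss_b %.4f  loss_d %.4f  f1 %s", epoch,
                      row$loss_b, row$loss_d,
                      if (is.na(row$f1)) "-" else sprintf("%.4f", row$f1)))
    }
    if (!is.null(heldout) && (stale >= config$patience || best$f1 >= 1)) break
  }
  structure(list(
    params = if (!is.null(heldout)) best$params else params,
    final_params = params,
    config = config, vocab = vocab, label_set = lab_set,
    log = dplyr::bind_rows(log_rows),
    best_f1 = if (is.null(heldout)) NA_real_ else best$f1,
    best_epoch = best$epoch,
    epochs_run = length(log_rows)
  ), class = "nner_fit")
}

predict_corpus <- function(params, config, vocab, sentences) {
  lab_set <- vocab$label_set
  lapply(sentences, function(s) {
    fw <- nner_forward(s, params, config, vocab)
    decode_sentence(fw, lab_set, config)
  })
}

#' Predict mentions for new sentences
#'
#' Evaluation-mode inference: encode, score all candidate spans, gate
#' through the *predicted* boundary probabilities (when gating is
#' enabled), and resolve overlaps. Deterministic: no dropout is active.
#'
#' @param object a fitted `nner_fit`.
#' @param newdata a corpus (list of [sentence()] objects).
#' @param ... unused.
#' @return list of prediction tibbles (`start`, `end`, `label`, `score`),
#'   one per sentence.
#' @export
predict.nner_fit <- function(object, newdata, ...) {
  predict_corpus(object$params, object$config, object$vocab, newdata)
}

#' Predicted boundary probabilities for new sentences
#'
#' Evaluation-mode output of the auxiliary boundary-detection head.
#'
#' @param object a fitted `nner_fit`.
#' @param newdata a corpus.
#' @return list of N x 2 probability matrices (columns `O`, `I`), one per
#'   sentence.
#' @export
predict_boundaries <- function(object, newdata) {
  lapply(newdata, function(s) {
    nner_forward(s, object$params, object$config, object$vocab)$boundary
  })
}

#' @export
print.nner_fit <- function(x, ...) {
  cat("<nner_fit> ", length(x$label_set$entity_types), " entity types, ",
      x$epochs_run, " epochs", sep = "")
  if (!is.na(x$best_f1)) cat(sprintf(", best held-out F1 %.4f (epoch %d)",
                                     x$best_f1, x$best_epoch))
  cat("\n")
  invisible(x)
}

#' Tidy the training log of a fit
#'
#' @param x a `nner_fit`.
#' @param ... unused.
#' @return the per-epoch log as a tibble: losses and (with a held-out set)
#'   precision, recall and F1.
#' @export
tidy.nner_fit <- function(x, ...) x$log

#' One-row summary of a fit
#'
#' @param x a `nner_fit`.
#' @param ... unused.
#' @return tibble with epochs run, final losses and best held-out F1.
#' @export
glance.nner_fit <- function(x, ...) {
  last <- x$log[nrow(x$log), ]
  tibble(epochs = x$epochs_run, loss_b = last$loss_b, loss_d = last$loss_d,
         multi_loss = last$multi_loss, best_f1 = x$best_f1,
         best_epoch = x$best_epoch,
         n_parameters = sum(vapply(x$params, length, integer(1))))
}

#' Training-curve plot for a fit
#'
#' Loss curves (span, boundary, combined) and, when available, held-out
#' F1 against the epoch number.
#'
#' @param object a `nner_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.nner_fit <- function(object, ...) {
  log <- object$log
  long <- dplyr::bind_rows(
    tibble(epoch = log$epoch, metric = "loss_b", value = log$loss_b),
    tibble(epoch = log$epoch, metric = "loss_d", value = log$loss_d),
    tibble(epoch = log$epoch, metric = "multi_loss", value = log$multi_loss),
    if (!all(is.na(log$f1))) tibble(epoch = log$epoch, metric = "held-out F1",
                                    value = log$f1)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
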