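#' Candidate mentions from a span score tensor
#'
#' For every enumerated span, takes the class with the highest score
#' (argmax over the `C + 1` classes) and keeps the span as a candidate iff
#' that class is an entity type, i.e. spans whose best class is
#' non-entity are discarded. The candidate's ranking score is the winning
#' class's raw biaffine score, or its softmax probability under
#' `rank_by = "probability"`.
#'
#' @param scores array from [score_spans()] (`NA` outside the enumeration).
#' @param lab_set the corpus [label_set()].
#' @param rank_by `"score"` or `"probability"`.
#' @return tibble of candidates: `start`, `end` (0-based, inclusive),
#'   `label`, `score`.
#' @export
predict_span_labels <- function(scores, lab_set, rank_by = c("score", "probability")) {
  rank_by <- match.arg(rank_by)
  n <- dim(scores)[1]
  n_class <- dim(scores)[3]
  empty <- tibble(start = integer(), end = integer(),
                  label = character(), score = double())
  idx <- which(!is.na(matrix(scores[, , 1], n, n)))
  if (length(idx) == 0) return(empty)
  # linear cell indices -> (i, j); one row per enumerated span
  S <- vapply(seq_len(n_class),
              function(cc) matrix(scores[, , cc], n, n)[idx],
              numeric(length(idx)))
  S <- matrix(S, nrow = length(idx))
  best <- max.col(S, ties.method = "first")
  keep <- best != n_class  # drop spans whose argmax is non-entity
  if (!any(keep)) return(empty)
  idx <- idx[keep]; best <- best[keep]; S <- S[keep, , drop = FALSE]
  raw <- S[cbind(seq_along(best), best)]
  sc <- if (rank_by == "score") {
    raw
  } else {
    exp(raw - apply(S, 1, max)) / rowSums(exp(S - apply(S, 1, max)))
  }
  tibble(start = ((idx - 1L) %% n),
         end = ((idx - 1L) %/% n),
         label = lab_set$entity_types[best],
         score = sc)
}

#' Filter candidates through the boundary gate
#'
#' A candidate `(i, j)` survives iff the boundary task endorses its
#' endpoints: with predicted boundary probabilities, `P(I) >= threshold`
#' at both token `i` and token `j`; with gold labels, both endpoints are
#' labeled `I`. Under the `"inside"` labeling scheme every gold mention
#' passes its own gold gate by construction, since all its tokens are `I`.
#' A threshold of 0 passes everything.
#'
#' @param candidates tibble from [predict_span_labels()].
#' @param boundary either a character vector of `"O"`/`"I"` labels (gold)
#'   or an N x 2 probability matrix with columns `O`, `I` (predicted).
#' @param threshold probability threshold for predicted boundaries.
#' @return the surviving candidate rows.
#' @export
boundary_gate <- function(candidates, boundary, threshold = 0.5) {
  if (nrow(candidates) == 0) return(candidates)
  p_i <- if (is.character(boundary)) {
    as.numeric(boundary == "I")
  } else {
    boundary[, "I"]
  }
  keep <- p_i[candidates$start + 1L] >= threshold &
    p_i[candidates$end + 1L] >= threshold
  candidates[keep, , drop = FALSE]
}

crosses <- function(s1, e1, s2, e2) {
  (s1 < s2 & s2 <= e1 & e1 < e2) | (s2 < s1 & s1 <= e2 & e2 < e1)
}

#' Resolve partial overlaps among scored candidates
#'
#' Greedy sweep in descending score order: a candidate is kept iff it does
#' not cross (partially overlap) any already-kept mention. Two spans cross
#' iff one starts strictly inside the other and ends strictly beyond it;
#' containment and disjointness never block, so nested predictions
#' survive. Ties in score break by `(start, end, label)` for full
#' determinism. The operation is idempotent and invariant under adding a
#' constant to all scores.
#'
#' @param candidates tibble with `start`, `end`, `label`, `score`.
#' @return the kept mentions, in the order visited.
#' @export
resolve_overlaps <- function(candidates) {
  if (nrow(candidates) <= 1) return(candidates)
  ord <- order(-candidates$score, candidates$start, candidates$end, candidates$label)
  cand <- candidates[ord, , drop = FALSE]
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    kept <- which(keep)
    keep[k] <- !any(crosses(cand$start[k], cand$end[k],
                            cand$start[kept], cand$end[kept]))
  }
  cand[keep, , drop = FALSE]
}

#' Decode one sentence into its final mention set
#'
#' Composition of the three decoding stages: span-label prediction from
#' the score tensor, boundary gating (when enabled), and greedy overlap
#' resolution. Deterministic given the model outputs.
#'
#' @param forward list with `scores` (array) and `boundary` (N x 2
#'   probability matrix or gold label vector), as from the model's
#'   evaluation-mode forward pass.
#' @param lab_set the corpus [label_set()].
#' @param config a [model_config()]; `use_gate`, `gate_threshold` and
#'   `rank_by` govern decoding.
#' @return tibble of predicted mentions (`start`, `end`, `label`, `score`).
#' @export
decode_sentence <- function(forward, lab_set, config = model_config()) {
  cand <- predict_span_labels(forward$scores, lab_set, config$rank_by)
  if (config$use_gate && !is.null(forward$boundary)) {
    cand <- boundary_gate(cand, forward$boundary, config$gate_threshold)
  }
  resolve_overlaps(cand)
}
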