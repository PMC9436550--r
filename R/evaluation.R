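#' Match predicted against gold mentions
#'
#' Exact matching on the full `(start, end, label)` triple: a predicted
#' mention is a true positive iff an identical gold triple exists.
#' Counts are returned per entity type; micro counts are their sums.
#'
#' @param pred,gold mention tibbles (`start`, `end`, `label`) for the same
#'   sentence, or corpora (lists of sentences / prediction tibbles) —
#'   counts are pooled across sentences.
#' @return tibble with columns `label`, `tp`, `fp`, `fn`.
#' @export
match_mentions <- function(pred, gold) {
  key <- function(m) if (nrow(m) == 0) character() else paste(m$start, m$end, m$label)
  pk <- key(pred); gk <- key(gold)
  labs <- sort(unique(c(pred$label, gold$label)))
  if (length(labs) == 0) {
    return(tibble(label = character(), tp = integer(), fp = integer(),
                  fn = integer()))
  }
  purrr::map_dfr(labs, function(l) {
    p <- pk[pred$label == l]
    g <- gk[gold$label == l]
    tibble(label = l,
           tp = sum(p %in% g),
           fp = sum(!p %in% g),
           fn = sum(!g %in% p))
  })
}

#' Precision, recall and F1 from match counts
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F1 = 2PR/(P+R)`; a zero
#' denominator yields 0 by convention. Vectorized over count vectors.
#'
#' @param tp,fp,fn non-negative counts.
#' @return tibble with columns `precision`, `recall`, `f1`.
#' @export
prf <- function(tp, fp, fn) {
  p <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  r <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f <- ifelse(p + r > 0, 2 * p * r / (p + r), 0)
  tibble(precision = p, recall = r, f1 = f)
}

#' Entity-level evaluation of a predicted corpus
#'
#' Pools exact-match counts over sentences and reports micro-averaged and
#' per-type precision/recall/F1.
#'
#' @param pred list of prediction tibbles (one per sentence) or a corpus
#'   of sentences carrying predicted mentions.
#' @param gold the gold corpus (same length and sentence order).
#' @return list with `overall` (one-row tibble: `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f1`) and `per_type` (tibble with one row per
#'   entity type).
#' @export
ner_evaluate <- function(pred, gold) {
  if (length(pred) != length(gold)) abort("pred and gold differ in length")
  counts <- purrr::map_dfr(seq_along(gold), function(i) {
    p <- pred[[i]]
    if (inherits(p, "nner_sentence")) p <- p$mentions
    match_mentions(as_mentions(p), gold[[i]]$mentions)
  })
  per_type <- counts |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(tp = sum(.data$tp), fp = sum(.data$fp), fn = sum(.data$fn),
                     .groups = "drop")
  per_type <- dplyr::bind_cols(per_type, prf(per_type$tp, per_type$fp, per_type$fn))
  overall <- tibble(tp = sum(per_type$tp), fp = sum(per_type$fp), fn = sum(per_type$fn))
  overall <- dplyr::bind_cols(overall, prf(overall$tp, overall$fp, overall$fn))
  list(overall = overall, per_type = per_type)
}
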