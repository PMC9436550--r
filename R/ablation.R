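#' Paired ablation of the boundary task (single-task vs multi-task)
#'
#' Trains the single-task biaffine baseline (`alpha = 0`, boundary gate
#' off — the boundary head then contributes nothing to the objective or
#' to decoding) and the multi-task model (`alpha > 0`) under identical
#' seeds, data and every other setting, then evaluates both on the same
#' test corpus. The comparison of interest is recall: boundary
#' supervision exists to recover candidate spans the plain span
#' classifier misses.
#'
#' @param train_corpus,test_corpus corpora with gold mentions.
#' @param config base [model_config()]; `alpha` and `seed` are overridden
#'   per arm.
#' @param alphas mixing ratios to compare (0 = single-task baseline).
#' @param seeds integer vector of seeds; each seed yields one paired set
#'   of runs.
#' @param verbose print progress.
#' @return list with `runs` (tibble: seed, alpha, precision, recall, f1,
#'   epochs) and `summary` (per-alpha means).
#' @export
run_ablation <- function(train_corpus, test_corpus, config = model_config(),
                         alphas = c(0, 1), seeds = 1:5, verbose = FALSE) {
  runs <- purrr::map_dfr(seeds, function(sd) {
    purrr::map_dfr(alphas, function(a) {
      cfg <- config
      cfg$seed <- as.integer(sd)
      cfg$alpha <- a
      cfg$use_gate <- config$use_gate && a > 0
      fit <- ner_train(train_corpus, cfg, heldout = test_corpus, verbose = FALSE)
      ev <- ner_evaluate(predict(fit, test_corpus), test_corpus)
      if (verbose) {
        message(sprintf("seed %d  alpha %.2f  P %.3f R %.3f F1 %.3f",
                        sd, a, ev$overall$precision, ev$overall$recall,
                        ev$overall$f1))
      }
      tibble(seed = sd, alpha = a,
             precision = ev$overall$precision, recall = ev$overall$recall,
             f1 = ev$overall$f1, epochs = fit$epochs_run)
    })
  })
  summary <- runs |>
    dplyr::group_by(.data$alpha) |>
    dplyr::summarise(precision = mean(.data$precision), recall = mean(.data$recall),
                     f1 = mean(.data$f1), .groups = "drop")
  list(runs = runs, summary = summary)
}
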