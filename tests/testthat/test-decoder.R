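ls2 <- label_set(c("X", "Y"))

# scores array helper: n tokens, entries list of (i, j, vector over classes)
mk_scores <- function(n, n_class, entries) {
  sc <- array(NA_real_, c(n, n, n_class))
  for (i in seq_len(n)) for (j in i:n) sc[i, j, ] <- c(rep(-5, n_class - 1), 5)
  for (e in entries) sc[e[[1]], e[[2]], ] <- e[[3]]
  sc
}

test_that("span label prediction takes the per-span argmax", {
  # every span prefers non-entity -> empty candidate set
  sc <- mk_scores(3, 3, list())
  expect_equal(nrow(predict_span_labels(sc, ls2)), 0)
  # single span preferring X with score 2
  sc <- mk_scores(3, 3, list(list(1, 2, c(2, 0, -1))))
  got <- predict_span_labels(sc, ls2)
  expect_equal(got, tibble::tibble(start = 0L, end = 1L, label = "X", score = 2))
  # probability ranking is the softmax of the winning class
  got_p <- predict_span_labels(sc, ls2, rank_by = "probability")
  expect_equal(got_p$score, exp(2) / sum(exp(c(2, 0, -1))), tolerance = 1e-9)
})

test_that("span label prediction equals per-span brute force", {
  set.seed(77)
  for (rep in 1:25) {
    n <- sample(2:5, 1)
    sc <- array(NA_real_, c(n, n, 3))
    for (i in seq_len(n)) for (j in i:n) sc[i, j, ] <- rnorm(3)
    got <- predict_span_labels(sc, ls2)
    for (i in seq_len(n)) for (j in i:n) {
      v <- sc[i, j, ]
      row <- got[got$start == i - 1 & got$end == j - 1, ]
      if (which.max(v) == 3) {
        expect_equal(nrow(row), 0)
      } else {
        expect_equal(row$label, c("X", "Y")[which.max(v)])
        expect_equal(row$score, max(v))
      }
    }
  }
})

test_that("the boundary gate keeps spans endorsed at both endpoints", {
  cand <- tibble::tibble(start = c(0L, 1L, 2L), end = c(1L, 3L, 2L),
                         label = "X", score = c(3, 2, 1))
  # gold labels: every gold mention passes its own gate
  gold <- c("I", "I", "O", "I")
  kept <- boundary_gate(cand, gold)
  expect_equal(kept$start, c(0L, 1L))  # (2,2) blocked: token 2 is O
  # all-O boundary -> nothing survives
  expect_equal(nrow(boundary_gate(cand, rep("O", 4))), 0)
  # threshold 0 passes everything through predicted probabilities
  probs <- cbind(O = runif(4), I = runif(4))
  expect_equal(boundary_gate(cand, probs, threshold = 0), cand)
})

test_that("gold mentions always pass the gold inside-scheme gate", {
  corp <- generate_corpus(synth_config(n_sentences = 40, p_nest = 0.5, seed = 21))
  for (s in corp) {
    m <- s$mentions
    if (nrow(m) == 0) next
    cand <- dplyr::mutate(m, score = 1)
    kept <- boundary_gate(cand, make_boundary_labels(s, "inside"))
    expect_equal(nrow(kept), nrow(m))
  }
})

test_that("overlap resolution keeps nesting and blocks crossings", {
  nested <- tibble::tibble(start = c(0L, 1L), end = c(3L, 2L),
                           label = c("X", "Y"), score = c(0.9, 0.8))
  expect_equal(nrow(resolve_overlaps(nested)), 2)  # containment never blocks
  crossing <- tibble::tibble(start = c(0L, 1L), end = c(2L, 3L),
                             label = c("X", "Y"), score = c(0.9, 0.8))
  kept <- resolve_overlaps(crossing)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$label, "X")  # higher score wins
})

test_that("overlap resolution equals the descending-order oracle", {
  set.seed(55)
  for (rep in 1:200) {
    k <- sample(1:8, 1)
    cand <- tibble::tibble(start = sample(0:6, k, replace = TRUE))
    cand$end <- cand$start + sample(0:3, k, replace = TRUE)
    cand$label <- sample(c("X", "Y"), k, replace = TRUE)
    cand$score <- round(rnorm(k), 2)  # rounding forces occasional ties
    cand <- cand[!duplicated(paste(cand$start, cand$end)), , drop = FALSE]
    got <- resolve_overlaps(cand)
    want <- oracle_resolve(cand)
    expect_equal(dplyr::arrange(got, start, end), dplyr::arrange(want, start, end),
                 ignore_attr = TRUE)
    # no crossing pair survives
    if (nrow(got) > 1) {
      for (a in 1:(nrow(got) - 1)) for (b in (a + 1):nrow(got)) {
        expect_false(oracle_crossing(got$start[a], got$end[a],
                                     got$start[b], got$end[b]))
      }
    }
    # idempotence
    expect_equal(dplyr::arrange(resolve_overlaps(got), start, end),
                 dplyr::arrange(got, start, end), ignore_attr = TRUE)
    # score-shift invariance
    shifted <- cand; shifted$score <- shifted$score + 7.5
    expect_equal(dplyr::arrange(resolve_overlaps(shifted), start, end)[c("start", "end", "label")],
                 dplyr::arrange(got, start, end)[c("start", "end", "label")],
                 ignore_attr = TRUE)
  }
})

test_that("a span scored highest for its class decodes to that mention", {
  # "damage to the respiratory center": the full five-token span carries
  # the top score for the clinical-manifestation class and must decode
  # to exactly that typed mention
  lab <- label_set(c("CLINICAL", "OTHER"))
  sc <- mk_scores(5, 3, list(list(1, 5, c(6, -1, -3))))
  cfg <- model_config(use_gate = FALSE)
  got <- decode_sentence(list(scores = sc, boundary = NULL), lab, cfg)
  expect_equal(got[c("start", "end", "label")],
               tibble::tibble(start = 0L, end = 4L, label = "CLINICAL"))
})

test_that("decoding composes the stages deterministically", {
  st <- tiny_setup()
  s <- st$corpus[[3]]
  fw <- nestner:::nner_forward(s, st$params, st$cfg, st$vocab)
  d1 <- decode_sentence(fw, st$lab_set, st$cfg)
  d2 <- decode_sentence(fw, st$lab_set, st$cfg)
  expect_identical(d1, d2)
  # gating disabled vs threshold 0: identical outputs
  cfg_off <- st$cfg; cfg_off$use_gate <- FALSE
  cfg_zero <- st$cfg; cfg_zero$gate_threshold <- 0
  expect_equal(decode_sentence(fw, st$lab_set, cfg_off),
               decode_sentence(fw, st$lab_set, cfg_zero))
  # zero weights with bias favouring non-entity -> empty prediction
  p0 <- st$params
  p0$U1[] <- 0; p0$U2[] <- 0
  p0$b_span <- c(-1, -1, -1, 5)
  fw0 <- nestner:::nner_forward(s, p0, st$cfg, st$vocab)
  expect_equal(nrow(decode_sentence(fw0, st$lab_set, cfg_off)), 0)
})
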