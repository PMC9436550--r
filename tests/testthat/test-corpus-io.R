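test_that("CoNLL reader turns BIO runs into mentions", {
  f <- withr::local_tempfile()
  writeLines(c("the O", "colon B-DIS", "cancer I-DIS"), f)
  corp <- read_conll(f)
  expect_length(corp, 1)
  expect_equal(corp[[1]]$tokens, c("the", "colon", "cancer"))
  expect_equal(corp[[1]]$mentions,
               tibble::tibble(start = 1L, end = 2L, label = "DIS"))
})

test_that("CoNLL reader handles empty files and -DOCSTART-", {
  f <- withr::local_tempfile()
  writeLines(character(), f)
  expect_length(read_conll(f), 0)
  writeLines(c("-DOCSTART- O", "", "x B-PER"), f)
  corp <- read_conll(f)
  expect_length(corp, 1)
  expect_equal(corp[[1]]$tokens, "x")
})

test_that("a mixed six-sentence CoNLL file matches its hand enumeration", {
  f <- withr::local_tempfile()
  writeLines(c(
    "in O",       "london B-LOC", "today O",    "",
    "john B-PER", "smith I-PER",  "and O",      "mary B-PER", "",
    "acme B-ORG", "corp I-ORG",   "ltd I-ORG",  "",
    "paris B-LOC","texas B-LOC",  "",
    "he O",       "walked O",     "",
    "un B-ORG",   "chief O",      "kofi B-PER", "annan I-PER"
  ), f)
  corp <- read_conll(f)
  expect_length(corp, 6)
  got <- dplyr::bind_rows(lapply(seq_along(corp), function(i) {
    m <- corp[[i]]$mentions
    if (nrow(m)) m$sent <- i
    m
  }))
  # independent hand parse of the fixture above (0-based inclusive)
  want <- tibble::tibble(
    start = c(1L, 0L, 3L, 0L, 0L, 1L, 0L, 2L),
    end   = c(1L, 1L, 3L, 2L, 0L, 1L, 0L, 3L),
    label = c("LOC", "PER", "PER", "ORG", "LOC", "LOC", "ORG", "PER"),
    sent  = c(1L, 2L, 2L, 3L, 4L, 4L, 6L, 6L)
  )
  expect_equal(dplyr::arrange(got, sent, start), want)
  # 10 B/I runs minus merges = 8 mentions; every mention is in range
  for (i in seq_along(corp)) {
    m <- corp[[i]]$mentions
    expect_true(all(m$start >= 0 & m$start <= m$end &
                      m$end < length(corp[[i]]$tokens)))
  }
})

test_that("dangling I- tags are repaired to B- with a warning", {
  f <- withr::local_tempfile()
  writeLines(c("a O", "b I-PER", "c B-LOC", "d I-ORG"), f)
  expect_warning(corp <- read_conll(f), "repaired 2")
  expect_equal(corp[[1]]$mentions$label, c("PER", "LOC", "ORG"))
  expect_equal(corp[[1]]$mentions$start, c(1L, 2L, 3L))
})

test_that("span-JSONL reader accepts nesting and enforces invariants", {
  f <- withr::local_tempfile()
  writeLines('{"tokens":["mRNA"],"mentions":[{"start":0,"end":0,"label":"RNA"}]}', f)
  corp <- read_jsonl_spans(f)
  expect_length(corp, 1)
  expect_equal(corp[[1]]$mentions$label, "RNA")

  writeLines(paste0('{"tokens":["a","b","c","d"],"mentions":',
                    '[{"start":0,"end":3,"label":"PER"},',
                    '{"start":1,"end":2,"label":"ORG"}]}'), f)
  corp <- read_jsonl_spans(f)
  expect_equal(nrow(corp[[1]]$mentions), 2)  # containment is legal

  writeLines("not json at all {", f)
  expect_error(read_jsonl_spans(f), "line 1")
  writeLines('{"tokens":["a"],"mentions":[{"start":0,"end":5,"label":"X"}]}', f)
  expect_error(read_jsonl_spans(f), "line 1")
  writeLines('{"tokens":["a","b"],"mentions":[{"start":1,"end":0,"label":"X"}]}', f)
  expect_error(read_jsonl_spans(f), "end < start")
})

test_that("write/read span-JSONL round-trips a 50-sentence synthetic corpus", {
  corp <- generate_corpus(synth_config(n_sentences = 50, seed = 9))
  f <- withr::local_tempfile()
  write_jsonl_spans(corp, f)
  back <- read_jsonl_spans(f)
  expect_length(back, length(corp))
  for (i in seq_along(corp)) {
    expect_equal(back[[i]]$tokens, corp[[i]]$tokens)
    a <- dplyr::arrange(corp[[i]]$mentions, start, end, label)
    b <- dplyr::arrange(back[[i]]$mentions, start, end, label)
    expect_equal(b, a, ignore_attr = TRUE)
  }
})

test_that("span-JSONL output is deterministic and sorted", {
  s <- sentence(c("a", "b", "c"),
                data.frame(start = c(2, 0), end = c(2, 1), label = c("Z", "A")))
  f <- withr::local_tempfile()
  write_jsonl_spans(list(s), f)
  line <- readLines(f)
  expect_match(line, '\\{"start":0,"end":1,"label":"A"\\},\\{"start":2,"end":2,"label":"Z"\\}')
  write_jsonl_spans(list(), f)
  expect_length(readLines(f), 0)
})

test_that("crossing gold mentions are kept but flagged", {
  expect_warning(
    s <- sentence(letters[1:5],
                  data.frame(start = c(0, 2), end = c(3, 4), label = c("X", "Y"))),
    "crossing"
  )
  expect_equal(nrow(s$mentions), 2)
})

test_that("boundary labels follow the inside and endpoints schemes", {
  s <- sentence(letters[1:5], data.frame(start = 1, end = 3, label = "X"))
  expect_equal(make_boundary_labels(s), c("O", "I", "I", "I", "O"))
  expect_equal(make_boundary_labels(sentence(letters[1:4])), rep("O", 4))
  s2 <- sentence(letters[1:5],
                 data.frame(start = c(0, 2), end = c(4, 2), label = c("X", "Y")))
  expect_equal(make_boundary_labels(s2, "inside"), rep("I", 5))
  expect_equal(make_boundary_labels(s2, "endpoints"), c("I", "O", "I", "O", "I"))
})

test_that("inside labels equal the interval union on random sentences", {
  set.seed(42)
  for (rep in 1:200) {
    n <- sample(3:12, 1)
    m <- random_mentions(n)
    s <- suppressWarnings(sentence(paste0("t", seq_len(n)), m))
    want <- if (is.null(m)) rep("O", n) else oracle_inside_labels(n, s$mentions)
    got <- make_boundary_labels(s, "inside")
    expect_equal(got, want)
    expect_equal(sum(got == "I"), sum(want == "I"))  # I-count = union size
  }
})

test_that("vocabulary construction is deterministic and honours min_count", {
  corp <- list(
    sentence(c("a", "a", "b"), data.frame(start = 0, end = 0, label = "X")),
    sentence(c("a", "c"), data.frame(start = 1, end = 1, label = "Y")),
    sentence("z", data.frame(start = 0, end = 0, label = "Z"))
  )
  v <- build_vocab(corp, min_count = 2)
  expect_false("b" %in% v$words)          # below min_count -> unknown
  expect_equal(unname(nestner:::word_indices("b", v)), 2L)
  v2 <- build_vocab(corp, min_count = 2)
  expect_identical(v, v2)                  # two runs, identical assignment
  expect_equal(v$label_set$entity_types, c("X", "Y", "Z"))
  expect_error(build_vocab(list()), "empty")
})

test_that("word-vector files load with dimension checking", {
  f <- withr::local_tempfile()
  writeLines(c("cat 1 2 3", "dog 4 5 6"), f)
  m <- read_word_vectors(f)
  expect_equal(dim(m), c(2, 3))
  expect_equal(m["dog", ], c(4, 5, 6))
  writeLines(c("cat 1 2 3", "dog 4 5"), f)
  expect_error(read_word_vectors(f), "line 2")
})
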