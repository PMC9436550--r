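test_that("character CNN matches a hand-unrolled convolution", {
  st <- tiny_setup()
  v <- st$vocab; cfg <- st$cfg; p <- st$params
  word <- "abca"
  out <- char_cnn(word, p, cfg, v)
  expect_length(out, cfg$char_filters * length(cfg$char_widths))
  # loop oracle: embed characters, slide each filter, max-pool
  ch <- nestner:::char_indices(word, v)[[1]]
  emb <- t(p$E_char[ch, , drop = FALSE])  # dc x len
  want <- c()
  for (w in seq_along(cfg$char_widths)) {
    k <- cfg$char_widths[w]
    W <- p[[paste0("conv_W", k)]]; b <- p[[paste0("conv_b", k)]]
    for (f in seq_len(nrow(W))) {
      vals <- sapply(1:(ncol(emb) - k + 1), function(pos) {
        sum(W[f, ] * as.vector(emb[, pos:(pos + k - 1)])) + b[f]
      })
      want <- c(want, max(vals))
    }
  }
  expect_equal(out, want, tolerance = 1e-12)
})

test_that("character CNN handles degenerate and zero cases", {
  st <- tiny_setup()
  out <- char_cnn("a", st$params, st$cfg, st$vocab)  # shorter than widths
  expect_length(out, 4)
  expect_true(all(is.finite(out)))
  p0 <- st$params
  for (k in st$cfg$char_widths) {
    p0[[paste0("conv_W", k)]][] <- 0
    p0[[paste0("conv_b", k)]][] <- 0
  }
  expect_equal(char_cnn("xyz", p0, st$cfg, st$vocab), rep(0, 4))
})

test_that("token embeddings concatenate char and word blocks in order", {
  st <- tiny_setup()
  s <- st$corpus[[1]]
  X <- embed_tokens(s, st$params, st$cfg, st$vocab)
  char_w <- st$cfg$char_filters * length(st$cfg$char_widths)
  expect_equal(nrow(X), char_w + st$cfg$word_dim)  # no contextual block
  expect_equal(ncol(X), length(s$tokens))
  # word block equals the table row; char block equals char_cnn
  t1 <- s$tokens[1]
  wid <- nestner:::word_indices(t1, st$vocab)
  expect_equal(X[(char_w + 1):nrow(X), 1], st$params$E_word[wid, ])
  expect_equal(X[1:char_w, 1], char_cnn(t1, st$params, st$cfg, st$vocab))
})

test_that("unknown tokens use the unknown embedding row", {
  st <- tiny_setup()
  s <- sentence(c("zzzznever_seen"))
  X <- embed_tokens(s, st$params, st$cfg, st$vocab)
  char_w <- st$cfg$char_filters * length(st$cfg$char_widths)
  expect_equal(X[(char_w + 1):nrow(X), 1], st$params$E_word[2, ])
})

test_that("contextual block length mismatches are fatal", {
  st <- tiny_setup()
  s <- st$corpus[[1]]
  lm <- matrix(0, 4, length(s$tokens) + 1)
  expect_error(embed_tokens(s, st$params, st$cfg, st$vocab, lm = lm),
               "wrong sequence length")
})

test_that("BiLSTM encoding is deterministic in evaluation mode", {
  st <- tiny_setup()
  X <- embed_tokens(st$corpus[[1]], st$params, st$cfg, st$vocab)
  H1 <- bilstm_encode(X, st$params, st$cfg)
  H2 <- bilstm_encode(X, st$params, st$cfg)
  expect_identical(H1, H2)
  expect_equal(dim(H1), c(st$cfg$lstm_size, ncol(X)))
  # length-1 sequence: both directions see one step
  H3 <- bilstm_encode(X[, 1, drop = FALSE], st$params, st$cfg)
  expect_equal(dim(H3), c(st$cfg$lstm_size, 1))
  expect_true(all(is.finite(H3)))
})

test_that("head/tail projections are independent affine+ReLU maps", {
  st <- tiny_setup()
  H <- matrix(c(0.3, -1, 2, 0.5, 1, -2, 0.1, 0.7, -0.4, 0.2, 0.9, -1.1), 6, 2)
  pr <- head_tail_project(H, st$params, st$cfg)
  want_s <- pmax(st$params$mlp_s_W %*% H + st$params$mlp_s_b, 0)
  want_e <- pmax(st$params$mlp_e_W %*% H + st$params$mlp_e_b, 0)
  expect_equal(pr$s, want_s, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(pr$e, want_e, ignore_attr = TRUE, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(pr$s, pr$e)))  # independent weights
  # auxiliary per-token softmax outputs are distributions
  expect_equal(colSums(pr$s_prob), rep(1, 2))
  # zero weights, zero bias -> zero representations
  p0 <- st$params
  p0$mlp_s_W[] <- 0; p0$mlp_s_b[] <- 0; p0$mlp_e_W[] <- 0; p0$mlp_e_b[] <- 0
  pr0 <- head_tail_project(H, p0, st$cfg)
  expect_true(all(pr0$s == 0) && all(pr0$e == 0))
})

test_that("post-softmax span representations are available as an option", {
  st <- tiny_setup()
  cfg2 <- st$cfg; cfg2$span_repr <- "post_softmax"
  H <- matrix(rnorm(12), 6, 2)
  pr <- head_tail_project(H, st$params, cfg2)
  expect_equal(colSums(pr$s), rep(1, 2), tolerance = 1e-9)
})

test_that("every parameter group receives gradient on a generic batch", {
  st <- tiny_setup()
  out <- sent_grad(st$corpus[[1]], st, training = FALSE, alpha = 1)
  expect_setequal(names(out$grads), names(unclass(st$params)))
  for (nm in names(out$grads)) {
    expect_gt(max(abs(out$grads[[nm]])), 0, label = paste("grad", nm))
  }
})

test_that("analytic gradients match central finite differences", {
  st <- tiny_setup(seed = 11, n_sentences = 3)
  s <- st$corpus[[1]]
  base <- sent_grad(s, st, alpha = 0.7)
  eps <- 1e-5
  set.seed(2)
  for (nm in names(base$grads)) {
    ii <- sample(length(st$params[[nm]]), min(3, length(st$params[[nm]])))
    for (i in ii) {
      up <- st; up$params[[nm]][i] <- up$params[[nm]][i] + eps
      dn <- st; dn$params[[nm]][i] <- dn$params[[nm]][i] - eps
      lu <- sent_grad(s, up, alpha = 0.7); ld <- sent_grad(s, dn, alpha = 0.7)
      num <- ((lu$loss_b + 0.7 * lu$loss_d) - (ld$loss_b + 0.7 * ld$loss_d)) / (2 * eps)
      ana <- base$grads[[nm]][i]
      expect_equal(ana, num, tolerance = 1e-3,
                   label = paste("d loss /", nm, "[", i, "]"))
    }
  }
})
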