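test_that("context-mention encoding has the boundary-state shape contract", {
  tab <- toy_embeddings()
  m <- tiny_model(tab)
  ctx <- c("severe", "fever", "specified", "the")
  v <- encode_context_mention(m, ctx, 2, 3)
  expect_length(v, 4 * m$config$hidden_dim)
  expect_true(all(is.finite(v)))
  # deterministic in inference mode
  expect_identical(v, encode_context_mention(m, ctx, 2, 3))
  # a mention opening the sentence zeroes the two pre-mention slots
  v0 <- encode_context_mention(m, ctx, 1, 2)
  H <- m$config$hidden_dim
  expect_equal(v0[seq_len(2 * H)], rep(0, 2 * H))
  expect_false(all(v0[(2 * H + 1):(4 * H)] == 0))
  expect_error(encode_context_mention(m, ctx, 3, 9), "out of bounds")
})

test_that("entity encoding averages the model's word embeddings", {
  v <- matrix(c(2, 0,
                0, 2), nrow = 2, byrow = TRUE,
              dimnames = list(c("p", "q"), NULL))
  tab <- embedding_table(v)
  m <- linking_model(tab, model_config(word_dim = 2, pos_dim = 2,
                                       hidden_dim = 2, layers = 1,
                                       ffn_hidden = 3, seed = 1))
  expect_equal(as.numeric(encode_entity(m, "p")), c(2, 0))
  expect_equal(as.numeric(encode_entity(m, c("p", "q"))), c(1, 1))
  oov <- encode_entity(m, c("zz", "yy"))
  expect_equal(as.numeric(oov), c(0, 0))
  expect_true(attr(oov, "all_oov"))
  expect_error(encode_entity(m, character(0)), "no tokens")
  # cross-module consistency: equals average_embed on the same table
  tab2 <- toy_embeddings()
  m2 <- tiny_model(tab2)
  toks <- c("fever", "specified")
  expect_equal(as.numeric(encode_entity(m2, toks)),
               as.numeric(average_embed(tab2, toks)))
})

test_that("score_candidate matches a hand-computed forward pass", {
  # 2-dim toy model, 1 layer, hand-set weights
  v <- matrix(c(1, 0,
                0, 1), nrow = 2, byrow = TRUE,
              dimnames = list(c("p", "q"), NULL))
  tab <- embedding_table(v)
  m <- linking_model(tab, model_config(word_dim = 2, pos_dim = 1,
                                       hidden_dim = 2, layers = 1,
                                       ffn_hidden = 2, seed = 3))
  # overwrite scorer with known weights; encoder output is whatever the
  # (fixed) LSTM computes, so compute the reference from its pieces
  m$params$ffn_W1 <- matrix(seq(0.1, 1.0, length.out = 2 * 10), 2, 10)
  m$params$ffn_b1 <- matrix(c(0.05, -0.05), 2, 1)
  m$params$ffn_W2 <- matrix(c(0.3, -0.2), 1, 2)
  m$params$ffn_b2 <- matrix(0.1, 1, 1)
  ctx <- c("p", "q", "p")
  e <- as.numeric(encode_entity(m, c("p", "q")))
  vv <- encode_context_mention(m, ctx, 2, 2)
  z <- c(e, vv)
  a1 <- pmax(m$params$ffn_W1 %*% z + m$params$ffn_b1[, 1], 0)
  expected <- as.numeric(m$params$ffn_W2 %*% a1 + 0.1)
  expect_equal(score_candidate(m, c("p", "q"), ctx, 2, 2), expected)
  # averaging makes the entity encoder order-free
  expect_equal(score_candidate(m, c("q", "p"), ctx, 2, 2), expected)
})

test_that("mil_margin_loss reproduces hand-substituted hinge values", {
  # stub model whose scorer output we control through a lookup:
  # use a real model but evaluate the loss formula through score vectors
  # computed by the same public scorer, then compare against direct
  # substitution of those scores into the hinge.
  tab <- toy_embeddings()
  kb <- toy_kb()
  m <- tiny_model(tab)
  tk <- ws()
  pt <- list(sentence_id = 1, tokens = c("severe", "fever", "specified"),
             start = 2, end = 3,
             positives = c("R50.800", "R50.900"),
             negatives = c("K52.916", "A00"), gold = NA_character_)
  s <- function(code) {
    nm <- kb$entities$name[match(code, kb$entities$raw)]
    score_candidate(m, tk$tokenize(nm), pt$tokens, pt$start, pt$end)
  }
  for (delta in c(0, 0.1, 0.5, 2)) {
    expected <- max(0, max(s("K52.916"), s("A00")) + delta -
                      max(s("R50.800"), s("R50.900")))
    expect_equal(mil_margin_loss(m, list(pt), kb, delta = delta,
                                 tokenizer = tk),
                 expected, label = sprintf("delta=%g", delta))
  }
  # loss over a batch is the sum of per-point hinges
  expect_equal(mil_margin_loss(m, list(pt, pt), kb, delta = 0.5,
                               tokenizer = tk),
               2 * mil_margin_loss(m, list(pt), kb, delta = 0.5,
                                   tokenizer = tk))
  # permutation invariance within bags
  pt2 <- pt
  pt2$positives <- rev(pt$positives)
  pt2$negatives <- rev(pt$negatives)
  expect_equal(mil_margin_loss(m, list(pt2), kb, tokenizer = tk),
               mil_margin_loss(m, list(pt), kb, tokenizer = tk))
  pt3 <- pt
  pt3$negatives <- character(0)
  expect_error(mil_margin_loss(m, list(pt3), kb, tokenizer = tk),
               "empty candidate bag")
})

test_that("analytic gradients match finite differences", {
  tab <- toy_embeddings()
  kb <- toy_kb()
  tk <- ws()
  m <- tiny_model(tab)
  pt <- list(sentence_id = 1,
             tokens = c("severe", "fever", "specified", "mild", "the"),
             start = 2, end = 3,
             positives = c("R50.800", "A00"),
             negatives = c("K52.916"), gold = NA_character_)
  delta <- 2  # large margin keeps the hinge active and away from its kink
  lg <- milink:::loss_and_grads(m, list(pt), kb, delta = delta,
                                tokenizer = tk)
  expect_gt(lg$loss, 0)
  eps <- 1e-5
  set.seed(31)
  for (nm in names(m$params)) {
    p <- m$params[[nm]]
    for (i in sample(length(p), min(8, length(p)))) {
      m2 <- m
      m2$params[[nm]][i] <- p[i] + eps
      up <- mil_margin_loss(m2, list(pt), kb, delta = delta, tokenizer = tk)
      m2$params[[nm]][i] <- p[i] - eps
      dn <- mil_margin_loss(m2, list(pt), kb, delta = delta, tokenizer = tk)
      fd <- (up - dn) / (2 * eps)
      an <- lg$grads[[nm]][i]
      expect_equal(an, fd, tolerance = 1e-4,
                   label = sprintf("grad %s[%d]", nm, i))
    }
  }
})

test_that("model checkpoints round-trip and validate dimensions", {
  tab <- toy_embeddings()
  m <- tiny_model(tab)
  m$pretrained <- TRUE
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path, table = tab)
  expect_equal(m2$config, m$config)
  expect_true(m2$pretrained)
  for (nm in names(m$params)) {
    expect_equal(unname(m2$params[[nm]]), unname(m$params[[nm]]),
                 label = nm)
  }
  ctx <- c("severe", "fever", "specified")
  expect_equal(score_candidate(m2, c("fever"), ctx, 2, 2),
               score_candidate(m, c("fever"), ctx, 2, 2))
  tab_wrong <- toy_embeddings(dim = 6)
  expect_error(load_model(path, table = tab_wrong), "word_dim")
})

test_that("linking_model rejects mismatched dimensions", {
  tab <- toy_embeddings(dim = 4)
  expect_error(linking_model(tab, model_config(word_dim = 5)),
               "does not match")
})
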