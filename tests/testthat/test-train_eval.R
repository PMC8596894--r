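# A pocket-sized world shared by the training-loop tests: built once per
# file, small enough that every test stays fast.
small_bench <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      val <<- generate_benchmark(synth_config(n_sentences = 120L, seed = 17L))
    }
    val
  }
})

small_pre_ds <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      b <- small_bench()
      val <<- build_mil_dataset(b$train, b$dict, b$kb, b$table,
        candidate_config("topk", "random_topn", k = 1, pool_n = 20,
                         seed = 17),
        b$tokenizer, gold = b$gold)
    }
    val
  }
})

small_model <- function(seed = 17) {
  b <- small_bench()
  linking_model(b$table, model_config(word_dim = b$table$dim, pos_dim = 4,
                                      hidden_dim = 8, layers = 2,
                                      ffn_hidden = 16, seed = seed))
}

test_that("zero-epoch training is the identity and pretraining gates MIL", {
  b <- small_bench()
  m0 <- small_model()
  ds <- small_pre_ds()
  tc <- train_config(epochs_pretrain = 0L, epochs_mil = 0L, seed = 1)
  m1 <- pretrain_model(m0, ds, b$kb, tc, b$tokenizer)
  expect_true(m1$pretrained)
  expect_equal(m1$params, m0$params)
  # an unpretrained model refuses MIL training without the override
  expect_error(train_mil(m0, ds, b$kb, tc, b$tokenizer), "pretrained")
  m2 <- train_mil(m1, ds, b$kb, tc, b$tokenizer)
  expect_equal(m2$params, m0$params)
  # pretraining contract: singleton positive bags only
  ds_k2 <- build_mil_dataset(b$train[1:20, ], b$dict, b$kb, b$table,
    candidate_config("topk", "random_topn", k = 2, pool_n = 20, seed = 1),
    b$tokenizer)
  expect_error(pretrain_model(m0, ds_k2, b$kb, tc, b$tokenizer),
               "singleton")
})

test_that("training is reproducible and its loss decreases", {
  b <- small_bench()
  ds <- small_pre_ds()
  tc <- train_config(epochs_pretrain = 3L, batch_size = 50, seed = 5)
  m1 <- pretrain_model(small_model(), ds, b$kb, tc, b$tokenizer)
  m2 <- pretrain_model(small_model(), ds, b$kb, tc, b$tokenizer)
  expect_identical(attr(m1, "history"), attr(m2, "history"))
  expect_identical(m1$params, m2$params)
  h <- attr(m1, "history")
  expect_lt(h[length(h)], h[1])
})

test_that("link_mention agrees with exhaustive scoring of the pool", {
  b <- small_bench()
  tk <- b$tokenizer
  m <- small_model()
  idx <- bel_index(b$table, b$kb, tk)
  lab <- labeled_from_corpus(b$eval, b$kb, tk)
  for (i in seq_len(min(5, nrow(lab)))) {
    got <- link_mention(m, lab$tokens[[i]], lab$start[[i]], lab$end[[i]],
                        b$kb, idx, pool_n = 10, tokenizer = tk)
    pool <- rank_entities(idx,
                          mention_tokens =
                            lab$tokens[[i]][lab$start[[i]]:lab$end[[i]]],
                          n = 10)
    brute <- vapply(pool$name, function(nm)
      score_candidate(m, tk$tokenize(nm), lab$tokens[[i]],
                      lab$start[[i]], lab$end[[i]]), numeric(1))
    expect_equal(got$code, pool$code[order(-brute, pool$code)])
    expect_equal(got$score, sort(brute, decreasing = TRUE),
                 ignore_attr = TRUE)
  }
  # a pool of one forces the prediction
  one <- link_mention(m, lab$tokens[[1]], lab$start[[1]], lab$end[[1]],
                      b$kb, idx, pool_n = 1, tokenizer = tk)
  expect_equal(nrow(one), 1L)
})

test_that("evaluate_accuracy counts correct top-1 links", {
  b <- small_bench()
  m <- small_model()
  lab <- labeled_from_corpus(b$eval, b$kb, b$tokenizer)
  rep <- evaluate_accuracy(m, lab, b$kb, b$table, pool_n = 20,
                           tokenizer = b$tokenizer)
  expect_s3_class(rep, "milink_eval_report")
  expect_equal(rep$accuracy, rep$n_correct / rep$n_total)
  expect_equal(rep$n_total, nrow(lab))
  expect_error(evaluate_accuracy(m, lab[0, ], b$kb, b$table,
                                 tokenizer = b$tokenizer), "empty")
  bad <- lab[1, ]
  bad$gold <- "Z99.999"
  expect_error(evaluate_accuracy(m, bad, b$kb, b$table,
                                 tokenizer = b$tokenizer), "absent")
})

test_that("pool recall is monotone in N and exact at full KB size", {
  b <- small_bench()
  lab <- labeled_from_corpus(b$eval, b$kb, b$tokenizer)
  rec <- candidate_recall_at_n(b$table, b$kb, lab,
                               n_values = c(1, 2, 5, 10, 24),
                               tokenizer = b$tokenizer)
  expect_true(all(diff(rec) >= 0))
  expect_equal(unname(rec[["24"]]), 1)  # every gold is in the KB
})

test_that("pool recall matches exhaustive enumeration on a toy set", {
  tk <- ws()
  kb <- toy_kb()
  tab <- toy_embeddings(extra_tokens = c("feverish", "queasy"))
  lab <- data.frame(start = c(1L, 1L, 2L), end = c(1L, 1L, 2L),
                    gold = c("R50.800", "R11.x02", "K52.916"),
                    stringsAsFactors = FALSE)
  lab$tokens <- list(c("feverish"), c("queasy"), c("the", "severe"))
  for (n in c(1L, 3L, 6L)) {
    manual <- mean(vapply(seq_len(nrow(lab)), function(i) {
      ranked <- brute_rank(tab, kb, lab$tokens[[i]][lab$start[i]:lab$end[i]],
                           tk)
      match(lab$gold[[i]], ranked) <= n
    }, logical(1)))
    got <- candidate_recall_at_n(tab, kb, lab, n_values = n, tokenizer = tk)
    expect_equal(unname(got), manual, label = sprintf("N=%d", n))
  }
})

test_that("validation-based early stopping never returns a worse model", {
  b <- small_bench()
  ds <- small_pre_ds()
  lab <- labeled_from_corpus(b$eval, b$kb, b$tokenizer)
  val <- list(labeled = lab[seq_len(min(15, nrow(lab))), ],
              table = b$table, pool_n = 20)
  m0 <- pretrain_model(small_model(), ds, b$kb,
                       train_config(epochs_pretrain = 1L, seed = 3),
                       b$tokenizer)
  acc0 <- evaluate_accuracy(m0, val$labeled, b$kb, b$table, 20,
                            b$tokenizer)$accuracy
  m1 <- train_mil(m0, ds, b$kb,
                  train_config(epochs_mil = 2L, seed = 3, patience = 1),
                  b$tokenizer, validation = val)
  acc1 <- evaluate_accuracy(m1, val$labeled, b$kb, b$table, 20,
                            b$tokenizer)$accuracy
  expect_gte(acc1, acc0)
})
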