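#' Run the full synthetic-benchmark training experiment
#'
#' One end-to-end replication unit: generate a synthetic world, pretrain the
#' ranker on BEL pseudo-gold data, MIL-train it with hard-negative bags, and
#' evaluate everything on held-out mentions. The held-out split is divided
#' into a validation half (driving MIL checkpoint selection, including the
#' epoch-0 pretrained checkpoint) and a test half (reported).
#'
#' MIL training rebuilds its dataset with fresh negative draws each epoch,
#' which keeps margin violations — the only channel through which the
#' hard-max loss learns — from dying out on a small corpus; see the methods
#' vignette for why this mirrors the negative-coverage a web-scale corpus
#' provides for free.
#'
#' @param seed Integer seed for the world, the model and the training run.
#' @param context_signal Strength of gold-cluster context tokens in the
#'   generated corpus, in `[0, 1]`.
#' @param n_sentences Corpus size (default 2000, the benchmark default).
#' @param hidden_dim,pos_dim,ffn_hidden Model sizes. The defaults (32 / 8 /
#'   48) are a scaled-down configuration that trains within minutes on one
#'   CPU; the full-size reference setting is `hidden_dim = 100`.
#' @param pre_epochs,mil_epochs Epoch budgets for the two stages.
#' @param pre_draws,mil_draws Negative bags per mention (see
#'   [build_mil_dataset()]).
#' @param mil_k Positive bag size for the MIL stage (TopK strategy; the
#'   strongest reference configuration).
#' @return A list: `bel` (BEL top-1 accuracy), `agree` (pretrained model's
#'   held-out top-1 agreement with BEL), `pre` (pretrained accuracy), `mil`
#'   (MIL-trained accuracy after validation selection), `gain` (`mil -
#'   pre`), `n_test` (test mentions), plus the `models` and the benchmark
#'   `bench` for further inspection.
#' @export
mil_enhancement_run <- function(seed, context_signal = 0.8,
                                n_sentences = 2000L, hidden_dim = 32L,
                                pos_dim = 8L, ffn_hidden = 48L,
                                pre_epochs = 10L, mil_epochs = 8L,
                                pre_draws = 5L, mil_draws = 2L,
                                mil_k = 3L) {
  bench <- generate_benchmark(synth_config(seed = seed,
                                           context_signal = context_signal,
                                           n_sentences = n_sentences))
  tk <- bench$tokenizer
  idx <- bel_index(bench$table, bench$kb, tk)
  lab <- labeled_from_corpus(bench$eval, bench$kb, tk)
  nval <- floor(nrow(lab) / 2)
  val <- lab[seq_len(nval), , drop = FALSE]
  test <- lab[-seq_len(nval), , drop = FALSE]

  pre_ds <- build_mil_dataset(bench$train, bench$dict, bench$kb,
    bench$table,
    candidate_config("topk", "random_topn", k = 1, pool_n = 20,
                     seed = seed),
    tk, negative_draws = pre_draws)
  model <- linking_model(bench$table,
    model_config(word_dim = bench$table$dim, pos_dim = pos_dim,
                 hidden_dim = hidden_dim, layers = 2,
                 ffn_hidden = ffn_hidden, seed = seed))
  model <- pretrain_model(model, pre_ds, bench$kb,
                          train_config(epochs_pretrain = pre_epochs,
                                       seed = seed), tk)

  bel_top1 <- vapply(seq_len(nrow(test)), function(i)
    rank_entities(idx,
                  mention_tokens =
                    test$tokens[[i]][test$start[[i]]:test$end[[i]]],
                  n = 1)$code[[1]], "")
  pred_pre <- vapply(seq_len(nrow(test)), function(i)
    link_mention(model, test$tokens[[i]], test$start[[i]], test$end[[i]],
                 bench$kb, idx, 20, tk)$code[[1]], "")
  a_pre <- mean(pred_pre == test$gold)
  a_pre_val <- evaluate_accuracy(model, val, bench$kb, idx, 20,
                                 tk)$accuracy

  best <- list(acc = a_pre_val, model = model)
  m <- model
  for (ep in seq_len(mil_epochs)) {
    mil_ds <- build_mil_dataset(bench$train, bench$dict, bench$kb,
      bench$table,
      candidate_config("topk", "random_topn", k = mil_k, pool_n = 20,
                       seed = seed * 131L + ep),
      tk, negative_draws = mil_draws)
    m <- train_mil(m, mil_ds, bench$kb,
                   train_config(epochs_mil = 1L, seed = seed * 17L + ep),
                   tk)
    av <- evaluate_accuracy(m, val, bench$kb, idx, 20, tk)$accuracy
    if (av > best$acc + 1e-12) best <- list(acc = av, model = m)
  }
  a_mil <- evaluate_accuracy(best$model, test, bench$kb, idx, 20,
                             tk)$accuracy

  list(bel = mean(bel_top1 == test$gold),
       agree = mean(pred_pre == bel_top1),
       pre = a_pre, mil = a_mil, gain = a_mil - a_pre,
       n_test = nrow(test),
       models = list(pretrained = model, mil = best$model),
       bench = bench)
}
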