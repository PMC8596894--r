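#' Training configuration
#'
#' @param batch_size Data points per optimizer step (default 100).
#' @param learning_rate Adam step size (default 1e-3).
#' @param optimizer Only `"adam"` is provided.
#' @param margin Margin delta of the loss (default 0.1).
#' @param epochs_pretrain Pretraining epochs on BEL pseudo-gold points.
#' @param epochs_mil MIL training epochs.
#' @param patience Early-stopping patience (epochs without validation
#'   accuracy improvement) when a labeled validation set is supplied;
#'   otherwise training runs the configured epochs.
#' @param seed One seed governs batch shuffling for a whole training run.
#' @param verbose Emit one structured log line per epoch.
#' @return A `milink_train_config` list.
#' @export
train_config <- function(batch_size = 100L, learning_rate = 1e-3,
                         optimizer = "adam", margin = 0.1,
                         epochs_pretrain = 5L, epochs_mil = 5L,
                         patience = 3L, seed = 1L, verbose = FALSE) {
  optimizer <- match.arg(optimizer, "adam")
  stopifnot(batch_size >= 1L, learning_rate > 0, margin >= 0,
            epochs_pretrain >= 0L, epochs_mil >= 0L, patience >= 1L)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, optimizer = optimizer,
                 margin = margin,
                 epochs_pretrain = as.integer(epochs_pretrain),
                 epochs_mil = as.integer(epochs_mil),
                 patience = as.integer(patience), seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "milink_train_config")
}

adam_init <- function(params) {
  list(m = zero_grads(params), v = zero_grads(params), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      skip = character(0)) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    if (nm %in% skip) next
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mh <- state$m[[nm]] / bc1
    vh <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}

log_line <- function(verbose, stage, epoch, loss, metric = NA) {
  if (!verbose) return(invisible())
  cat(sprintf("stage=%s epoch=%d loss=%.6f metric=%s\n",
              stage, epoch, loss,
              if (is.na(metric)) "NA" else sprintf("%.4f", metric)))
}

run_epochs <- function(model, points, kb, config, tokenizer, stage,
                       epochs, validation = NULL) {
  skip <- if (model$config$finetune_embeddings) character(0) else "Wemb"
  state <- adam_init(model$params)
  best <- list(acc = -Inf, params = model$params, bad = 0L)
  if (!is.null(validation)) {
    # the incoming model is the epoch-0 checkpoint: early stopping may
    # conclude that no training epoch beat it
    rep0 <- evaluate_accuracy(model, validation$labeled, kb,
                              validation$table,
                              pool_n = validation$pool_n %||% 20L,
                              tokenizer = tokenizer)
    best$acc <- rep0$accuracy
  }
  history <- numeric(0)
  for (epoch in seq_len(epochs)) {
    ord <- sample(length(points))
    epoch_loss <- 0
    for (b0 in seq(1L, length(points), by = config$batch_size)) {
      batch <- points[ord[b0:min(b0 + config$batch_size - 1L,
                                 length(points))]]
      lg <- loss_and_grads(model, batch, kb, delta = config$margin,
                           tokenizer = tokenizer)
      epoch_loss <- epoch_loss + lg$loss
      upd <- adam_step(model$params, lg$grads, state,
                       lr = config$learning_rate, skip = skip)
      model$params <- upd$params
      state <- upd$state
    }
    history <- c(history, epoch_loss)
    metric <- NA
    if (!is.null(validation)) {
      rep <- evaluate_accuracy(model, validation$labeled, kb,
                               validation$table,
                               pool_n = validation$pool_n %||% 20L,
                               tokenizer = tokenizer)
      metric <- rep$accuracy
      if (metric > best$acc + 1e-12) {
        best <- list(acc = metric, params = model$params, bad = 0L)
      } else {
        best$bad <- best$bad + 1L
        if (best$bad >= config$patience) {
          log_line(config$verbose, stage, epoch, epoch_loss, metric)
          model$params <- best$params
          attr(model, "history") <- history
          return(model)
        }
      }
    }
    log_line(config$verbose, stage, epoch, epoch_loss, metric)
  }
  if (!is.null(validation) && best$acc > -Inf) model$params <- best$params
  attr(model, "history") <- history
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pretrain the ranker on BEL pseudo-gold data
#'
#' Stage one of the curriculum: each data point's single positive is the BEL
#' top-1 entity, treated as a pseudo gold label, so the network first
#' acquires the basic linker's ranking behavior before MIL training refines
#' it.
#'
#' @param model A freshly initialized `milink_model`.
#' @param dataset A `milink_mil_dataset` built with `positive_strategy =
#'   "topk"`, `k = 1` (enforced).
#' @param kb A `milink_kb`.
#' @param config A [train_config()] (`epochs_pretrain` epochs are run).
#' @param tokenizer Tokenizer for entity names.
#' @param validation Optional list `(labeled, table, pool_n)` enabling
#'   accuracy-based early stopping, see [evaluate_accuracy()].
#' @return The trained model with `pretrained = TRUE` and an attribute
#'   `history` of per-epoch losses.
#' @export
pretrain_model <- function(model, dataset, kb, config = train_config(),
                           tokenizer = milink_tokenizer("character"),
                           validation = NULL) {
  stopifnot(inherits(model, "milink_model"),
            inherits(dataset, "milink_mil_dataset"))
  tokenizer <- as_tokenizer(tokenizer)
  if (!all(vapply(dataset$points, function(p) length(p$positives) == 1L,
                  logical(1)))) {
    stop("pretraining requires singleton positive bags ",
         "(build the dataset with positive_strategy='topk', k=1)",
         call. = FALSE)
  }
  if (config$epochs_pretrain > 0L && length(dataset$points) > 0L) {
    model <- with_seed(config$seed,
      run_epochs(model, dataset$points, kb, config, tokenizer,
                 stage = "pretrain", epochs = config$epochs_pretrain,
                 validation = validation))
  }
  model$pretrained <- TRUE
  model
}

#' MIL-train a pretrained ranker
#'
#' Stage two: minimizes the triplet max-margin loss over multi-entity
#' positive bags, letting the model exploit context to promote whichever
#' bag member it can best justify — the mechanism by which it can overtake
#' the basic linker it was pretrained to imitate.
#'
#' @param model A pretrained `milink_model` (set `force = TRUE` to train an
#'   unpretrained model anyway).
#' @param dataset A `milink_mil_dataset`.
#' @param kb A `milink_kb`.
#' @param config A [train_config()] (`epochs_mil` epochs are run).
#' @param tokenizer Tokenizer for entity names.
#' @param validation Optional list `(labeled, table, pool_n)`; enables
#'   early stopping on validation accuracy with `config$patience`.
#' @param force Allow training a model that skipped pretraining.
#' @return The trained model (attribute `history` holds per-epoch losses).
#' @export
train_mil <- function(model, dataset, kb, config = train_config(),
                      tokenizer = milink_tokenizer("character"),
                      validation = NULL, force = FALSE) {
  stopifnot(inherits(model, "milink_model"),
            inherits(dataset, "milink_mil_dataset"))
  if (!model$pretrained && !force) {
    stop("model has not been pretrained; pass force = TRUE to override",
         call. = FALSE)
  }
  tokenizer <- as_tokenizer(tokenizer)
  if (config$epochs_mil > 0L && length(dataset$points) > 0L) {
    model <- with_seed(config$seed + 1L,
      run_epochs(model, dataset$points, kb, config, tokenizer,
                 stage = "mil", epochs = config$epochs_mil,
                 validation = validation))
  }
  model
}

#' Link one mention
#'
#' Inference: BEL retrieves the top `pool_n` candidates (the negative bag is
#' empty at inference, so the model only re-ranks this positive pool); each
#' is scored by the neural ranker; the output is sorted by descending model
#' score with ties broken by ascending code. The first row is the predicted
#' link.
#'
#' @param model A trained `milink_model`.
#' @param context Sentence tokens.
#' @param start,end Mention span (1-based inclusive).
#' @param kb A `milink_kb`.
#' @param table A `milink_embeddings` (or a prebuilt [bel_index()]).
#' @param pool_n BEL pool size (default 20).
#' @param tokenizer Shared tokenizer.
#' @return A data.frame `code`, `name`, `cluster`, `bel_score`, `score`,
#'   sorted by descending model score.
#' @export
link_mention <- function(model, context, start, end, kb, table,
                         pool_n = 20L,
                         tokenizer = milink_tokenizer("character")) {
  stopifnot(inherits(model, "milink_model"))
  tokenizer <- as_tokenizer(tokenizer)
  index <- if (inherits(table, "milink_bel")) table
           else bel_index(table, kb, tokenizer)
  pool <- rank_entities(index, mention_tokens = context[start:end],
                        n = pool_n)
  fwd <- context_forward(model, context, start, end)
  scores <- vapply(seq_len(nrow(pool)), function(i) {
    em <- entity_token_mean(model, tokenizer$tokenize(pool$name[[i]]))
    ffn_forward(model, c(em$e, fwd$v))$s
  }, numeric(1))
  ord <- order(-scores, pool$code)
  out <- pool[ord, , drop = FALSE]
  names(out)[names(out) == "score"] <- "bel_score"
  out$score <- scores[ord]
  rownames(out) <- NULL
  out
}

#' Linking accuracy on a labeled set
#'
#' A prediction is correct iff the top-ranked code equals the gold code;
#' accuracy is the ratio of correctly linked mention-entity pairs to all
#' pairs. A gold entity missing from the BEL pool counts as incorrect (pool
#' recall failures propagate).
#'
#' @param model A trained `milink_model`.
#' @param labeled A data.frame (or list of rows) with columns/fields
#'   `tokens` (list of character vectors), `start`, `end`, `gold`.
#' @param kb A `milink_kb` containing every gold code.
#' @param table A `milink_embeddings` or [bel_index()].
#' @param pool_n BEL pool size.
#' @param tokenizer Shared tokenizer.
#' @return A `milink_eval_report`: list with `n_total`, `n_correct`,
#'   `accuracy`, `recall_at_n` (empty here; see [candidate_recall_at_n()]).
#' @export
evaluate_accuracy <- function(model, labeled, kb, table, pool_n = 20L,
                              tokenizer = milink_tokenizer("character")) {
  rows <- labeled_rows(labeled)
  if (length(rows) == 0L) stop("empty labeled set", call. = FALSE)
  tokenizer <- as_tokenizer(tokenizer)
  index <- if (inherits(table, "milink_bel")) table
           else bel_index(table, kb, tokenizer)
  missing <- setdiff(unique(vapply(rows, `[[`, "", "gold")),
                     kb$entities$raw)
  if (length(missing) > 0L) {
    stop("gold code(s) absent from the knowledge base: ",
         paste(sQuote(missing), collapse = ", "), call. = FALSE)
  }
  correct <- 0L
  for (r in rows) {
    ranked <- link_mention(model, r$tokens, r$start, r$end, kb, index,
                           pool_n = pool_n, tokenizer = tokenizer)
    if (ranked$code[[1L]] == r$gold) correct <- correct + 1L
  }
  structure(list(n_total = length(rows), n_correct = correct,
                 accuracy = correct / length(rows),
                 recall_at_n = numeric(0)),
            class = "milink_eval_report")
}

#' @export
print.milink_eval_report <- function(x, ...) {
  cat(sprintf("<milink_eval_report: accuracy %.4f (%d/%d)>\n",
              x$accuracy, x$n_correct, x$n_total))
  if (length(x$recall_at_n) > 0L) {
    cat("recall@N:",
        paste(sprintf("%s=%.4f", names(x$recall_at_n), x$recall_at_n),
              collapse = " "), "\n")
  }
  invisible(x)
}

labeled_rows <- function(labeled) {
  if (is.data.frame(labeled)) {
    lapply(seq_len(nrow(labeled)), function(i) {
      list(tokens = labeled$tokens[[i]], start = labeled$start[[i]],
           end = labeled$end[[i]], gold = labeled$gold[[i]])
    })
  } else {
    labeled
  }
}

#' Gold recall of the BEL candidate pool at several sizes
#'
#' For each pool size N, the fraction of labeled mentions whose gold code
#' appears among the BEL top-N candidates. Non-decreasing in N by
#' construction; the curve typically flattens once pools cover the clusters
#' the mentions live in, which motivates the default pool size of 20.
#'
#' @param table A `milink_embeddings` or [bel_index()].
#' @param kb A `milink_kb`.
#' @param labeled Labeled mentions, as in [evaluate_accuracy()].
#' @param n_values Positive integer pool sizes.
#' @param tokenizer Shared tokenizer.
#' @return Named numeric vector, one recall per N.
#' @export
candidate_recall_at_n <- function(table, kb, labeled,
                                  n_values = c(1L, 5L, 10L, 20L, 50L),
                                  tokenizer = milink_tokenizer("character")) {
  stopifnot(all(n_values >= 1L))
  rows <- labeled_rows(labeled)
  tokenizer <- as_tokenizer(tokenizer)
  index <- if (inherits(table, "milink_bel")) table
           else bel_index(table, kb, tokenizer)
  n_values <- as.integer(n_values)
  hits <- setNames(numeric(length(n_values)), n_values)
  n_max <- min(max(n_values), kb_size(kb))
  for (r in rows) {
    pool <- rank_entities(index, mention_tokens = r$tokens[r$start:r$end],
                          n = n_max)
    rank_gold <- match(r$gold, pool$code)
    for (j in seq_along(n_values)) {
      if (!is.na(rank_gold) && rank_gold <= n_values[[j]]) {
        hits[[j]] <- hits[[j]] + 1
      }
    }
  }
  hits / length(rows)
}
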