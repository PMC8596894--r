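#' Neural ranker configuration
#'
#' Architecture hyperparameters of the entity linking model: a multi-layer
#' bidirectional LSTM over word + positional embeddings encodes the
#' context-mention pair through its boundary states; entities are encoded by
#' token-average embeddings; a one-hidden-layer feed-forward network scores
#' the pair.
#'
#' @param word_dim Word embedding dimension (must match the pretrained
#'   table).
#' @param pos_dim Learned absolute-position embedding dimension.
#' @param hidden_dim LSTM hidden size per direction (default 100).
#' @param layers Number of stacked BiLSTM layers (default 2).
#' @param ffn_hidden Hidden width of the scorer.
#' @param margin Margin delta of the triplet max-margin loss (default 0.1).
#' @param max_len Positions are clipped at this sentence length.
#' @param activation Scorer nonlinearity, `"relu"` or `"tanh"`.
#' @param finetune_embeddings Update the word embedding layer during
#'   training (default `TRUE`; it is initialized from the pretrained
#'   vectors either way).
#' @param seed Seed for parameter initialization.
#' @return A `milink_model_config` list.
#' @export
model_config <- function(word_dim, pos_dim = 20L, hidden_dim = 100L,
                         layers = 2L, ffn_hidden = 100L, margin = 0.1,
                         max_len = 64L, activation = c("relu", "tanh"),
                         finetune_embeddings = TRUE, seed = 1L) {
  activation <- match.arg(activation)
  stopifnot(word_dim >= 1L, pos_dim >= 1L, hidden_dim >= 1L, layers >= 1L,
            ffn_hidden >= 1L, margin >= 0, max_len >= 1L)
  structure(list(word_dim = as.integer(word_dim),
                 pos_dim = as.integer(pos_dim),
                 hidden_dim = as.integer(hidden_dim),
                 layers = as.integer(layers),
                 ffn_hidden = as.integer(ffn_hidden),
                 margin = margin, max_len = as.integer(max_len),
                 activation = activation,
                 finetune_embeddings = isTRUE(finetune_embeddings),
                 seed = as.integer(seed)),
            class = "milink_model_config")
}

unif_mat <- function(nr, nc, r) matrix(runif(nr * nc, -r, r), nr, nc)

lstm_param_names <- function(config) {
  out <- character(0)
  for (l in seq_len(config$layers)) {
    for (d in c("f", "b")) out <- c(out, sprintf("lstm%d%s", l, d))
  }
  out
}

#' Initialize the entity linking model
#'
#' The word embedding layer is initialized from (a copy of) the pretrained
#' table; positional embeddings, LSTM and scorer weights are initialized
#' uniformly at `±1/sqrt(fan_in)`, with forget-gate biases at 1.
#'
#' @param table A `milink_embeddings` providing the pretrained word vectors
#'   and the vocabulary.
#' @param config A [model_config()] whose `word_dim` equals `table$dim`.
#' @return A `milink_model`: list with `config`, `vocab`, `oov_policy`,
#'   `params` (named list of matrices) and a `pretrained` flag.
#' @export
linking_model <- function(table, config) {
  stopifnot(inherits(table, "milink_embeddings"),
            inherits(config, "milink_model_config"))
  if (table$dim != config$word_dim) {
    stop("config word_dim (", config$word_dim,
         ") does not match embedding table (", table$dim, ")", call. = FALSE)
  }
  with_seed(config$seed, {
    H <- config$hidden_dim
    params <- list(
      Wemb = table$vectors,
      Pemb = unif_mat(config$max_len, config$pos_dim,
                      1 / sqrt(config$pos_dim)))
    din <- config$word_dim + config$pos_dim
    for (nm in lstm_param_names(config)) {
      l <- as.integer(substr(nm, 5L, 5L))
      d_in <- if (l == 1L) din else 2L * H
      b <- numeric(4L * H)
      b[(H + 1L):(2L * H)] <- 1  # forget-gate bias
      params[[paste0(nm, "_W")]] <- unif_mat(4L * H, d_in, 1 / sqrt(d_in))
      params[[paste0(nm, "_U")]] <- unif_mat(4L * H, H, 1 / sqrt(H))
      params[[paste0(nm, "_b")]] <- matrix(b, ncol = 1L)
    }
    zdim <- config$word_dim + 4L * H
    params$ffn_W1 <- unif_mat(config$ffn_hidden, zdim, sqrt(2 / zdim))
    params$ffn_b1 <- matrix(0, config$ffn_hidden, 1L)
    params$ffn_W2 <- unif_mat(1L, config$ffn_hidden,
                              sqrt(2 / config$ffn_hidden))
    params$ffn_b2 <- matrix(0, 1L, 1L)
    structure(list(config = config, vocab = rownames(table$vectors),
                   oov_policy = table$oov_policy, params = params,
                   pretrained = FALSE),
              class = "milink_model")
  })
}

#' @export
print.milink_model <- function(x, ...) {
  cat(sprintf(paste0("<milink_model: %d-layer BiLSTM (H=%d), %d-word vocab",
                     " (dim %d), ffn=%d, %spretrained>\n"),
              x$config$layers, x$config$hidden_dim, length(x$vocab),
              x$config$word_dim, x$config$ffn_hidden,
              if (x$pretrained) "" else "not "))
  invisible(x)
}

# Indices of in-vocabulary tokens; NA marks OOV.
vocab_index <- function(model, tokens) match(tokens, model$vocab)

# Full context forward pass; returns caches for backprop.
context_forward <- function(model, tokens, start, end) {
  cfg <- model$config
  T_ <- length(tokens)
  if (T_ == 0L) stop("empty context", call. = FALSE)
  if (start < 1L || end > T_ || start > end) {
    stop("mention span [", start, ", ", end, "] out of bounds for a ",
         T_, "-token context", call. = FALSE)
  }
  idx <- vocab_index(model, tokens)
  E <- matrix(0, cfg$word_dim, T_)
  known <- !is.na(idx)
  if (any(known)) {
    E[, known] <- t(model$params$Wemb[idx[known], , drop = FALSE])
  }
  pos <- pmin(seq_len(T_), cfg$max_len)
  P <- t(model$params$Pemb[pos, , drop = FALSE])
  X <- rbind(E, P)
  H <- cfg$hidden_dim
  caches <- vector("list", cfg$layers)
  for (l in seq_len(cfg$layers)) {
    pf <- model$params; pre <- sprintf("lstm%d", l)
    ff <- lstm_forward_cpp(X, pf[[paste0(pre, "f_W")]],
                           pf[[paste0(pre, "f_U")]],
                           pf[[paste0(pre, "f_b")]][, 1L], FALSE)
    bb <- lstm_forward_cpp(X, pf[[paste0(pre, "b_W")]],
                           pf[[paste0(pre, "b_U")]],
                           pf[[paste0(pre, "b_b")]][, 1L], TRUE)
    caches[[l]] <- list(X = X, f = ff, b = bb)
    X <- rbind(ff$H, bb$H)
  }
  top_f <- caches[[cfg$layers]]$f$H
  top_b <- caches[[cfg$layers]]$b$H
  zero <- numeric(H)
  pre_t <- start - 1L
  v <- c(if (pre_t >= 1L) top_f[, pre_t] else zero,
         if (pre_t >= 1L) top_b[, pre_t] else zero,
         top_f[, end], top_b[, end])
  list(v = v, caches = caches, idx = idx, pos = pos, T_ = T_,
       start = start, end = end)
}

#' Encode a context-mention pair
#'
#' Each token is represented by its word embedding concatenated with a
#' learned absolute-position embedding; the sequence runs through the
#' stacked BiLSTM. The context-mention vector is the concatenation of the
#' last-layer forward and backward states at the token just before the
#' mention and at the mention's last token,
#' `[f(h-1), b(h-1), f(k), b(k)]`. When the mention opens the sentence the
#' two pre-mention slots are zero vectors. Together the four states read the
#' full sentence including the mention (via `f(k)` and `b(h-1)`).
#'
#' @param model A `milink_model`.
#' @param context Character vector of sentence tokens.
#' @param start,end Mention span, 1-based inclusive token indices.
#' @return Numeric vector of length `4 * hidden_dim`.
#' @export
encode_context_mention <- function(model, context, start, end) {
  stopifnot(inherits(model, "milink_model"))
  context_forward(model, context, start, end)$v
}

entity_token_mean <- function(model, tokens) {
  idx <- vocab_index(model, tokens)
  known <- !is.na(idx)
  denom <- if (model$oov_policy == "zero_vector") length(tokens)
           else max(1L, sum(known))
  e <- numeric(model$config$word_dim)
  if (any(known)) {
    e <- colSums(model$params$Wemb[idx[known], , drop = FALSE]) / denom
  }
  list(e = e, idx = idx[known], denom = denom, all_oov = !any(known))
}

#' Encode a KB entity
#'
#' Token-average of the model's word embedding layer over the entity name
#' tokens — the same operation as [average_embed()], but over the model's
#' (possibly fine-tuned) embeddings.
#'
#' @param model A `milink_model`.
#' @param name_tokens Non-empty character vector of entity name tokens.
#' @return Numeric vector of length `word_dim`; attribute `all_oov` marks a
#'   fully out-of-vocabulary name.
#' @export
encode_entity <- function(model, name_tokens) {
  stopifnot(inherits(model, "milink_model"))
  if (length(name_tokens) == 0L) {
    stop("entity name has no tokens", call. = FALSE)
  }
  em <- entity_token_mean(model, name_tokens)
  structure(em$e, all_oov = em$all_oov)
}

activate <- function(x, kind) {
  if (kind == "relu") pmax(x, 0) else tanh(x)
}
activate_grad <- function(pre, post, kind) {
  if (kind == "relu") as.numeric(pre > 0) else 1 - post^2
}

ffn_forward <- function(model, z) {
  p <- model$params
  a1_pre <- as.numeric(p$ffn_W1 %*% z + p$ffn_b1[, 1L])
  a1 <- activate(a1_pre, model$config$activation)
  s <- sum(p$ffn_W2[1L, ] * a1) + p$ffn_b2[1L, 1L]
  list(s = s, z = z, a1_pre = a1_pre, a1 = a1)
}

#' Score a candidate entity against a context-mention pair
#'
#' `s(e, m, c)`: the feed-forward scorer applied to the concatenation of the
#' entity vector and the context-mention boundary-state vector.
#'
#' @param model A `milink_model`.
#' @param name_tokens Entity name tokens.
#' @param context Sentence tokens.
#' @param start,end Mention span (1-based inclusive).
#' @return A single finite number.
#' @export
score_candidate <- function(model, name_tokens, context, start, end) {
  v <- encode_context_mention(model, context, start, end)
  e <- encode_entity(model, name_tokens)
  ffn_forward(model, c(e, v))$s
}

# Resolve entity name tokens for a set of codes, cached per call site.
entity_tokens_for <- function(kb, codes, tokenizer) {
  pos <- match(codes, kb$entities$raw)
  if (anyNA(pos)) {
    stop("code(s) not in knowledge base: ",
         paste(sQuote(codes[is.na(pos)]), collapse = ", "), call. = FALSE)
  }
  lapply(kb$entities$name[pos], tokenizer$tokenize)
}

point_scores <- function(model, point, kb, tokenizer) {
  fwd <- context_forward(model, point$tokens, point$start, point$end)
  score_set <- function(codes) {
    toks <- entity_tokens_for(kb, codes, tokenizer)
    vapply(toks, function(tt) {
      em <- entity_token_mean(model, tt)
      ffn_forward(model, c(em$e, fwd$v))$s
    }, numeric(1))
  }
  list(pos = score_set(point$positives), neg = score_set(point$negatives),
       fwd = fwd)
}

#' Triplet max-margin multi-instance loss
#'
#' For each data point the loss is
#' `[ max_{e in E-} s(e,m,c) + delta - max_{e in E+} s(e,m,c) ]_+`
#' and the batch loss is the sum over data points. The max over a bag is a
#' hard max; a data point contributes zero exactly when its best positive
#' beats its best negative by at least the margin.
#'
#' @param model A `milink_model`.
#' @param batch List of MIL data points (elements of
#'   `milink_mil_dataset$points`); every point needs non-empty `positives`
#'   and `negatives`.
#' @param kb A `milink_kb` resolving candidate codes to names.
#' @param delta Margin (defaults to the model's configured margin).
#' @param tokenizer Tokenizer for entity names.
#' @return A single non-negative number.
#' @export
mil_margin_loss <- function(model, batch, kb,
                            delta = model$config$margin,
                            tokenizer = milink_tokenizer("character")) {
  stopifnot(inherits(model, "milink_model"), delta >= 0)
  tokenizer <- as_tokenizer(tokenizer)
  total <- 0
  for (p in batch) {
    if (length(p$positives) == 0L || length(p$negatives) == 0L) {
      stop("data point ", p$sentence_id,
           " has an empty candidate bag", call. = FALSE)
    }
    sc <- point_scores(model, p, kb, tokenizer)
    total <- total + max(0, max(sc$neg) + delta - max(sc$pos))
  }
  total
}

zero_grads <- function(params) {
  lapply(params, function(p) matrix(0, nrow(p), ncol(p)))
}

add_ffn_grads <- function(model, fwd_ffn, ds, grads) {
  cfg <- model$config
  da1 <- ds * model$params$ffn_W2[1L, ] *
    activate_grad(fwd_ffn$a1_pre, fwd_ffn$a1, cfg$activation)
  grads$ffn_W2 <- grads$ffn_W2 + ds * matrix(fwd_ffn$a1, nrow = 1L)
  grads$ffn_b2 <- grads$ffn_b2 + ds
  grads$ffn_W1 <- grads$ffn_W1 + tcrossprod(da1, fwd_ffn$z)
  grads$ffn_b1 <- grads$ffn_b1 + da1
  dz <- as.numeric(crossprod(model$params$ffn_W1, da1))
  list(grads = grads, dz = dz)
}

# Backprop through the stacked BiLSTM given dLoss/dv.
add_context_grads <- function(model, fwd, dv, grads) {
  cfg <- model$config
  H <- cfg$hidden_dim
  T_ <- fwd$T_
  dHf <- matrix(0, H, T_); dHb <- matrix(0, H, T_)
  pre_t <- fwd$start - 1L
  if (pre_t >= 1L) {
    dHf[, pre_t] <- dHf[, pre_t] + dv[1:H]
    dHb[, pre_t] <- dHb[, pre_t] + dv[(H + 1L):(2L * H)]
  }
  dHf[, fwd$end] <- dHf[, fwd$end] + dv[(2L * H + 1L):(3L * H)]
  dHb[, fwd$end] <- dHb[, fwd$end] + dv[(3L * H + 1L):(4L * H)]
  for (l in rev(seq_len(cfg$layers))) {
    cache <- fwd$caches[[l]]
    pre <- sprintf("lstm%d", l)
    p <- model$params
    bf <- lstm_backward_cpp(cache$X, p[[paste0(pre, "f_W")]],
                            p[[paste0(pre, "f_U")]],
                            cache$f$H, cache$f$C, cache$f$I, cache$f$F,
                            cache$f$O, cache$f$G, dHf, FALSE)
    bb <- lstm_backward_cpp(cache$X, p[[paste0(pre, "b_W")]],
                            p[[paste0(pre, "b_U")]],
                            cache$b$H, cache$b$C, cache$b$I, cache$b$F,
                            cache$b$O, cache$b$G, dHb, TRUE)
    for (d in c("f", "b")) {
      bw <- if (d == "f") bf else bb
      grads[[paste0(pre, d, "_W")]] <- grads[[paste0(pre, d, "_W")]] + bw$dW
      grads[[paste0(pre, d, "_U")]] <- grads[[paste0(pre, d, "_U")]] + bw$dU
      grads[[paste0(pre, d, "_b")]] <- grads[[paste0(pre, d, "_b")]] + bw$db
    }
    dX <- bf$dX + bb$dX
    if (l > 1L) {
      dHf <- dX[1:H, , drop = FALSE]
      dHb <- dX[(H + 1L):(2L * H), , drop = FALSE]
    } else {
      dE <- dX[1:cfg$word_dim, , drop = FALSE]
      dP <- dX[(cfg$word_dim + 1L):(cfg$word_dim + cfg$pos_dim), ,
               drop = FALSE]
      known <- !is.na(fwd$idx)
      if (any(known) && cfg$finetune_embeddings) {
        gw <- rowsum(t(dE[, known, drop = FALSE]),
                     group = fwd$idx[known], reorder = FALSE)
        rows <- as.integer(rownames(gw))
        grads$Wemb[rows, ] <- grads$Wemb[rows, , drop = FALSE] + gw
      }
      gp <- rowsum(t(dP), group = fwd$pos, reorder = FALSE)
      prow <- as.integer(rownames(gp))
      grads$Pemb[prow, ] <- grads$Pemb[prow, , drop = FALSE] + gp
    }
  }
  grads
}

add_entity_grads <- function(model, em, dz_e, grads) {
  if (!model$config$finetune_embeddings || length(em$idx) == 0L) return(grads)
  g <- dz_e / em$denom
  rows <- unique(em$idx)
  for (r in rows) {
    n_occ <- sum(em$idx == r)
    grads$Wemb[r, ] <- grads$Wemb[r, ] + n_occ * g
  }
  grads
}

# Loss and full analytic gradients over a batch of MIL data points.
# The hard max routes the gradient through exactly one positive and one
# negative entity per violating data point; the context vector is shared by
# both scorer passes, so their dv contributions add before BPTT.
loss_and_grads <- function(model, batch, kb, delta = model$config$margin,
                           tokenizer = milink_tokenizer("character")) {
  tokenizer <- as_tokenizer(tokenizer)
  cfg <- model$config
  grads <- zero_grads(model$params)
  total <- 0
  H4 <- 4L * cfg$hidden_dim
  for (p in batch) {
    fwd <- context_forward(model, p$tokens, p$start, p$end)
    pos_toks <- entity_tokens_for(kb, p$positives, tokenizer)
    neg_toks <- entity_tokens_for(kb, p$negatives, tokenizer)
    pos_em <- lapply(pos_toks, entity_token_mean, model = model)
    neg_em <- lapply(neg_toks, entity_token_mean, model = model)
    pos_ffn <- lapply(pos_em, function(em) ffn_forward(model, c(em$e, fwd$v)))
    neg_ffn <- lapply(neg_em, function(em) ffn_forward(model, c(em$e, fwd$v)))
    s_pos <- vapply(pos_ffn, `[[`, numeric(1), "s")
    s_neg <- vapply(neg_ffn, `[[`, numeric(1), "s")
    i_pos <- which.max(s_pos); i_neg <- which.max(s_neg)
    hinge <- s_neg[i_neg] + delta - s_pos[i_pos]
    if (hinge <= 0) next
    total <- total + hinge
    dv <- numeric(H4)
    for (side in c("neg", "pos")) {
      ds <- if (side == "neg") 1 else -1
      ffn <- if (side == "neg") neg_ffn[[i_neg]] else pos_ffn[[i_pos]]
      em <- if (side == "neg") neg_em[[i_neg]] else pos_em[[i_pos]]
      res <- add_ffn_grads(model, ffn, ds, grads)
      grads <- res$grads
      grads <- add_entity_grads(model, em, res$dz[1:cfg$word_dim], grads)
      dv <- dv + res$dz[(cfg$word_dim + 1L):(cfg$word_dim + H4)]
    }
    grads <- add_context_grads(model, fwd, dv, grads)
  }
  list(loss = total, grads = grads)
}

#' Save a model checkpoint
#'
#' Writes the configuration, vocabulary and all parameter matrices as one
#' JSON document (text-only; adequate for the small models this package
#' trains).
#'
#' @param model A `milink_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "milink_model"))
  payload <- list(
    config = unclass(model$config),
    vocab = model$vocab,
    oov_policy = model$oov_policy,
    pretrained = model$pretrained,
    params = lapply(model$params, function(p) {
      list(dim = dim(p), data = as.numeric(p))
    }))
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path File written by [save_model()].
#' @param table Optional `milink_embeddings`; when supplied, the checkpoint's
#'   vocabulary and word dimension are validated against it.
#' @return A `milink_model`.
#' @export
load_model <- function(path, table = NULL) {
  payload <- jsonlite::fromJSON(readLines(path, warn = FALSE),
                                simplifyVector = TRUE)
  cfg <- payload$config
  config <- model_config(word_dim = cfg$word_dim, pos_dim = cfg$pos_dim,
                         hidden_dim = cfg$hidden_dim, layers = cfg$layers,
                         ffn_hidden = cfg$ffn_hidden, margin = cfg$margin,
                         max_len = cfg$max_len, activation = cfg$activation,
                         finetune_embeddings = cfg$finetune_embeddings,
                         seed = cfg$seed)
  params <- lapply(payload$params, function(p) {
    matrix(p$data, nrow = p$dim[[1L]], ncol = p$dim[[2L]])
  })
  if (!is.null(table)) {
    if (table$dim != config$word_dim) {
      stop("checkpoint word_dim ", config$word_dim,
           " does not match embedding file (", table$dim, ")", call. = FALSE)
    }
    if (!identical(rownames(table$vectors), payload$vocab)) {
      stop("checkpoint vocabulary does not match embedding file",
           call. = FALSE)
    }
  }
  rownames(params$Wemb) <- payload$vocab
  structure(list(config = config, vocab = payload$vocab,
                 oov_policy = payload$oov_policy, params = params,
                 pretrained = isTRUE(payload$pretrained)),
            class = "milink_model")
}
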