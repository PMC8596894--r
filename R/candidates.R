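#' Candidate-generation configuration
#'
#' Controls how the positive bag E+ and negative bag E- of each MIL data
#' point are built from the BEL candidate pool.
#'
#' @param positive_strategy `"topk"` (the K most similar entities) or
#'   `"clusterk"` (sweep the pool by descending similarity, pulling in whole
#'   ICD10 clusters until K distinct clusters are covered).
#' @param negative_strategy `"random_topn"` (K hard negatives sampled from
#'   the size-N pool, excluding E+) or `"random_all"` (K negatives sampled
#'   from the whole KB minus E+).
#' @param k Number of positive entities (topk) or clusters (clusterk), and
#'   the number of negatives.
#' @param pool_n Size N of the BEL candidate pool; must exceed `k`. The
#'   default 20 follows the observation that pool recall plateaus past
#'   N = 20.
#' @param seed Integer seed governing negative sampling for one dataset
#'   build.
#' @return A `milink_candidate_config` list.
#' @export
candidate_config <- function(positive_strategy = c("topk", "clusterk"),
                             negative_strategy = c("random_topn", "random_all"),
                             k = 3L, pool_n = 20L, seed = 1L) {
  positive_strategy <- match.arg(positive_strategy)
  negative_strategy <- match.arg(negative_strategy)
  k <- as.integer(k); pool_n <- as.integer(pool_n)
  stopifnot(k >= 1L)
  if (pool_n <= k) stop("pool_n must exceed k (N > K)", call. = FALSE)
  structure(list(positive_strategy = positive_strategy,
                 negative_strategy = negative_strategy,
                 k = k, pool_n = pool_n, seed = as.integer(seed)),
            class = "milink_candidate_config")
}

#' TopK positive candidates
#'
#' The K entities most similar to the mention, in ranking order.
#'
#' @param ranked A data.frame from [rank_entities()] (descending by score).
#' @param k Number of positives.
#' @return Character vector of entity codes.
#' @export
select_positives_topk <- function(ranked, k) {
  stopifnot(k >= 1L)
  if (nrow(ranked) == 0L) stop("empty candidate ranking", call. = FALSE)
  if (nrow(ranked) < k) {
    warning("ranking holds ", nrow(ranked), " entities; k=", k,
            " positives requested")
  }
  head(ranked$code, min(k, nrow(ranked)))
}

#' ClusterK positive candidates
#'
#' Sweeps the pool by descending similarity. Each time an entity of a
#' not-yet-covered cluster is reached, that entity and every pool member of
#' the same cluster are added; the sweep stops once `k` distinct clusters
#' are covered. Exploiting the code hierarchy this way shrinks the positive
#' bag without giving up much gold recall.
#'
#' @param pool A data.frame from [rank_entities()] with a `cluster` column
#'   (the size-N pool), descending by score.
#' @param kb A `milink_kb` (used only when `pool` lacks cluster keys).
#' @param k Number of clusters to cover.
#' @return Character vector of entity codes (pool order within the sweep).
#' @export
select_positives_clusterk <- function(pool, kb = NULL, k) {
  stopifnot(k >= 1L)
  if (nrow(pool) == 0L) stop("empty candidate pool", call. = FALSE)
  clusters <- pool$cluster
  if (is.null(clusters)) {
    stopifnot(inherits(kb, "milink_kb"))
    clusters <- kb$entities$cluster[match(pool$code, kb$entities$raw)]
  }
  n_avail <- length(unique(clusters))
  if (n_avail < k) {
    warning("pool holds ", n_avail, " clusters; k=", k,
            " requested — returning the whole pool")
    return(pool$code)
  }
  covered <- character(0)
  selected <- character(0)
  for (i in seq_len(nrow(pool))) {
    cl <- clusters[[i]]
    if (cl %in% covered) next
    covered <- c(covered, cl)
    selected <- c(selected, pool$code[clusters == cl])
    if (length(covered) == k) break
  }
  selected
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Random-All negative candidates
#'
#' K entities sampled uniformly without replacement from the whole KB minus
#' the positive bag. These negatives are easy (usually far from the
#' mention); Random-TopN gives harder ones.
#'
#' @param kb A `milink_kb`.
#' @param positives Character vector of positive entity codes.
#' @param k Number of negatives.
#' @param seed Integer seed, or `NULL` to draw from the current RNG stream.
#' @return Character vector of codes disjoint from `positives`.
#' @export
select_negatives_random_all <- function(kb, positives, k, seed = NULL) {
  stopifnot(inherits(kb, "milink_kb"), k >= 1L)
  eligible <- setdiff(kb$entities$raw, positives)
  if (length(eligible) < k) {
    stop("only ", length(eligible), " entities remain outside E+; ",
         "cannot sample k=", k, " negatives", call. = FALSE)
  }
  with_seed(seed, sample(eligible, k))
}

#' Random-TopN negative candidates
#'
#' K hard negatives sampled uniformly without replacement from the size-N
#' BEL pool, excluding the positive bag. If fewer than `k` pool members are
#' eligible, all of them are returned with a warning.
#'
#' @param pool A data.frame from [rank_entities()] (the size-N pool).
#' @param positives Character vector of positive entity codes.
#' @param k Number of negatives.
#' @param seed Integer seed, or `NULL` to draw from the current RNG stream.
#' @return Character vector of codes disjoint from `positives`.
#' @export
select_negatives_random_topn <- function(pool, positives, k, seed = NULL) {
  stopifnot(k >= 1L)
  eligible <- setdiff(pool$code, positives)
  if (length(eligible) == 0L) {
    stop("candidate pool is entirely contained in E+", call. = FALSE)
  }
  if (length(eligible) < k) {
    warning("only ", length(eligible), " pool entities outside E+; ",
            "returning all of them")
    k <- length(eligible)
  }
  with_seed(seed, sample(eligible, k))
}

#' Build a MIL dataset from a raw corpus
#'
#' For every dictionary mention detected in the corpus, ranks KB entities
#' with BEL, forms the size-N pool, and builds the positive bag E+ and
#' negative bag E- according to `config`. Mentions whose surface string
#' equals a KB entity name verbatim are excluded — those cases are solved by
#' plain string match and would not exercise the model. One RNG stream,
#' seeded from `config$seed`, drives all negative sampling, so a dataset is
#' a reproducible artifact.
#'
#' @param corpus A data.frame with columns `sentence_id` and `text` (or a
#'   list-column `tokens` of pre-tokenized sentences).
#' @param dict A `milink_dictionary`.
#' @param kb A `milink_kb`.
#' @param table A `milink_embeddings`.
#' @param config A [candidate_config()].
#' @param tokenizer Tokenizer shared by corpus, dictionary and KB names.
#' @param gold Optional named character vector `sentence_id -> gold code`
#'   (synthetic / evaluation data only); recorded on matching data points.
#' @param negative_draws Number of independently sampled negative bags per
#'   mention; each draw becomes its own data point (positives identical).
#'   At web scale a mention surface recurs thousands of times and thereby
#'   meets many different random negatives; on a small corpus `negative_draws
#'   > 1` restores that negative-pool coverage, which margin training needs
#'   to pin down a full ranking. Default 1 (one data point per mention).
#' @return A `milink_mil_dataset`: list of data points, each with
#'   `sentence_id`, `tokens`, `start`, `end` (1-based inclusive span),
#'   `positives`, `negatives`, `gold` (possibly `NA`).
#' @export
build_mil_dataset <- function(corpus, dict, kb, table, config,
                              tokenizer = milink_tokenizer("character"),
                              gold = NULL, negative_draws = 1L) {
  stopifnot(negative_draws >= 1L)
  stopifnot(inherits(config, "milink_candidate_config"))
  tokenizer <- as_tokenizer(tokenizer)
  index <- bel_index(table, kb, tokenizer)
  entity_names <- kb$entities$name
  points <- vector("list", 0L)
  with_seed(config$seed, {
    for (r in seq_len(nrow(corpus))) {
      sid <- corpus$sentence_id[[r]]
      toks <- if (!is.null(corpus$tokens)) corpus$tokens[[r]]
              else tokenizer$tokenize(corpus$text[[r]])
      spans <- tryCatch(detect_mentions(toks, dict, tokenizer),
                        error = function(e) {
                          stop("sentence ", sid, ": ", conditionMessage(e),
                               call. = FALSE)
                        })
      if (nrow(spans) == 0L) next
      for (s in seq_len(nrow(spans))) {
        if (spans$surface[[s]] %in% entity_names) next  # exact string match
        mtoks <- toks[spans$start[[s]]:spans$end[[s]]]
        pool <- rank_entities(index, mention_tokens = mtoks,
                              n = config$pool_n)
        pos <- switch(config$positive_strategy,
          topk = select_positives_topk(pool, config$k),
          clusterk = select_positives_clusterk(pool, kb, config$k))
        g <- if (!is.null(gold)) unname(gold[as.character(sid)]) else NA_character_
        for (draw in seq_len(negative_draws)) {
          neg <- switch(config$negative_strategy,
            random_topn = select_negatives_random_topn(pool, pos, config$k,
                                                       seed = NULL),
            random_all = select_negatives_random_all(kb, pos, config$k,
                                                     seed = NULL))
          points[[length(points) + 1L]] <- list(
            sentence_id = sid, tokens = toks,
            start = spans$start[[s]], end = spans$end[[s]],
            positives = pos, negatives = neg,
            gold = if (is.null(g) || is.na(g)) NA_character_ else g)
        }
      }
    }
  })
  structure(list(points = points, config = config,
                 tokenizer = tokenizer$name),
            class = "milink_mil_dataset")
}

#' @export
print.milink_mil_dataset <- function(x, ...) {
  cat(sprintf("<milink_mil_dataset: %d data points (%s / %s, k=%d, N=%d)>\n",
              length(x$points), x$config$positive_strategy,
              x$config$negative_strategy, x$config$k, x$config$pool_n))
  invisible(x)
}

#' Write a MIL dataset as JSONL
#'
#' One data point per line with fields `sentence_id, tokens, mention_start,
#' mention_end, positives, negatives, gold` (nullable). Span indices on disk
#' are 0-based half-open; the in-memory representation is 1-based inclusive.
#'
#' @param dataset A `milink_mil_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mil_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "milink_mil_dataset"))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (p in dataset$points) {
    rec <- list(sentence_id = p$sentence_id, tokens = p$tokens,
                mention_start = p$start - 1L, mention_end = p$end,
                positives = as.list(p$positives),
                negatives = as.list(p$negatives),
                gold = if (is.na(p$gold)) NULL else p$gold)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null"), con)
  }
  invisible(path)
}

#' Read a MIL dataset from JSONL
#'
#' @param path File written by [write_mil_dataset()].
#' @return A `milink_mil_dataset` (without the originating config).
#' @export
read_mil_dataset <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  points <- lapply(lines, function(l) {
    rec <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    list(sentence_id = rec$sentence_id,
         tokens = as.character(rec$tokens),
         start = rec$mention_start + 1L, end = rec$mention_end,
         positives = as.character(rec$positives),
         negatives = as.character(rec$negatives),
         gold = if (is.null(rec$gold)) NA_character_ else rec$gold)
  })
  structure(list(points = points, config = NULL, tokenizer = NA_character_),
            class = "milink_mil_dataset")
}
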