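#' Precompute entity vectors for the basic entity linker
#'
#' Every KB entity's representation (token-average embedding of its name) is
#' computed once and cached; retrieval then reduces to one matrix-vector
#' cosine against the mention vector.
#'
#' @param table A `milink_embeddings`.
#' @param kb A `milink_kb`.
#' @param tokenizer A [milink_tokenizer()] (or its name). Entity names and
#'   mentions must share one tokenizer.
#' @return A `milink_bel` index: list with `matrix` (entities x dim, KB
#'   order), `norms`, `codes`, and the inputs it was built from.
#' @export
bel_index <- function(table, kb, tokenizer = milink_tokenizer("character")) {
  stopifnot(inherits(table, "milink_embeddings"), inherits(kb, "milink_kb"))
  tokenizer <- as_tokenizer(tokenizer)
  n <- kb_size(kb)
  if (n == 0L) stop("cannot index an empty knowledge base", call. = FALSE)
  mat <- matrix(0, nrow = n, ncol = table$dim)
  for (i in seq_len(n)) {
    mat[i, ] <- average_embed(table, tokenizer$tokenize(kb$entities$name[[i]]))
  }
  structure(list(matrix = mat, norms = sqrt(rowSums(mat^2)),
                 codes = kb$entities$raw, table = table, kb = kb,
                 tokenizer = tokenizer),
            class = "milink_bel")
}

#' Rank KB entities by embedding similarity to a mention (BEL)
#'
#' The basic entity linker: cosine similarity between the mention's average
#' word embedding and each entity's cached average name embedding. Ties are
#' broken by ascending raw code so rankings are reproducible.
#'
#' @param table A `milink_embeddings`, or a prebuilt [bel_index()] (then
#'   `kb`/`tokenizer` are taken from the index).
#' @param kb A `milink_kb`; ignored when `table` is a `milink_bel`.
#' @param mention_tokens Non-empty character vector of mention tokens.
#' @param n Number of candidates to return; capped at the KB size.
#' @param tokenizer Tokenizer used for entity names when building a fresh
#'   index.
#' @return A data.frame with columns `code`, `name`, `cluster`, `score`,
#'   sorted by descending score.
#' @export
rank_entities <- function(table, kb = NULL, mention_tokens, n = 20L,
                          tokenizer = milink_tokenizer("character")) {
  if (inherits(table, "milink_bel")) {
    index <- table
  } else {
    index <- bel_index(table, kb, tokenizer)
  }
  stopifnot(n >= 1L)
  if (length(mention_tokens) == 0L) {
    stop("mention has no tokens", call. = FALSE)
  }
  m <- average_embed(index$table, mention_tokens)
  nm <- sqrt(sum(m^2))
  scores <- if (nm == 0) {
    rep(0, length(index$codes))
  } else {
    denom <- index$norms * nm
    raw <- as.numeric(index$matrix %*% m)
    ifelse(denom == 0, 0, raw / ifelse(denom == 0, 1, denom))
  }
  ord <- order(-scores, index$codes)
  top <- head(ord, min(n, length(ord)))
  ents <- index$kb$entities[top, , drop = FALSE]
  data.frame(code = ents$raw, name = ents$name, cluster = ents$cluster,
             score = scores[top], row.names = NULL,
             stringsAsFactors = FALSE)
}
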