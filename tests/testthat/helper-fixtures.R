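# Shared in-code fixtures: a hand-sized KB, embeddings with known geometry,
# and a tiny model configuration cheap enough for exhaustive checks.

toy_kb <- function() {
  knowledge_base(
    codes = c("R50.800", "R50.801", "R50.900", "K52.916", "R11.x02",
              "A00"),
    names = c("fever specified", "fever recurrent", "fever unspecified",
              "diarrhea infectious", "nausea plain", "cholera classic"))
}

# deterministic embeddings: every token gets a fixed vector
toy_embeddings <- function(dim = 4, seed = 99, extra_tokens = character(0)) {
  tokens <- unique(c(unlist(strsplit(toy_kb()$entities$name, " ")),
                     "severe", "mild", "the", extra_tokens))
  set.seed(seed)
  m <- matrix(rnorm(length(tokens) * dim), ncol = dim,
              dimnames = list(tokens, NULL))
  embedding_table(m)
}

ws <- function() milink_tokenizer("whitespace")

tiny_model <- function(table, seed = 7, ...) {
  linking_model(table, model_config(word_dim = table$dim, pos_dim = 2,
                                    hidden_dim = 3, layers = 2,
                                    ffn_hidden = 5, seed = seed, ...))
}

# brute-force cosine ranking oracle, independent of rank_entities internals
brute_rank <- function(table, kb, mention_tokens, tokenizer) {
  scores <- vapply(seq_len(nrow(kb$entities)), function(i) {
    e <- average_embed(table, tokenizer$tokenize(kb$entities$name[[i]]))
    m <- average_embed(table, mention_tokens)
    cosine_sim(m, e)
  }, numeric(1))
  kb$entities$raw[order(-scores, kb$entities$raw)]
}

random_kb <- function(n_entities, vocab_pool, seed) {
  set.seed(seed)
  n_cat <- max(1L, n_entities %/% 4L)
  codes <- character(0)
  while (length(codes) < n_entities) {
    cat_code <- sprintf("%s%02d", sample(LETTERS, 1), sample(0:99, 1))
    sub <- sprintf("%02d%d", sample(0:99, 1), sample(0:9, 1))
    codes <- unique(c(codes, paste0(cat_code, ".", sub)))
  }
  codes <- codes[seq_len(n_entities)]
  names_ <- vapply(seq_len(n_entities), function(i)
    paste(sample(vocab_pool, 2), collapse = " "), "")
  knowledge_base(codes, names_)
}

random_embeddings <- function(vocab, dim, seed) {
  set.seed(seed)
  embedding_table(matrix(rnorm(length(vocab) * dim), ncol = dim,
                         dimnames = list(vocab, NULL)))
}
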