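#' Synthetic benchmark configuration
#'
#' The generator emulates the four pipeline inputs: a hierarchical
#' ICD10-like KB, word embeddings whose cluster-mates are geometrically
#' close, a symptom dictionary holding canonical names plus noisy colloquial
#' variants, and a gold-labeled sentence corpus embedding those variants.
#'
#' Geometry: every category gets a random unit direction; cluster centroids
#' are category direction plus a scaled random offset, so the hard
#' confusions are between neighboring clusters of one category (mirroring
#' real ICD10 error cases, where the difficult candidates are adjacent
#' codes). Canonical name tokens scatter around their cluster centroid with
#' dispersion `cluster_tightness`; colloquial variant tokens scatter around
#' their *entity's* canonical mean with four times that dispersion;
#' cluster-indicative context-signal tokens sit tightly by the centroid;
#' background filler tokens are random unit vectors.
#'
#' @param n_categories Number of ICD10-like categories (letter + 2 digits).
#' @param clusters_per_category Clusters (first sub-classifications) per
#'   category.
#' @param entities_per_cluster Entities (extension digits) per cluster; at
#'   most 10.
#' @param embed_dim Embedding dimension.
#' @param cluster_tightness Within-cluster token dispersion relative to the
#'   between-cluster scale, in (0, 1]; larger is *looser* (1 makes the
#'   within/between separation vanish).
#' @param variant_rate Probability that a sentence's mention uses a noisy
#'   colloquial variant instead of the canonical entity name. Canonical
#'   (exact-string) mentions are later excluded from training and
#'   evaluation, as they are solvable by plain string match.
#' @param context_signal Probability that a sentence carries
#'   gold-cluster-indicative signal tokens — the context information that
#'   surface similarity alone cannot see.
#' @param n_sentences Corpus size.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A `milink_synth_config` list.
#' @export
synth_config <- function(n_categories = 2L, clusters_per_category = 3L,
                         entities_per_cluster = 4L, embed_dim = 32L,
                         cluster_tightness = 0.3, variant_rate = 0.7,
                         context_signal = 0.8, n_sentences = 2000L,
                         seed = 1L) {
  stopifnot(n_categories >= 1L, clusters_per_category >= 1L,
            entities_per_cluster >= 1L, embed_dim >= 2L,
            cluster_tightness > 0, cluster_tightness <= 1,
            variant_rate >= 0, variant_rate <= 1,
            context_signal >= 0, context_signal <= 1, n_sentences >= 1L)
  structure(list(n_categories = as.integer(n_categories),
                 clusters_per_category = as.integer(clusters_per_category),
                 entities_per_cluster = as.integer(entities_per_cluster),
                 embed_dim = as.integer(embed_dim),
                 cluster_tightness = cluster_tightness,
                 variant_rate = variant_rate,
                 context_signal = context_signal,
                 n_sentences = as.integer(n_sentences),
                 seed = as.integer(seed)),
            class = "milink_synth_config")
}

san <- function(x) gsub(".", "_", x, fixed = TRUE)

#' Generate a synthetic ICD10-like knowledge base
#'
#' Codes follow the grammar letter + two digits, `"."`, two-digit first
#' sub-classification, one extension digit (e.g. `"A00.010"`), so every
#' code round-trips through [parse_code()] and [cluster_key()] to its
#' intended cluster. Entity names are two synthetic tokens.
#'
#' @param config A [synth_config()].
#' @return A `milink_kb` with `n_categories * clusters_per_category *
#'   entities_per_cluster` entities.
#' @export
generate_kb <- function(config) {
  stopifnot(inherits(config, "milink_synth_config"))
  if (config$n_categories > 2600L || config$clusters_per_category > 100L ||
      config$entities_per_cluster > 10L) {
    stop("configuration exceeds the synthetic code space", call. = FALSE)
  }
  codes <- character(0); names_ <- character(0)
  for (ci in seq_len(config$n_categories)) {
    cat_code <- sprintf("%s%02d", LETTERS[((ci - 1L) %/% 100L) + 1L],
                        (ci - 1L) %% 100L)
    for (cl in seq_len(config$clusters_per_category)) {
      for (e in seq_len(config$entities_per_cluster)) {
        code <- sprintf("%s.%02d%d", cat_code, cl - 1L, e - 1L)
        codes <- c(codes, code)
        names_ <- c(names_, paste(sprintf("nm_%s_%d", san(code), 1:2),
                                  collapse = " "))
      }
    }
  }
  knowledge_base(codes, names_)
}

unit_vec <- function(d) {
  v <- rnorm(d)
  v / sqrt(sum(v^2))
}

n_variants_per_entity <- 2L
n_signal_per_cluster <- 3L
n_background_tokens <- 60L
# Geometry constants, calibrated once so that the default world reproduces
# the difficulty regime of real colloquial symptom linking: basic-linker
# top-1 accuracy around 0.6 on variant mentions and a pool recall curve
# that plateaus well before N = 20.
cluster_offset_scale <- 0.4
variant_dispersion_mult <- 4

#' Generate synthetic embeddings for a KB
#'
#' Builds the full vocabulary — canonical name tokens, colloquial variant
#' tokens, cluster signal tokens and background tokens — with the geometry
#' described in [synth_config()].
#'
#' @param kb A `milink_kb` from [generate_kb()].
#' @param config The same [synth_config()].
#' @return A list: `table` (a `milink_embeddings`), `variants` (data.frame
#'   `code`, `surface` of every colloquial variant), `signal_tokens`
#'   (named list cluster -> character vector).
#' @export
generate_embeddings <- function(kb, config) {
  stopifnot(inherits(kb, "milink_kb"), inherits(config, "milink_synth_config"))
  d <- config$embed_dim
  tight <- config$cluster_tightness
  with_seed(config$seed + 1L, {
    ents <- kb$entities
    cats <- unique(ents$category)
    cat_dirs <- lapply(cats, function(x) unit_vec(d))
    names(cat_dirs) <- cats
    clusters <- unique(ents$cluster)
    centroids <- list()
    for (cl in clusters) {
      cat_of <- ents$category[match(cl, ents$cluster)]
      v <- cat_dirs[[cat_of]] + cluster_offset_scale * unit_vec(d)
      centroids[[cl]] <- v / sqrt(sum(v^2))
    }
    vocab <- list()
    put <- function(token, vec) vocab[[token]] <<- vec
    ent_means <- list()
    for (i in seq_len(nrow(ents))) {
      mu <- centroids[[ents$cluster[[i]]]]
      toks <- strsplit(ents$name[[i]], " ", fixed = TRUE)[[1L]]
      vecs <- lapply(toks, function(tk) {
        v <- mu + tight * rnorm(d) / sqrt(d)
        put(tk, v)
        v
      })
      ent_means[[ents$raw[[i]]]] <- Reduce(`+`, vecs) / length(vecs)
    }
    var_code <- character(0); var_surface <- character(0)
    for (i in seq_len(nrow(ents))) {
      base <- ent_means[[ents$raw[[i]]]]
      for (v in seq_len(n_variants_per_entity)) {
        toks <- sprintf("vr_%s_%d_%d", san(ents$raw[[i]]), v, 1:2)
        for (tk in toks) {
          put(tk, base + variant_dispersion_mult * tight * rnorm(d) / sqrt(d))
        }
        var_code <- c(var_code, ents$raw[[i]])
        var_surface <- c(var_surface, paste(toks, collapse = " "))
      }
    }
    signal_tokens <- list()
    for (cl in clusters) {
      toks <- sprintf("sg_%s_%d", san(cl), seq_len(n_signal_per_cluster))
      for (tk in toks) {
        put(tk, centroids[[cl]] + 0.5 * tight * rnorm(d) / sqrt(d))
      }
      signal_tokens[[cl]] <- toks
    }
    for (i in seq_len(n_background_tokens)) {
      put(sprintf("bg_%03d", i), unit_vec(d))
    }
    mat <- do.call(rbind, vocab)
    rownames(mat) <- names(vocab)
    list(table = embedding_table(mat),
         variants = data.frame(code = var_code, surface = var_surface,
                               stringsAsFactors = FALSE),
         signal_tokens = signal_tokens)
  })
}

#' Generate a labeled synthetic corpus and its term dictionary
#'
#' Each sentence holds background filler tokens, exactly one mention
#' (canonical entity name with probability `1 - variant_rate`, else one of
#' the entity's colloquial variants, which never equals any entity name
#' string), and — with probability `context_signal` — two
#' gold-cluster-indicative signal tokens. The gold code and the mention span
#' are recorded. The dictionary contains every canonical name and every
#' variant, each mapped to its canonical entity.
#'
#' @param kb A `milink_kb`.
#' @param emb The list returned by [generate_embeddings()].
#' @param config The same [synth_config()].
#' @return A list: `corpus` (data.frame `sentence_id`, `text`, `gold`,
#'   `start`, `end`, `is_variant`; span indices are 1-based inclusive token
#'   positions) and `dict` (a `milink_dictionary`).
#' @export
generate_corpus <- function(kb, emb, config) {
  stopifnot(inherits(kb, "milink_kb"), inherits(config, "milink_synth_config"))
  ents <- kb$entities
  with_seed(config$seed + 2L, {
    n <- config$n_sentences
    text <- character(n); gold <- character(n)
    start <- integer(n); end <- integer(n); is_variant <- logical(n)
    for (s in seq_len(n)) {
      ei <- sample.int(nrow(ents), 1L)
      gold[[s]] <- ents$raw[[ei]]
      use_variant <- runif(1) < config$variant_rate
      is_variant[[s]] <- use_variant
      mention <- if (use_variant) {
        cand <- emb$variants$surface[emb$variants$code == gold[[s]]]
        cand[[sample.int(length(cand), 1L)]]
      } else {
        ents$name[[ei]]
      }
      mtoks <- strsplit(mention, " ", fixed = TRUE)[[1L]]
      n_bg <- sample(4:7, 1L)
      ctx <- sprintf("bg_%03d", sample.int(n_background_tokens, n_bg,
                                           replace = TRUE))
      if (runif(1) < config$context_signal) {
        sig <- emb$signal_tokens[[ents$cluster[[ei]]]]
        ctx <- c(ctx, sig[sample.int(length(sig), 2L, replace = TRUE)])
      } else {
        ctx <- c(ctx, sprintf("bg_%03d",
                              sample.int(n_background_tokens, 2L,
                                         replace = TRUE)))
      }
      ctx <- ctx[sample.int(length(ctx))]
      at <- sample.int(length(ctx) + 1L, 1L)
      toks <- append(ctx, mtoks, after = at - 1L)
      text[[s]] <- paste(toks, collapse = " ")
      start[[s]] <- at
      end[[s]] <- at + length(mtoks) - 1L
    }
    terms <- c(ents$name, emb$variants$surface)
    canonical <- setNames(c(ents$raw, emb$variants$code), terms)
    list(corpus = data.frame(sentence_id = seq_len(n), text = text,
                             gold = gold, start = start, end = end,
                             is_variant = is_variant,
                             stringsAsFactors = FALSE),
         dict = term_dictionary(terms, canonical))
  })
}

#' Generate a full synthetic benchmark
#'
#' Convenience wrapper running [generate_kb()], [generate_embeddings()] and
#' [generate_corpus()], then splitting the corpus into train and eval
#' partitions.
#'
#' @param config A [synth_config()].
#' @param train_frac Fraction of sentences assigned to the training split.
#' @return A list: `kb`, `table`, `dict`, `corpus`, `train` / `eval`
#'   (corpus subsets), `gold` (named vector sentence_id -> code),
#'   `tokenizer` (whitespace), `config`.
#' @export
generate_benchmark <- function(config = synth_config(), train_frac = 0.75) {
  kb <- generate_kb(config)
  emb <- generate_embeddings(kb, config)
  cg <- generate_corpus(kb, emb, config)
  n <- nrow(cg$corpus)
  idx <- with_seed(config$seed + 3L,
                   sample.int(n, size = floor(train_frac * n)))
  list(kb = kb, table = emb$table, dict = cg$dict, corpus = cg$corpus,
       train = cg$corpus[sort(idx), , drop = FALSE],
       eval = cg$corpus[-sort(idx), , drop = FALSE],
       gold = setNames(cg$corpus$gold, cg$corpus$sentence_id),
       tokenizer = milink_tokenizer("whitespace"), config = config)
}

#' Labeled mentions from a synthetic corpus
#'
#' Converts corpus rows into the labeled-set shape consumed by
#' [evaluate_accuracy()] and [candidate_recall_at_n()]. Mentions whose
#' surface equals a KB entity name verbatim are dropped by default — they
#' are solvable by exact string match, so both training and evaluation
#' exclude them.
#'
#' @param corpus Corpus data.frame from [generate_corpus()].
#' @param kb A `milink_kb` (needed for the exact-match filter).
#' @param tokenizer Shared tokenizer.
#' @param exclude_exact Drop exact-name mentions (default `TRUE`).
#' @return A data.frame with list-column `tokens` plus `start`, `end`,
#'   `gold`.
#' @export
labeled_from_corpus <- function(corpus, kb,
                                tokenizer = milink_tokenizer("whitespace"),
                                exclude_exact = TRUE) {
  tokenizer <- as_tokenizer(tokenizer)
  toks <- lapply(corpus$text, tokenizer$tokenize)
  surface <- vapply(seq_len(nrow(corpus)), function(i) {
    detokenize(toks[[i]][corpus$start[[i]]:corpus$end[[i]]], tokenizer)
  }, "")
  keep <- if (exclude_exact) !(surface %in% kb$entities$name)
          else rep(TRUE, nrow(corpus))
  out <- data.frame(start = corpus$start[keep], end = corpus$end[keep],
                    gold = corpus$gold[keep], stringsAsFactors = FALSE)
  out$tokens <- toks[keep]
  out
}

#' Write a corpus as JSONL
#'
#' One record per sentence: `sentence_id`, `text`, and for labeled corpora
#' `gold`, `mention_start`, `mention_end` (0-based half-open token
#' indices).
#'
#' @param corpus Corpus data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(corpus))) {
    rec <- list(sentence_id = corpus$sentence_id[[i]],
                text = corpus$text[[i]])
    if (!is.null(corpus$gold)) {
      rec$gold <- corpus$gold[[i]]
      rec$mention_start <- corpus$start[[i]] - 1L
      rec$mention_end <- corpus$end[[i]]
    }
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Read a corpus from JSONL
#'
#' Accepts the format of [write_corpus_jsonl()]; `gold` and span fields are
#' optional.
#'
#' @param path JSONL file path.
#' @return A corpus data.frame (spans converted to 1-based inclusive).
#' @export
read_corpus_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  recs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  out <- data.frame(
    sentence_id = vapply(recs, function(r) as.character(r$sentence_id), ""),
    text = vapply(recs, `[[`, "", "text"), stringsAsFactors = FALSE)
  if (!is.null(recs[[1L]]$gold)) {
    out$gold <- vapply(recs, `[[`, "", "gold")
    out$start <- vapply(recs, function(r) r$mention_start + 1L, integer(1))
    out$end <- vapply(recs, function(r) as.integer(r$mention_end), integer(1))
  }
  out
}

#' Write all synthetic artifacts to a directory
#'
#' Emits `kb.tsv`, `embeddings.vec` (word2vec text), `dict.tsv`,
#' `corpus.jsonl` and `manifest.json` (the config and seed).
#'
#' @param bench Output of [generate_benchmark()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(bench, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_kb(bench$kb, file.path(dir, "kb.tsv"))
  write_word2vec(bench$table, file.path(dir, "embeddings.vec"))
  write_dictionary(bench$dict, file.path(dir, "dict.tsv"))
  write_corpus_jsonl(bench$corpus, file.path(dir, "corpus.jsonl"))
  writeLines(jsonlite::toJSON(unclass(bench$config), auto_unbox = TRUE),
             file.path(dir, "manifest.json"))
  invisible(dir)
}
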