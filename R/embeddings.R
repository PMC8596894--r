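#' Construct an embedding table
#'
#' @param vectors Numeric matrix, one row per token; rownames are the
#'   vocabulary.
#' @param oov_policy How out-of-vocabulary tokens enter an average:
#'   `"zero_vector"` (contribute a zero vector; the denominator counts all
#'   tokens) or `"skip_token"` (dropped; the denominator counts kept tokens).
#' @return A `milink_embeddings` object: list with `dim`, `vectors`,
#'   `oov_policy`.
#' @export
embedding_table <- function(vectors, oov_policy = c("zero_vector", "skip_token")) {
  oov_policy <- match.arg(oov_policy)
  stopifnot(is.matrix(vectors), is.numeric(vectors),
            !is.null(rownames(vectors)))
  if (anyDuplicated(rownames(vectors))) {
    stop("duplicate tokens in embedding table", call. = FALSE)
  }
  structure(list(dim = ncol(vectors), vectors = vectors,
                 oov_policy = oov_policy),
            class = "milink_embeddings")
}

#' Read embeddings in word2vec text format
#'
#' The format is a UTF-8 header line `vocab_size dim` followed by one line
#' per token: `token v1 ... vdim`, space-separated.
#'
#' @param path File path.
#' @inheritParams embedding_table
#' @return A `milink_embeddings`.
#' @export
read_word2vec <- function(path, oov_policy = c("zero_vector", "skip_token")) {
  oov_policy <- match.arg(oov_policy)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) == 0L) stop("empty embedding file", call. = FALSE)
  hdr <- as.integer(strsplit(trimws(lines[[1L]]), "\\s+")[[1L]])
  if (length(hdr) != 2L || anyNA(hdr)) {
    stop("missing `vocab_size dim` header in ", sQuote(path), call. = FALSE)
  }
  body <- lines[-1L][nzchar(lines[-1L])]
  if (length(body) != hdr[[1L]]) {
    stop(sprintf("header promises %d vectors, file has %d",
                 hdr[[1L]], length(body)), call. = FALSE)
  }
  parts <- strsplit(body, " ", fixed = TRUE)
  tokens <- vapply(parts, `[[`, "", 1L)
  vecs <- t(vapply(parts, function(p) as.numeric(p[-1L]),
                   numeric(hdr[[2L]])))
  rownames(vecs) <- tokens
  embedding_table(vecs, oov_policy)
}

#' Write embeddings in word2vec text format
#'
#' @param table A `milink_embeddings`.
#' @param path Output file path.
#' @param digits Significant digits written per coordinate.
#' @return `path`, invisibly.
#' @export
write_word2vec <- function(table, path, digits = 8L) {
  stopifnot(inherits(table, "milink_embeddings"))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(nrow(table$vectors), table$dim), con)
  fmt <- paste0("%.", digits, "g")
  writeLines(vapply(seq_len(nrow(table$vectors)), function(i) {
    paste(c(rownames(table$vectors)[[i]],
            sprintf(fmt, table$vectors[i, ])), collapse = " ")
  }, ""), con)
  invisible(path)
}

#' Average embedding of a token sequence
#'
#' The representation of a mention or an entity name is the arithmetic mean
#' of its tokens' vectors, after applying the table's OOV policy. If the
#' policy leaves no contributing token, the zero vector is returned with
#' attribute `all_oov = TRUE`.
#'
#' @param table A `milink_embeddings`.
#' @param tokens Non-empty character vector.
#' @return Numeric vector of length `table$dim` (attribute `all_oov` flags a
#'   fully out-of-vocabulary input).
#' @export
average_embed <- function(table, tokens) {
  stopifnot(inherits(table, "milink_embeddings"))
  if (length(tokens) == 0L) {
    stop("cannot embed an empty token sequence", call. = FALSE)
  }
  idx <- match(tokens, rownames(table$vectors))
  known <- !is.na(idx)
  if (!any(known)) {
    return(structure(numeric(table$dim), all_oov = TRUE))
  }
  total <- colSums(table$vectors[idx[known], , drop = FALSE])
  denom <- if (table$oov_policy == "zero_vector") length(tokens)
           else sum(known)
  structure(total / denom, all_oov = FALSE)
}

#' Cosine similarity
#'
#' Standard cosine; defined as 0 when either vector has zero norm, so that
#' fully out-of-vocabulary mentions rank last instead of erroring.
#'
#' @param u,v Numeric vectors of equal length.
#' @return A number in `[-1, 1]`.
#' @export
cosine_sim <- function(u, v) {
  if (length(u) != length(v)) {
    stop("cosine_sim: dimension mismatch (", length(u), " vs ", length(v),
         ")", call. = FALSE)
  }
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(0)
  s <- sum(u * v) / (nu * nv)
  max(-1, min(1, s))
}

#' @export
print.milink_embeddings <- function(x, ...) {
  cat(sprintf("<milink_embeddings: %d tokens x %d dims, oov=%s>\n",
              nrow(x$vectors), x$dim, x$oov_policy))
  invisible(x)
}
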