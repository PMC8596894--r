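#' Load a term dictionary
#'
#' One surface form per line, optionally followed by `<TAB>code` mapping the
#' term to its canonical KB entity. Empty lines are skipped with a warning;
#' duplicate terms are deduplicated (a later canonical mapping wins).
#'
#' @param path File path (UTF-8).
#' @return A `milink_dictionary`: list with `terms` (character vector) and
#'   `canonical` (named character vector, term -> code; possibly empty).
#' @export
load_dictionary <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  empty <- !nzchar(trimws(lines))
  if (any(empty)) warning(sum(empty), " empty dictionary line(s) skipped")
  lines <- lines[!empty]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  terms <- vapply(fields, `[[`, "", 1L)
  codes <- vapply(fields, function(f) if (length(f) >= 2L) f[[2L]] else NA_character_, "")
  mapped <- !is.na(codes)
  if (any(mapped)) parse_code(codes[mapped])  # errors on malformed codes
  canonical <- setNames(codes[mapped], terms[mapped])
  canonical <- canonical[!duplicated(names(canonical), fromLast = TRUE)]
  term_dictionary(unique(terms), canonical)
}

#' Construct a term dictionary in memory
#'
#' @param terms Character vector of surface forms (no empty strings).
#' @param canonical Optional named character vector mapping a term to its
#'   canonical entity code.
#' @return A `milink_dictionary`.
#' @export
term_dictionary <- function(terms, canonical = character(0)) {
  stopifnot(is.character(terms))
  if (any(!nzchar(terms))) stop("dictionary contains an empty term", call. = FALSE)
  if (length(terms) == 0L) warning("dictionary is empty")
  structure(list(terms = unique(terms), canonical = canonical),
            class = "milink_dictionary")
}

#' @export
print.milink_dictionary <- function(x, ...) {
  cat(sprintf("<milink_dictionary: %d terms, %d canonical mappings>\n",
              length(x$terms), length(x$canonical)))
  invisible(x)
}

#' Write a term dictionary to TSV
#'
#' @param dict A `milink_dictionary`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dictionary <- function(dict, path) {
  stopifnot(inherits(dict, "milink_dictionary"))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  codes <- dict$canonical[dict$terms]
  out <- ifelse(is.na(codes), dict$terms,
                paste(dict$terms, codes, sep = "\t"))
  writeLines(out, con)
  invisible(path)
}

# Tokenized dictionary keyed for O(1) span lookup.
compile_dictionary <- function(dict, tokenizer) {
  tokenizer <- as_tokenizer(tokenizer)
  toks <- lapply(dict$terms, tokenizer$tokenize)
  keep <- lengths(toks) > 0L
  keys <- vapply(toks[keep], paste, "", collapse = "\x1f")
  env <- new.env(parent = emptyenv(), size = length(keys))
  for (k in keys) assign(k, TRUE, envir = env)
  list(keys = env, max_len = if (any(keep)) max(lengths(toks[keep])) else 0L)
}

#' Detect dictionary mentions in a token sequence
#'
#' Greedy left-to-right longest-match scan: at each position the longest
#' dictionary term starting there wins, the scan resumes after it, so the
#' returned spans are non-overlapping and sorted by start. Detection is
#' independent of dictionary order. Every occurrence of a term is emitted.
#'
#' @param tokens Character vector (the tokenized sentence).
#' @param dict A `milink_dictionary`.
#' @param tokenizer Tokenizer shared with the dictionary terms.
#' @return A data.frame with 1-based inclusive `start`, `end` token indices
#'   and the `surface` string of each mention. Zero rows when nothing
#'   matches. (The on-disk MIL dataset uses 0-based half-open indices; see
#'   [write_mil_dataset()].)
#' @examples
#' tk <- milink_tokenizer("character")
#' d <- term_dictionary(c("恶心", "头疼"))
#' detect_mentions(tk$tokenize("严重恶心头疼"), d, tk)
#' @export
detect_mentions <- function(tokens, dict,
                            tokenizer = milink_tokenizer("character")) {
  stopifnot(inherits(dict, "milink_dictionary"))
  tokenizer <- as_tokenizer(tokenizer)
  compiled <- compile_dictionary(dict, tokenizer)
  L <- length(tokens)
  starts <- integer(0); ends <- integer(0); surfaces <- character(0)
  i <- 1L
  while (i <= L && compiled$max_len > 0L) {
    matched <- 0L
    for (len in seq(min(compiled$max_len, L - i + 1L), 1L)) {
      key <- paste(tokens[i:(i + len - 1L)], collapse = "\x1f")
      if (exists(key, envir = compiled$keys, inherits = FALSE)) {
        matched <- len
        break
      }
    }
    if (matched > 0L) {
      starts <- c(starts, i)
      ends <- c(ends, i + matched - 1L)
      surfaces <- c(surfaces,
                    detokenize(tokens[i:(i + matched - 1L)], tokenizer))
      i <- i + matched
    } else {
      i <- i + 1L
    }
  }
  data.frame(start = starts, end = ends, surface = surfaces,
             stringsAsFactors = FALSE)
}
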