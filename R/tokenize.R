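#' Tokenizers
#'
#' All modules share one tokenizer contract: a function mapping a string to a
#' character vector of tokens, plus the joiner used to reconstruct a surface
#' string from tokens. The default is character-level, which is robust for
#' Chinese text without a word segmenter; `"whitespace"` suits pre-segmented
#' or synthetic corpora whose tokens are space-separated.
#'
#' @param name `"character"` or `"whitespace"`.
#' @return An object of class `milink_tokenizer`: a list with elements
#'   `name`, `tokenize` (function `character(1) -> character()`), and
#'   `collapse` (the string used to join tokens back into a surface form).
#' @examples
#' tk <- milink_tokenizer("whitespace")
#' tk$tokenize("severe nausea headache")
#' @export
milink_tokenizer <- function(name = c("character", "whitespace")) {
  name <- match.arg(name)
  tok <- switch(name,
    character = function(x) {
      stopifnot(is.character(x), length(x) == 1L)
      if (!nzchar(x)) return(character(0))
      strsplit(x, "", fixed = TRUE)[[1L]]
    },
    whitespace = function(x) {
      stopifnot(is.character(x), length(x) == 1L)
      out <- strsplit(trimws(x), "\\s+")[[1L]]
      out[nzchar(out)]
    }
  )
  structure(
    list(name = name, tokenize = tok,
         collapse = if (name == "character") "" else " "),
    class = "milink_tokenizer"
  )
}

#' @export
print.milink_tokenizer <- function(x, ...) {
  cat("<milink_tokenizer:", x$name, ">\n")
  invisible(x)
}

detokenize <- function(tokens, tokenizer) {
  paste(tokens, collapse = tokenizer$collapse)
}

as_tokenizer <- function(x) {
  if (inherits(x, "milink_tokenizer")) return(x)
  milink_tokenizer(x)
}
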