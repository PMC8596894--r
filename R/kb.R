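#' Parse an ICD10-style code
#'
#' ICD10 codes consist of a 3-character *category* (a letter followed by two
#' alphanumerics, e.g. `"R50"`), optionally followed by a decimal point and
#' up to four alphanumeric sub-classification characters. Localized editions
#' append an extra classification character after the two-character
#' sub-classification (codes like `"R50.x002"`), hence the 4-character cap.
#' The placeholder character `"x"` (as in `"R11.x02"`) is treated literally;
#' it carries no wildcard semantics.
#'
#' @param code A character vector of raw codes.
#' @return A data.frame with columns `raw`, `category` (3 characters) and
#'   `subclassification` (possibly `""`).
#' @examples
#' parse_code(c("R50.800", "K52.916", "R11.x02", "A00"))
#' @export
parse_code <- function(code) {
  stopifnot(is.character(code))
  ok <- grepl("^[A-Za-z][A-Za-z0-9]{2}(\\.[A-Za-z0-9]{1,4})?$", code)
  if (!all(ok)) {
    bad <- unique(code[!ok])
    stop("malformed ICD10-style code(s): ",
         paste(sQuote(bad), collapse = ", "), call. = FALSE)
  }
  category <- substr(code, 1L, 3L)
  sub <- ifelse(nchar(code) > 3L, substr(code, 5L, nchar(code)), "")
  data.frame(raw = code, category = category, subclassification = sub,
             stringsAsFactors = FALSE)
}

#' Cluster key of an ICD10-style code
#'
#' Entities sharing the category and the *first sub-classification* (the
#' leading characters after the decimal point; two by default, e.g. the `80`
#' of `R50.800`) form one cluster. Codes whose sub-classification is shorter
#' than `subclass_chars` — including codes with no decimal part at all —
#' key to their raw code, i.e. they form singleton-style clusters.
#'
#' @param code A character vector of raw codes, or the data.frame returned
#'   by [parse_code()].
#' @param subclass_chars Number of sub-classification characters that define
#'   the cluster (default 2). Setting this at or above the full
#'   sub-classification length makes every entity its own cluster.
#' @return Character vector of cluster keys.
#' @examples
#' cluster_key(c("R50.800", "R50.801", "A00"))
#' @export
cluster_key <- function(code, subclass_chars = 2L) {
  stopifnot(subclass_chars >= 1L)
  parts <- if (is.data.frame(code)) code else parse_code(code)
  ifelse(nchar(parts$subclassification) >= subclass_chars,
         paste0(parts$category, ".",
                substr(parts$subclassification, 1L, subclass_chars)),
         parts$raw)
}

new_kb <- function(entities, subclass_chars = 2L) {
  entities$cluster <- cluster_key(
    entities[c("raw", "category", "subclassification")],
    subclass_chars = subclass_chars)
  structure(
    list(entities = entities,
         cluster_index = split(entities$raw, entities$cluster),
         subclass_chars = as.integer(subclass_chars)),
    class = "milink_kb")
}

#' Build a knowledge base from codes and names
#'
#' @param codes Character vector of unique ICD10-style codes.
#' @param names Character vector of entity name strings (non-empty), parallel
#'   to `codes`.
#' @param subclass_chars Cluster-key granularity, see [cluster_key()].
#' @return A `milink_kb`: a list with `entities` (data.frame of `raw`,
#'   `category`, `subclassification`, `name`, `cluster`, in input order) and
#'   `cluster_index` (named list mapping cluster key to member codes).
#' @examples
#' kb <- knowledge_base(c("R50.800", "R50.801", "K52.916"),
#'                      c("fever other", "fever specified", "diarrhea"))
#' kb$cluster_index
#' @export
knowledge_base <- function(codes, names, subclass_chars = 2L) {
  stopifnot(is.character(codes), is.character(names),
            length(codes) == length(names))
  dup <- unique(codes[duplicated(codes)])
  if (length(dup) > 0L) {
    stop("duplicate code(s) in knowledge base: ",
         paste(sQuote(dup), collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(trimws(names)))) {
    stop("empty entity name at position(s): ",
         paste(which(!nzchar(trimws(names))), collapse = ", "),
         call. = FALSE)
  }
  parts <- parse_code(codes)
  parts$name <- names
  if (nrow(parts) == 0L) warning("knowledge base is empty")
  new_kb(parts, subclass_chars)
}

#' Load a knowledge base from a TSV file
#'
#' Expects UTF-8 TSV with two columns, `code<TAB>name`. Lines starting with
#' `#` are comments; a first line literally equal to `code<TAB>name` is
#' treated as a header.
#'
#' @param path File path.
#' @param subclass_chars Cluster-key granularity, see [cluster_key()].
#' @return A `milink_kb`; entity order follows file order.
#' @seealso [write_kb()] for the round-trip writer.
#' @export
load_kb <- function(path, subclass_chars = 2L) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) > 0L && identical(lines[[1L]], "code\tname")) {
    lines <- lines[-1L]
    lineno <- lineno[-1L]
  }
  if (length(lines) == 0L) {
    warning("knowledge base file ", sQuote(path), " has no records")
    return(suppressWarnings(
      knowledge_base(character(0), character(0), subclass_chars)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  short <- which(nf < 2L)
  if (length(short) > 0L) {
    i <- short[[1L]]
    if (grepl("\t", lines[[i]], fixed = TRUE)) {
      stop("line ", lineno[[i]], ": empty entity name", call. = FALSE)
    }
    stop("line ", lineno[[i]], ": expected `code<TAB>name`", call. = FALSE)
  }
  codes <- vapply(fields, `[[`, "", 1L)
  nms <- vapply(fields, function(f) paste(f[-1L], collapse = "\t"), "")
  bad <- which(!nzchar(trimws(nms)))
  if (length(bad) > 0L) {
    stop("line ", lineno[bad[1L]], ": empty entity name", call. = FALSE)
  }
  ok <- grepl("^[A-Za-z][A-Za-z0-9]{2}(\\.[A-Za-z0-9]{1,4})?$", codes)
  if (!all(ok)) {
    stop("line ", lineno[which(!ok)[1L]], ": unparsable code ",
         sQuote(codes[which(!ok)[1L]]), call. = FALSE)
  }
  knowledge_base(codes, nms, subclass_chars)
}

#' Write a knowledge base to TSV
#'
#' Round-trip counterpart of [load_kb()].
#' @param kb A `milink_kb`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_kb <- function(kb, path) {
  stopifnot(inherits(kb, "milink_kb"))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("code\tname", con)
  if (nrow(kb$entities) > 0L) {
    writeLines(paste(kb$entities$raw, kb$entities$name, sep = "\t"), con)
  }
  invisible(path)
}

#' Entities in a cluster
#'
#' @param kb A `milink_kb`.
#' @param key Cluster key (unknown keys are allowed).
#' @return Character vector of member codes (empty if the key is absent).
#' @export
cluster_members <- function(kb, key) {
  stopifnot(inherits(kb, "milink_kb"), is.character(key), length(key) == 1L)
  members <- kb$cluster_index[[key]]
  if (is.null(members)) character(0) else members
}

kb_size <- function(kb) nrow(kb$entities)

#' @export
print.milink_kb <- function(x, ...) {
  cat(sprintf("<milink_kb: %d entities in %d clusters (subclass_chars=%d)>\n",
              nrow(x$entities), length(x$cluster_index), x$subclass_chars))
  invisible(x)
}
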