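#' Read a character-level tagged corpus in two-column CoNLL style
#'
#' The dialect is UTF-8, one character per line, TAB-separated columns, LF
#' line endings, with a blank line terminating each sentence. Column 1 is the
#' character, column 2 the gold BIO tag; an optional column 3 holds predicted
#' tags (as written by [write_conll()] for tagged output).
#'
#' @param path Path to the file.
#' @param column Which tag column to build the corpus from: `"tag"` (column
#'   2, the default) or `"pred"` (column 3, which must then be present).
#' @return A [ner_corpus()]. Segmentation labels are derived from the tags;
#'   the label inventory is collected from the tags seen.
#' @seealso [write_conll()]
#' @export
read_conll <- function(path, column = c("tag", "pred")) {
  column <- match.arg(column)
  if (!file.exists(path)) stop(sprintf("read_conll: no such file: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  sentences <- list()
  chars <- character(0)
  tags <- character(0)
  flush <- function() {
    if (length(chars)) {
      sentences[[length(sentences) + 1L]] <<- tagged_sentence(chars, tags)
    }
    chars <<- character(0); tags <<- character(0)
  }
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (line == "") { flush(); next }
    fields <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 2L || length(fields) > 3L)
      stop(sprintf("read_conll: line %d has %d columns (expected 2 or 3): '%s'",
                   ln, length(fields), line))
    tag <- if (column == "pred") {
      if (length(fields) < 3L)
        stop(sprintf("read_conll: line %d has no prediction column", ln))
      fields[3L]
    } else fields[2L]
    if (!grepl(bio_grammar, tag))
      stop(sprintf("read_conll: line %d: tag '%s' does not match the BIO grammar",
                   ln, tag))
    chars <- c(chars, fields[1L])
    tags <- c(tags, tag)
  }
  flush()
  ner_corpus(sentences)
}

#' Write a corpus in the two-column CoNLL-style dialect
#'
#' Inverse of [read_conll()]: each sentence becomes one line per character
#' (`<char>TAB<tag>`), followed by a blank line. When `predictions` is given,
#' a third TAB-separated column with the predicted tags is appended.
#'
#' @param corpus A [ner_corpus()].
#' @param path Output file path.
#' @param predictions Optional list of per-sentence predicted tag vectors,
#'   aligned with `corpus$sentences`.
#' @return Invisibly, `path`.
#' @export
write_conll <- function(corpus, path, predictions = NULL) {
  stopifnot(inherits(corpus, "ner_corpus"))
  if (!is.null(predictions) && length(predictions) != length(corpus$sentences))
    stop("write_conll: predictions must align with corpus sentences")
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (k in seq_along(corpus$sentences)) {
    s <- corpus$sentences[[k]]
    lines <- if (is.null(predictions)) {
      paste(s$chars, s$tags, sep = "\t")
    } else {
      if (length(predictions[[k]]) != length(s$chars))
        stop(sprintf("write_conll: prediction length mismatch in sentence %d", k))
      paste(s$chars, s$tags, predictions[[k]], sep = "\t")
    }
    writeLines(enc2utf8(c(lines, "")), con, sep = "\n", useBytes = TRUE)
  }
  invisible(path)
}

#' Split running text into sentences at the Chinese full stop
#'
#' Splits after every occurrence of the Chinese full stop (U+3002), keeping
#' the delimiter at the end of its segment; a trailing remnant without a full
#' stop is kept when non-empty. The concatenation of the output always equals
#' the input.
#'
#' @param text A single character string.
#' @return Character vector of sentence strings (possibly empty).
#' @examples
#' split_sentences("甲。乙。")
#' @export
split_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (nchar(text) == 0L) return(character(0))
  chars <- strsplit(text, "", fixed = FALSE)[[1L]]
  stops <- which(chars == "。")
  bounds <- unique(c(stops, length(chars)))
  starts <- c(1L, head(bounds, -1L) + 1L)
  keep <- starts <= bounds
  vapply(which(keep), function(i)
    paste(chars[starts[i]:bounds[i]], collapse = ""), character(1))
}
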