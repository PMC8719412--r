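#' @keywords internal
"_PACKAGE"

# Reserved padding character (Unicode private-use area, below the range the
# synthetic generator draws from).
PAD_CHAR <- "\uE000"

bio_grammar <- "^(O|[BI]-.+)$"

#' Construct a character-level tagged sentence
#'
#' A `tagged_sentence` holds one sentence as aligned sequences: its characters,
#' their BIO labels, the derived binary segmentation labels (1 for any
#' character inside an entity, 0 outside) and an attention mask separating real
#' characters from padding.
#'
#' @param chars Character vector of single characters (one Unicode code point
#'   per element).
#' @param tags Character vector of BIO labels, same length as `chars`. Each
#'   label is `"O"`, `"B-<type>"` or `"I-<type>"`.
#' @param seg_labels Optional integer vector of 0/1 segmentation labels. When
#'   `NULL` (the default) it is derived from `tags` via
#'   [bio_to_segmentation()].
#' @param attention_mask Optional integer vector of 0/1 flags, 1 marking real
#'   characters and 0 padding. Defaults to all 1.
#' @return An object of class `tagged_sentence`.
#' @seealso [ner_corpus()], [pad_truncate()]
#' @examples
#' tagged_sentence(c("a", "b", "c"), c("B-Drug", "I-Drug", "O"))
#' @export
tagged_sentence <- function(chars, tags, seg_labels = NULL,
                            attention_mask = NULL) {
  chars <- as.character(chars)
  tags <- as.character(tags)
  n <- length(chars)
  if (n == 0L) stop("tagged_sentence: zero-length sentences are not allowed")
  if (length(tags) != n)
    stop("tagged_sentence: chars and tags must have equal length")
  bad <- which(!grepl(bio_grammar, tags))
  if (length(bad))
    stop(sprintf("tagged_sentence: tag %d ('%s') does not match the BIO grammar",
                 bad[1L], tags[bad[1L]]))
  if (is.null(seg_labels)) seg_labels <- bio_to_segmentation(tags)
  seg_labels <- as.integer(seg_labels)
  if (length(seg_labels) != n || !all(seg_labels %in% c(0L, 1L)))
    stop("tagged_sentence: seg_labels must be 0/1 of the same length as chars")
  if (is.null(attention_mask)) attention_mask <- rep(1L, n)
  attention_mask <- as.integer(attention_mask)
  if (length(attention_mask) != n || !all(attention_mask %in% c(0L, 1L)))
    stop("tagged_sentence: attention_mask must be 0/1 of the same length as chars")
  if (!identical(seg_labels, bio_to_segmentation(tags)))
    stop("tagged_sentence: seg_labels inconsistent with tags (must be 1 iff tag != 'O')")
  structure(list(chars = chars, tags = tags, seg_labels = seg_labels,
                 attention_mask = attention_mask),
            class = "tagged_sentence")
}

#' @export
print.tagged_sentence <- function(x, ...) {
  cat(sprintf("<tagged_sentence> %d characters (%d real)\n",
              length(x$chars), sum(x$attention_mask)))
  cat("  ", paste(x$chars, collapse = ""), "\n", sep = "")
  cat("  ", paste(x$tags, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
length.tagged_sentence <- function(x) length(x$chars)

#' Construct a typed entity mention
#'
#' A contiguous entity span within a sentence. Spans use the 0-based,
#' half-open convention: `start` is the index of the first character of the
#' mention, `end` is one past the last, so `end - start` is the mention
#' length. All span reporting in this package uses this convention.
#'
#' @param etype Entity-type name.
#' @param start 0-based inclusive start index.
#' @param end Exclusive end index (`end > start`).
#' @param surface The mention's surface string; when sentence characters are
#'   supplied to higher-level functions this equals
#'   `paste(chars[(start + 1):end], collapse = "")`.
#' @return An object of class `entity_mention`.
#' @examples
#' entity_mention("Symptom", 0, 2, "ab")
#' @export
entity_mention <- function(etype, start, end, surface = NA_character_) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || end <= start)
    stop("entity_mention: need 0 <= start < end")
  if (!is.na(surface) && nchar(surface) != end - start)
    stop("entity_mention: surface length must equal end - start")
  structure(list(etype = as.character(etype), start = start, end = end,
                 surface = as.character(surface)),
            class = "entity_mention")
}

#' @export
print.entity_mention <- function(x, ...) {
  cat(sprintf("<entity_mention> %s [%d, %d) '%s'\n",
              x$etype, x$start, x$end, x$surface))
  invisible(x)
}

#' Construct a corpus of tagged sentences
#'
#' @param sentences List of [tagged_sentence()] objects.
#' @param label_inventory Optional character vector of entity-type names. When
#'   `NULL`, collected from the tags present in `sentences` (sorted).
#' @return An object of class `ner_corpus` with fields `sentences` and
#'   `label_inventory`.
#' @examples
#' s <- tagged_sentence(c("a", "b"), c("B-Drug", "I-Drug"))
#' ner_corpus(list(s))
#' @export
ner_corpus <- function(sentences, label_inventory = NULL) {
  if (!is.list(sentences) ||
      !all(vapply(sentences, inherits, logical(1), "tagged_sentence")))
    stop("ner_corpus: sentences must be a list of tagged_sentence objects")
  used <- corpus_types(sentences)
  if (is.null(label_inventory)) {
    label_inventory <- used
  } else {
    label_inventory <- as.character(label_inventory)
    missing_types <- setdiff(used, label_inventory)
    if (length(missing_types))
      stop(sprintf("ner_corpus: tags use types absent from label_inventory: %s",
                   paste(missing_types, collapse = ", ")))
  }
  structure(list(sentences = sentences, label_inventory = label_inventory),
            class = "ner_corpus")
}

corpus_types <- function(sentences) {
  tags <- unlist(lapply(sentences, `[[`, "tags"), use.names = FALSE)
  tags <- tags[tags != "O"]
  sort(unique(sub("^[BI]-", "", tags)))
}

#' @export
print.ner_corpus <- function(x, ...) {
  n_tok <- sum(vapply(x$sentences, function(s) sum(s$attention_mask), integer(1)))
  n_ent <- sum(vapply(x$sentences,
                      function(s) length(bio_to_entities(s$tags)), integer(1)))
  cat(sprintf("<ner_corpus> %d sentences, %d characters, %d entity mentions\n",
              length(x$sentences), n_tok, n_ent))
  cat("  types: ", paste(x$label_inventory, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
length.ner_corpus <- function(x) length(x$sentences)

#' Extract gold entity mentions from every sentence of a corpus
#'
#' @param corpus A [ner_corpus()].
#' @return A list (one element per sentence) of lists of [entity_mention()]s.
#' @export
corpus_mentions <- function(corpus) {
  lapply(corpus$sentences, function(s) {
    real <- s$attention_mask == 1L
    bio_to_entities(s$tags[real], chars = s$chars[real])
  })
}
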