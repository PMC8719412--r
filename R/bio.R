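#' Convert entity mentions to a BIO label sequence
#'
#' The first character of each mention receives `B-<type>`, subsequent
#' characters `I-<type>`, and all remaining positions `O`.
#'
#' @param length Sentence length (number of characters).
#' @param mentions List of [entity_mention()] objects with non-overlapping
#'   0-based half-open spans inside `[0, length)`.
#' @return Character vector of `length` BIO labels.
#' @examples
#' entities_to_bio(5, list(entity_mention("Sym", 0, 2)))
#' @export
entities_to_bio <- function(length, mentions) {
  length <- as.integer(length)
  if (length < 1L) stop("entities_to_bio: length must be positive")
  tags <- rep("O", length)
  if (!base::length(mentions)) return(tags)
  covered <- rep(FALSE, length)
  ord <- order(vapply(mentions, `[[`, integer(1), "start"))
  for (m in mentions[ord]) {
    if (m$end > length)
      stop(sprintf("entities_to_bio: mention [%d, %d) exceeds sentence length %d",
                   m$start, m$end, length))
    idx <- (m$start + 1L):m$end
    if (any(covered[idx]))
      stop(sprintf("entities_to_bio: mention [%d, %d) overlaps another mention",
                   m$start, m$end))
    covered[idx] <- TRUE
    tags[idx[1L]] <- paste0("B-", m$etype)
    if (base::length(idx) > 1L) tags[idx[-1L]] <- paste0("I-", m$etype)
  }
  tags
}

#' Extract entity mentions from a BIO label sequence
#'
#' Maximal `B-I...` runs of one type become mentions. A stray `I-<type>` not
#' preceded by a `B-`/`I-` label of the same type is repaired as an implicit
#' `B` (the conlleval convention), so the function is total over anything an
#' unconstrained CRF head can emit.
#'
#' @param tags Character vector of BIO labels.
#' @param chars Optional character vector of the sentence's characters, used
#'   to fill each mention's surface string.
#' @return List of [entity_mention()]s sorted by start position (0-based,
#'   half-open spans).
#' @examples
#' bio_to_entities(c("B-Sym", "I-Sym", "O"))
#' bio_to_entities(c("O", "I-Drug", "I-Drug")) # repaired to one Drug mention
#' @export
bio_to_entities <- function(tags, chars = NULL) {
  tags <- as.character(tags)
  bad <- which(!grepl(bio_grammar, tags))
  if (length(bad))
    stop(sprintf("bio_to_entities: unknown label '%s' at position %d",
                 tags[bad[1L]], bad[1L]))
  mentions <- list()
  cur_type <- NULL
  cur_start <- NA_integer_
  flush <- function(end_pos) {
    if (is.null(cur_type)) return()
    surface <- if (is.null(chars)) NA_character_ else
      paste(chars[(cur_start + 1L):end_pos], collapse = "")
    mentions[[length(mentions) + 1L]] <<-
      entity_mention(cur_type, cur_start, end_pos, surface)
  }
  for (i in seq_along(tags)) {
    tag <- tags[i]
    if (tag == "O") {
      flush(i - 1L); cur_type <- NULL
    } else {
      prefix <- substr(tag, 1L, 1L)
      etype <- substr(tag, 3L, nchar(tag))
      if (prefix == "B" || is.null(cur_type) || etype != cur_type) {
        flush(i - 1L)
        cur_type <- etype
        cur_start <- i - 1L
      }
    }
  }
  flush(length(tags))
  mentions
}

#' Derive binary segmentation labels from BIO labels
#'
#' The auxiliary segmentation task labels a character 1 when it is part of
#' any entity (tag `B-*` or `I-*`) and 0 otherwise.
#'
#' @param tags Character vector of BIO labels.
#' @return Integer vector of 0/1 labels, same length.
#' @examples
#' bio_to_segmentation(c("B-Sym", "I-Sym", "O"))
#' @export
bio_to_segmentation <- function(tags) {
  as.integer(tags != "O")
}

#' Pad or truncate a sentence to a fixed length
#'
#' Real positions keep attention mask 1; padding positions get the reserved
#' PAD character, tag `"O"` and mask 0. Sentences longer than `max_len` are
#' truncated (with a warning).
#'
#' @param sentence A [tagged_sentence()].
#' @param max_len Target length (positive integer; the reference training
#'   protocol uses 250).
#' @return A [tagged_sentence()] of length exactly `max_len`.
#' @examples
#' s <- tagged_sentence(c("a", "b", "c"), c("O", "O", "O"))
#' pad_truncate(s, 5)$attention_mask
#' @export
pad_truncate <- function(sentence, max_len) {
  stopifnot(inherits(sentence, "tagged_sentence"))
  max_len <- as.integer(max_len)
  if (max_len < 1L) stop("pad_truncate: max_len must be >= 1")
  n <- length(sentence$chars)
  if (n > max_len) {
    warning(sprintf("pad_truncate: truncating sentence of length %d to %d",
                    n, max_len))
    keep <- seq_len(max_len)
    return(tagged_sentence(sentence$chars[keep], sentence$tags[keep],
                           attention_mask = sentence$attention_mask[keep]))
  }
  if (n == max_len) return(sentence)
  pad <- max_len - n
  tagged_sentence(c(sentence$chars, rep(PAD_CHAR, pad)),
                  c(sentence$tags, rep("O", pad)),
                  attention_mask = c(sentence$attention_mask, rep(0L, pad)))
}
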