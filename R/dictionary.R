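# n-gram window half-widths: for each k in 2..6, a left fragment ending at i
# and a right fragment starting at i. Fixed slot order: 2L, 2R, 3L, 3R, ...,
# 6L, 6R (ten slots, 3 bits each -> 30-dimensional vector).
NGRAM_KS <- 2:6
N_SLOTS <- 10L
DICT_DIM <- 30L

#' Construct an entity dictionary (gazetteer)
#'
#' Maps entity surface strings to entity-type names. When one surface is
#' given several conflicting types, the type earliest in `type_order` wins
#' and a warning is emitted.
#'
#' @param surfaces Character vector of entity surface strings (non-empty).
#' @param types Character vector of entity-type names, same length.
#' @param type_order Ordered character vector of all admissible type names;
#'   earlier means higher priority in conflict resolution. Defaults to the
#'   unique types in `types`, in order of first appearance.
#' @return An object of class `entity_dictionary` with fields `entries`
#'   (named character vector, surface -> type) and `type_order`.
#' @seealso [load_dictionary()], [encode_position()]
#' @export
entity_dictionary <- function(surfaces = character(0),
                              types = character(0),
                              type_order = NULL) {
  surfaces <- as.character(surfaces); types <- as.character(types)
  if (length(surfaces) != length(types))
    stop("entity_dictionary: surfaces and types must have equal length")
  if (any(!nzchar(surfaces)))
    stop("entity_dictionary: empty surface strings are not allowed")
  if (is.null(type_order)) type_order <- unique(types)
  unknown <- setdiff(unique(types), type_order)
  if (length(unknown))
    stop(sprintf("entity_dictionary: unknown type name(s): %s",
                 paste(unknown, collapse = ", ")))
  entries <- character(0)
  if (length(surfaces)) {
    # resolve duplicates by type_order priority
    prio <- match(types, type_order)
    ord <- order(match(surfaces, unique(surfaces)), prio)
    surfaces <- surfaces[ord]; types <- types[ord]
    dup <- duplicated(surfaces)
    conflict <- surfaces[dup][types[dup] != types[match(surfaces[dup], surfaces)]]
    if (length(conflict))
      warning(sprintf(
        "entity_dictionary: %d surface(s) mapped to several types; kept the highest-priority type (e.g. '%s')",
        length(unique(conflict)), conflict[1L]))
    entries <- types[!dup]
    names(entries) <- surfaces[!dup]
  }
  structure(list(entries = entries, type_order = type_order),
            class = "entity_dictionary")
}

#' @export
print.entity_dictionary <- function(x, ...) {
  cat(sprintf("<entity_dictionary> %d entries, %d types (%s)\n",
              length(x$entries), length(x$type_order),
              paste(x$type_order, collapse = ", ")))
  invisible(x)
}

#' @export
length.entity_dictionary <- function(x) length(x$entries)

#' Load an entity dictionary from a TSV file
#'
#' Expects UTF-8 lines `<surface>TAB<type>`.
#'
#' @param path Path to the TSV file.
#' @param type_order Optional declared type inventory (ordered, highest
#'   priority first). A type in the file but not in `type_order` is an error.
#' @return An [entity_dictionary()].
#' @export
load_dictionary <- function(path, type_order = NULL) {
  if (!file.exists(path)) stop(sprintf("load_dictionary: no such file: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(entity_dictionary(type_order = type_order %||% character(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 2L))
    stop(sprintf("load_dictionary: line %d does not have 2 columns",
                 which(nf != 2L)[1L]))
  surfaces <- vapply(fields, `[[`, character(1), 1L)
  types <- vapply(fields, `[[`, character(1), 2L)
  entity_dictionary(surfaces, types, type_order = type_order)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a 3-bit entity-type code scheme
#'
#' Each entity type is assigned a distinct non-zero 3-bit code; the all-zero
#' code `(0, 0, 0)` is reserved for "no entity". At most 7 types fit in 3
#' bits. Two published per-dataset tables are available through
#' [builtin_scheme()].
#'
#' @param types Ordered character vector of entity-type names (at most 7).
#' @param codes Optional list of integer triplets (one per type). Defaults to
#'   the non-zero 3-bit codes in increasing binary order: `(0,0,1)`,
#'   `(0,1,0)`, `(0,1,1)`, `(1,0,0)`, `(1,0,1)`, `(1,1,0)`, `(1,1,1)`.
#' @return An object of class `type_code_scheme` with fields `codes` (named
#'   list of 3-bit integer vectors) and `none_code` (`c(0, 0, 0)`).
#' @export
type_code_scheme <- function(types, codes = NULL) {
  types <- as.character(types)
  if (anyDuplicated(types)) stop("type_code_scheme: duplicate type names")
  if (length(types) > 7L)
    stop("type_code_scheme: at most 7 types can carry distinct non-zero 3-bit codes")
  if (is.null(codes)) {
    codes <- lapply(seq_along(types), function(v)
      as.integer(c(v %/% 4 %% 2, v %/% 2 %% 2, v %% 2)))
  }
  if (length(codes) != length(types))
    stop("type_code_scheme: need one code per type")
  codes <- lapply(codes, as.integer)
  ok <- vapply(codes, function(cd)
    length(cd) == 3L && all(cd %in% c(0L, 1L)) && any(cd == 1L), logical(1))
  if (!all(ok))
    stop("type_code_scheme: every code must be a non-zero 3-bit 0/1 triplet")
  keys <- vapply(codes, paste, character(1), collapse = "")
  if (anyDuplicated(keys)) stop("type_code_scheme: codes must be distinct")
  names(codes) <- types
  structure(list(codes = codes, none_code = c(0L, 0L, 0L)),
            class = "type_code_scheme")
}

#' @export
print.type_code_scheme <- function(x, ...) {
  cat("<type_code_scheme>\n")
  for (t in names(x$codes))
    cat(sprintf("  %-20s (%s)\n", t, paste(x$codes[[t]], collapse = ", ")))
  invisible(x)
}

#' Published per-dataset 3-bit type-code tables
#'
#' The two benchmark code assignments: `"ccks2017"` codes disease (0,0,1),
#' anatomy (0,1,0), symptom (0,1,1), exam (1,0,0), treatment (1,0,1);
#' `"ccks2018"` (also used for the hospital discharge-record corpus) codes
#' drug (0,0,1), anatomy (0,1,0), independent symptom (0,1,1), describe
#' symptom (1,0,0), operation (1,0,1).
#'
#' @param name `"ccks2017"` or `"ccks2018"`.
#' @return A [type_code_scheme()].
#' @export
builtin_scheme <- function(name = c("ccks2017", "ccks2018")) {
  name <- match.arg(name)
  if (name == "ccks2017") {
    type_code_scheme(
      c("disease", "anatomy", "symptom", "exam", "treatment"),
      list(c(0, 0, 1), c(0, 1, 0), c(0, 1, 1), c(1, 0, 0), c(1, 0, 1)))
  } else {
    type_code_scheme(
      c("drug", "anatomy", "indep_symptom", "desc_symptom", "operation"),
      list(c(0, 0, 1), c(0, 1, 0), c(0, 1, 1), c(1, 0, 0), c(1, 0, 1)))
  }
}

#' Enumerate the ten n-gram fragments around one position
#'
#' For each n in 2..6 there is a left fragment (the n characters ending at
#' position `i`) and a right fragment (the n characters starting at `i`), in
#' fixed slot order 2L, 2R, 3L, 3R, ..., 6L, 6R. A fragment whose window
#' crosses a sentence boundary is absent (`NA`).
#'
#' @param chars Character vector (one character per element).
#' @param i Position, 1-based.
#' @return Character vector of length 10; absent fragments are `NA`.
#' @examples
#' fragments_at(strsplit("abcdefg", "")[[1]], 4)
#' @export
fragments_at <- function(chars, i) {
  n <- length(chars)
  i <- as.integer(i)
  if (is.na(i) || i < 1L || i > n)
    stop(sprintf("fragments_at: position %d out of range 1..%d", i, n))
  out <- rep(NA_character_, N_SLOTS)
  slot <- 1L
  for (k in NGRAM_KS) {
    if (i - k + 1L >= 1L)
      out[slot] <- paste(chars[(i - k + 1L):i], collapse = "")
    if (i + k - 1L <= n)
      out[slot + 1L] <- paste(chars[i:(i + k - 1L)], collapse = "")
    slot <- slot + 2L
  }
  out
}

#' Dictionary feature vector for one position
#'
#' Looks up each of the ten n-gram fragments of [fragments_at()] in the
#' dictionary (exact full-string match) and concatenates, in slot order, the
#' 3-bit code of the matched entity type — or `(0, 0, 0)` when the fragment
#' is absent or unmatched. The result is the 30-dimensional binary dictionary
#' feature of position `i`.
#'
#' @param chars Character vector of the sentence's characters.
#' @param i Position, 1-based.
#' @param dict An [entity_dictionary()].
#' @param scheme A [type_code_scheme()] covering the dictionary's types.
#' @return Integer vector of length 30 with entries in `{0, 1}`.
#' @export
encode_position <- function(chars, i, dict, scheme) {
  frags <- fragments_at(chars, i)
  out <- integer(DICT_DIM)
  if (!length(dict$entries)) return(out)
  hit <- match(frags, names(dict$entries))
  for (s in which(!is.na(hit))) {
    etype <- dict$entries[[hit[s]]]
    code <- scheme$codes[[etype]]
    if (is.null(code))
      stop(sprintf("encode_position: type '%s' has no code in the scheme", etype))
    out[(3L * (s - 1L) + 1L):(3L * s)] <- code
  }
  out
}

#' Dictionary feature matrix for a whole sentence
#'
#' Row `i` is [encode_position()] at position `i`.
#'
#' @inheritParams encode_position
#' @return Integer matrix of dimension `length(chars)` x 30.
#' @export
encode_sentence_dict <- function(chars, dict, scheme) {
  n <- length(chars)
  if (n == 0L) stop("encode_sentence_dict: empty sentence")
  out <- matrix(0L, nrow = n, ncol = DICT_DIM)
  if (!length(dict$entries)) return(out)
  # enumerate every in-bounds window once instead of per-position lookups
  keys <- names(dict$entries)
  for (k in NGRAM_KS) {
    if (k > n) break
    starts <- 1L:(n - k + 1L)
    wins <- vapply(starts, function(s)
      paste(chars[s:(s + k - 1L)], collapse = ""), character(1))
    hit <- match(wins, keys)
    for (w in which(!is.na(hit))) {
      code <- scheme$codes[[dict$entries[[hit[w]]]]]
      s <- starts[w]
      slot_l <- 2L * match(k, NGRAM_KS) - 1L     # left fragment of char s+k-1
      slot_r <- slot_l + 1L                      # right fragment of char s
      out[s + k - 1L, (3L * (slot_l - 1L) + 1L):(3L * slot_l)] <- code
      out[s, (3L * (slot_r - 1L) + 1L):(3L * slot_r)] <- code
    }
  }
  out
}
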