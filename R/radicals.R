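#' Construct a character-to-radical lookup table
#'
#' Chinese characters share sub-character structural components (radicals)
#' that often carry semantic information — anatomy terms, for instance, tend
#' to share the "meat" radical. The table maps characters to radical
#' identifiers in a contiguous 0-based index space; identifier 0 is reserved
#' for unknown/unmapped characters.
#'
#' @param chars Character vector of single characters.
#' @param radicals Character vector of radical names, same length.
#' @return An object of class `radical_table` with fields `mapping` (named
#'   integer vector char -> radical id), `radical_names` (id space, entry 1
#'   is the unknown radical) and `unk_radical` (always `0L`).
#' @seealso [radical_of()], [load_radicals()]
#' @export
radical_table <- function(chars = character(0), radicals = character(0)) {
  chars <- as.character(chars); radicals <- as.character(radicals)
  if (length(chars) != length(radicals))
    stop("radical_table: chars and radicals must have equal length")
  if (anyDuplicated(chars))
    stop("radical_table: duplicate character entries")
  radical_names <- c("<UNK_RADICAL>", sort(unique(radicals)))
  mapping <- match(radicals, radical_names) - 1L
  names(mapping) <- chars
  structure(list(mapping = mapping, radical_names = radical_names,
                 unk_radical = 0L),
            class = "radical_table")
}

#' @export
print.radical_table <- function(x, ...) {
  cat(sprintf("<radical_table> %d characters, %d radicals (+ unknown)\n",
              length(x$mapping), length(x$radical_names) - 1L))
  invisible(x)
}

#' Load a radical table from a TSV file
#'
#' Expects UTF-8 lines `<char>TAB<radical>` (e.g. derived from Unicode
#' Kangxi radical data).
#'
#' @param path Path to the TSV file.
#' @return A [radical_table()].
#' @export
load_radicals <- function(path) {
  if (!file.exists(path)) stop(sprintf("load_radicals: no such file: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(radical_table())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 2L))
    stop(sprintf("load_radicals: line %d does not have 2 columns",
                 which(nf != 2L)[1L]))
  radical_table(vapply(fields, `[[`, character(1), 1L),
                vapply(fields, `[[`, character(1), 2L))
}

#' Radical identifier of a character
#'
#' Total over all of Unicode: characters absent from the table map to the
#' reserved unknown radical (id 0).
#'
#' @param char A single character.
#' @param table A [radical_table()].
#' @return Integer radical identifier (0-based).
#' @export
radical_of <- function(char, table) {
  stopifnot(inherits(table, "radical_table"))
  id <- unname(table$mapping[char])
  if (length(id) != 1L || is.na(id)) table$unk_radical else id
}

# vectorized lookup used by the feature pipeline
radicals_of <- function(chars, table) {
  id <- unname(table$mapping[chars])
  id[is.na(id)] <- table$unk_radical
  id
}
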