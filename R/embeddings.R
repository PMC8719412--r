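# run `code` under a fixed RNG state, then restore the caller's state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Initialize an embedding matrix
#'
#' Entries are i.i.d. uniform on `[-sqrt(3/dim), +sqrt(3/dim)]`, which gives
#' each embedding dimension variance 1/dim. Reproducible given the seed.
#'
#' @param vocab_size Number of rows (vocabulary size).
#' @param dim Embedding width.
#' @param rng_seed Integer seed.
#' @return A `vocab_size` x `dim` numeric matrix.
#' @export
init_embedding <- function(vocab_size, dim, rng_seed) {
  stopifnot(vocab_size >= 1L, dim >= 1L)
  bound <- sqrt(3 / dim)
  with_seed(rng_seed,
            matrix(stats::runif(vocab_size * dim, -bound, bound),
                   nrow = vocab_size, ncol = dim))
}

#' Assemble the per-character network input matrix
#'
#' Each row is the concatenation, in order, of the character embedding, the
#' radical embedding and the 30-dimensional dictionary feature vector of one
#' position, giving width `char_dim + radical_dim + 30` (180 at the default
#' dimensions 100 and 50).
#'
#' @param char_ids Integer vector of 1-based character vocabulary indices.
#' @param radical_ids Integer vector of 0-based radical identifiers (as
#'   returned by [radical_of()]), same length.
#' @param dict_features Integer/numeric matrix `n` x 30 from
#'   [encode_sentence_dict()].
#' @param char_embeddings Character embedding matrix (vocab x char_dim).
#' @param radical_embeddings Radical embedding matrix (#radicals x
#'   radical_dim); row `id + 1` belongs to radical `id`.
#' @return Numeric matrix `n` x `(char_dim + radical_dim + 30)`.
#' @export
assemble_input <- function(char_ids, radical_ids, dict_features,
                           char_embeddings, radical_embeddings) {
  n <- length(char_ids)
  if (length(radical_ids) != n || nrow(dict_features) != n)
    stop("assemble_input: char_ids, radical_ids and dict_features must align")
  if (any(char_ids < 1L | char_ids > nrow(char_embeddings)))
    stop("assemble_input: character index out of vocabulary range")
  if (any(radical_ids < 0L | radical_ids >= nrow(radical_embeddings)))
    stop("assemble_input: radical identifier out of range")
  cbind(char_embeddings[char_ids, , drop = FALSE],
        radical_embeddings[radical_ids + 1L, , drop = FALSE],
        matrix(as.numeric(dict_features), nrow = n))
}
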