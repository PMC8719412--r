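# Shared fixtures and independent oracles used across the suite. Oracles are
# deliberately naive (enumeration / per-element loops) so they stay
# independent of the implementation paths they check.

synth_chars <- intToUtf8(0xE100 + 0:39, multiple = TRUE)

rand_chars <- function(n) {
  pool <- c(letters, synth_chars)
  pool[sample.int(length(pool), n, replace = TRUE)]
}

# random non-overlapping mention set over a sentence of length n
rand_mentions <- function(n, types = c("Sym", "Drug", "Ana"), max_m = 3L) {
  mentions <- list()
  free <- rep(TRUE, n)
  for (k in seq_len(sample.int(max_m + 1L, 1L) - 1L)) {
    len <- sample.int(min(4L, n), 1L)
    starts0 <- which(vapply(seq_len(n - len + 1L), function(s)
      all(free[s:(s + len - 1L)]), logical(1)))
    if (!length(starts0)) next
    s <- starts0[sample.int(length(starts0), 1L)]
    free[s:(s + len - 1L)] <- FALSE
    mentions[[length(mentions) + 1L]] <-
      entity_mention(types[sample.int(length(types), 1L)], s - 1L, s - 1L + len)
  }
  mentions
}

rand_corpus <- function(n_sentences, max_len = 12L) {
  sentences <- lapply(seq_len(n_sentences), function(i) {
    n <- sample(2:max_len, 1L)
    chars <- rand_chars(n)
    tags <- entities_to_bio(n, rand_mentions(n))
    tagged_sentence(chars, tags)
  })
  ner_corpus(sentences)
}

# position-wise window enumerator + lookup, independent of encode_position
brute_encode_position <- function(chars, i, dict, scheme) {
  n <- length(chars)
  out <- integer(30)
  slot <- 0L
  for (k in 2:6) {
    for (side in c("left", "right")) {
      slot <- slot + 1L
      idx <- if (side == "left") (i - k + 1L):i else i:(i + k - 1L)
      if (min(idx) < 1L || max(idx) > n) next
      frag <- paste(chars[idx], collapse = "")
      ty <- unname(dict$entries[frag])
      if (!is.na(ty))
        out[(3L * (slot - 1L) + 1L):(3L * slot)] <- scheme$codes[[ty]]
    }
  }
  out
}

# random dictionary drawn from the fragments of a sentence plus noise
rand_dict_for <- function(chars, scheme, n_entries = 4L) {
  frags <- unique(unlist(lapply(seq_along(chars), function(i) {
    f <- fragments_at(chars, i)
    f[!is.na(f)]
  })))
  picks <- character(0)
  if (length(frags))
    picks <- frags[sample.int(length(frags), min(n_entries, length(frags)))]
  extra <- vapply(seq_len(2L), function(j)
    paste(rand_chars(sample(2:6, 1L)), collapse = ""), character(1))
  surfaces <- unique(c(picks, extra))
  types <- names(scheme$codes)
  entity_dictionary(surfaces,
                    types[(seq_along(surfaces) - 1L) %% length(types) + 1L],
                    type_order = types)
}

# full path enumeration for a CRF instance: scores of all L^n paths
enumerate_crf_scores <- function(emissions, transitions) {
  n <- nrow(emissions); L <- ncol(emissions)
  tr <- transitions$transition_weights + transitions$transition_bias
  paths <- as.matrix(expand.grid(rep(list(seq_len(L)), n)))
  scores <- tr[L + 1L, paths[, 1L]] + emissions[1L, paths[, 1L]]
  if (n > 1L) {
    for (t in 2:n)
      scores <- scores + tr[cbind(paths[, t - 1L], paths[, t])] +
        emissions[t, paths[, t]]
  }
  list(paths = paths, scores = scores)
}

rand_crf_instance <- function(n_max = 4L, L_max = 4L) {
  n <- sample.int(n_max, 1L)
  L <- sample.int(L_max, 1L)
  list(emissions = matrix(stats::rnorm(n * L, sd = 2), n, L),
       transitions = crf_params(L,
                                matrix(stats::rnorm((L + 1L) * L), L + 1L, L),
                                matrix(stats::rnorm((L + 1L) * L, sd = 0.5),
                                       L + 1L, L)))
}

# small feature/model bundle for network-level tests
tiny_setup <- function(seed = 5L, sentences = 6L) {
  spec <- synth_spec(alphabet_size = 12L, dict_size = 10L,
                     sentences = sentences, test_sentences = 2L,
                     mean_sentence_length = 8, seed = seed)
  syn <- gen_synthetic(spec)
  model <- new_tagger_model(
    syn$train$label_inventory,
    unique(unlist(lapply(syn$train$sentences, `[[`, "chars"))),
    syn$dict, syn$scheme, syn$radicals,
    char_dim = 5L, radical_dim = 3L, hidden_size = 4L,
    dropout = 0, seed = seed + 1L)
  list(syn = syn, model = model)
}

# the scaled-down experiment configuration used for synthetic studies
small_cfg <- function(seed, epochs = 15L, use_dictionary = TRUE, ...) {
  train_config(batch_size = 32L, epochs = epochs, learning_rate = 0.01,
               char_dim = 16L, radical_dim = 8L, hidden_size = 24L,
               dropout = 0.2, seed = seed, use_dictionary = use_dictionary,
               ...)
}
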