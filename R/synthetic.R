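# Synthetic corpora for hermetic experimentation. The alphabet lives in the
# Unicode private-use area (starting just above the reserved PAD character) so
# generated text can never collide with real clinical text. The alphabet is
# split into an entity sub-alphabet (surfaces are built only from it) and a
# background sub-alphabet (never used inside surfaces); every mention is
# separated from the next by at least one background character, so background
# text can never spell a dictionary surface and planted mentions are the
# unique gold standard.

SYNTH_BASE <- 0xE100L

# sample() treats a length-1 numeric as 1:n; resample never does
resample <- function(x, size, replace = FALSE)
  x[sample.int(length(x), size, replace = replace)]

#' Specification of a synthetic study
#'
#' The defaults define the standard synthetic corpus used throughout the
#' package's experiments: 5 entity types (mirroring the benchmark corpora),
#' a 40-surface gazetteer over a 60-character alphabet, 200 training and 60
#' test sentences averaging 18 characters, 1.5 entities per sentence, 30% of
#' test mentions drawn from the rare pool (training occurrence 0-3) and full
#' dictionary coverage.
#'
#' @param alphabet_size Total synthetic alphabet size (entity + background
#'   characters; two thirds are entity characters).
#' @param n_types Number of entity types (at most 7, the non-zero 3-bit
#'   codes).
#' @param dict_size Number of unique entity surfaces in the inventory.
#' @param sentences Training sentences to generate.
#' @param test_sentences Test sentences to generate.
#' @param mean_sentence_length Average sentence length in characters.
#' @param entity_rate Expected entities per sentence.
#' @param rare_fraction Fraction of test mentions drawn from the rare pool
#'   (surfaces with training occurrence count in 0..3).
#' @param dict_coverage Fraction of inventory surfaces present in the
#'   emitted dictionary.
#' @param radical_enrichment Probability that a character's radical is the
#'   one shared by its majority entity type (see [gen_radicals()]).
#' @param seed Integer seed.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(alphabet_size = 60L, n_types = 5L, dict_size = 40L,
                       sentences = 200L, test_sentences = 60L,
                       mean_sentence_length = 18, entity_rate = 1.5,
                       rare_fraction = 0.3, dict_coverage = 1,
                       radical_enrichment = 0.3, seed = 1L) {
  stopifnot(alphabet_size >= 6L, n_types >= 1L, n_types <= 7L,
            dict_size >= 0L, sentences >= 1L, test_sentences >= 0L,
            mean_sentence_length >= 2, entity_rate >= 0,
            rare_fraction >= 0, rare_fraction <= 1,
            dict_coverage >= 0, dict_coverage <= 1,
            radical_enrichment >= 0, radical_enrichment <= 1)
  structure(list(alphabet_size = as.integer(alphabet_size),
                 n_types = as.integer(n_types),
                 dict_size = as.integer(dict_size),
                 sentences = as.integer(sentences),
                 test_sentences = as.integer(test_sentences),
                 mean_sentence_length = mean_sentence_length,
                 entity_rate = entity_rate,
                 rare_fraction = rare_fraction,
                 dict_coverage = dict_coverage,
                 radical_enrichment = radical_enrichment,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

synth_alphabets <- function(spec) {
  all_chars <- intToUtf8(SYNTH_BASE + seq_len(spec$alphabet_size) - 1L,
                         multiple = TRUE)
  n_entity <- max(2L, ceiling(2 * spec$alphabet_size / 3))
  list(entity = all_chars[seq_len(n_entity)],
       background = all_chars[(n_entity + 1L):spec$alphabet_size])
}

synth_types <- function(spec) sprintf("Type%d", seq_len(spec$n_types))

#' Generate a synthetic entity dictionary and its code scheme
#'
#' Surfaces are unique strings of length 2-6 over the entity sub-alphabet;
#' types are assigned round-robin so every type is populated. Distinct
#' non-zero 3-bit codes are assigned in binary order.
#'
#' @param spec A [synth_spec()].
#' @return List with elements `dict` (an [entity_dictionary()] holding the
#'   full surface inventory) and `scheme` (a [type_code_scheme()]).
#' @export
gen_dictionary <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  ab <- synth_alphabets(spec)
  types <- synth_types(spec)
  with_seed(spec$seed, {
    lens <- sample(2:6, spec$dict_size, replace = TRUE)
    # capacity check: distinct surfaces of length 2 need |A|^2 >= demand
    if (spec$dict_size > 0 && length(ab$entity)^2 < sum(lens == 2L))
      stop("gen_dictionary: alphabet too small for the requested dictionary size")
    surfaces <- character(0)
    for (l in lens) {
      repeat {
        cand <- paste(resample(ab$entity, l, replace = TRUE), collapse = "")
        if (!(cand %in% surfaces)) { surfaces <- c(surfaces, cand); break }
      }
    }
    dict <- entity_dictionary(surfaces,
                              types[(seq_along(surfaces) - 1L) %% spec$n_types + 1L],
                              type_order = types)
    list(dict = dict, scheme = type_code_scheme(types))
  })
}

# one synthetic sentence: background runs interleaved with the given mention
# surfaces; returns a tagged_sentence with the planted mentions as gold
build_sentence <- function(surfaces, types, mean_len, background) {
  k <- length(surfaces)
  ent_len <- if (k) sum(nchar(surfaces)) else 0L
  n_bg <- max(k + 1L, round(mean_len) - ent_len)
  # split n_bg background characters into k + 1 runs, each >= 1
  cuts <- if (k) sort(sample.int(n_bg - 1L, k)) else integer(0)
  runs <- diff(c(0L, cuts, n_bg))
  chars <- character(0)
  mentions <- list()
  for (j in seq_len(k + 1L)) {
    chars <- c(chars, resample(background, runs[j], replace = TRUE))
    if (j <= k) {
      start <- length(chars)
      surf_chars <- strsplit(surfaces[j], "")[[1L]]
      chars <- c(chars, surf_chars)
      mentions[[j]] <- entity_mention(types[j], start,
                                      start + length(surf_chars), surfaces[j])
    }
  }
  tags <- entities_to_bio(length(chars), mentions)
  tagged_sentence(chars, tags)
}

#' Generate train and test corpora with controlled entity rarity
#'
#' Sentences are background characters with embedded dictionary surfaces as
#' gold mentions (non-overlapping, separated by background characters). A
#' rare pool of surfaces is planted in the training set exactly 0, 1, 2 or 3
#' times (cycling); test mentions are drawn from the rare pool with
#' probability `rare_fraction` and from the common pool otherwise, so the
#' test set exercises every rarity bucket.
#'
#' @param spec A [synth_spec()].
#' @param dict The full-inventory [entity_dictionary()] from
#'   [gen_dictionary()].
#' @return List with elements `train` and `test`, both [ner_corpus()]
#'   objects.
#' @export
gen_corpus <- function(spec, dict) {
  stopifnot(inherits(spec, "synth_spec"), inherits(dict, "entity_dictionary"))
  if (spec$entity_rate > 0 && !length(dict$entries))
    stop("gen_corpus: dictionary must be non-empty when entity_rate > 0")
  if (length(dict$entries) &&
      max(nchar(names(dict$entries))) + 2 > spec$mean_sentence_length * 3)
    stop("gen_corpus: entities too long for the requested sentence length")
  ab <- synth_alphabets(spec)
  surfaces <- names(dict$entries)
  types_of <- unname(dict$entries)
  with_seed(spec$seed + 1L, {
    n_surf <- length(surfaces)
    rare_pool <- integer(0)
    if (n_surf >= 8L && spec$rare_fraction > 0 && spec$entity_rate > 0) {
      rare_pool <- sample.int(n_surf, max(4L, round(0.25 * n_surf)))
    }
    common_pool <- setdiff(seq_len(n_surf), rare_pool)
    if (!length(common_pool)) { common_pool <- seq_len(n_surf); rare_pool <- integer(0) }
    rare_counts <- if (length(rare_pool))
      stats::setNames(rep_len(0:3, length(rare_pool)), rare_pool) else integer(0)

    # training mention multiset: forced rare occurrences + common fill
    n_train_mentions <- stats::rpois(1L, spec$entity_rate * spec$sentences)
    forced <- rep(as.integer(names(rare_counts)), rare_counts)
    n_fill <- max(0L, n_train_mentions - length(forced))
    train_mention_ids <- c(forced,
                           if (n_fill) resample(common_pool, n_fill, replace = TRUE))
    train_mention_ids <- sample(train_mention_ids)  # spread over sentences
    train_assign <- if (length(train_mention_ids))
      split(train_mention_ids,
            sample.int(spec$sentences, length(train_mention_ids),
                       replace = TRUE)) else list()
    train <- lapply(seq_len(spec$sentences), function(s) {
      ids <- train_assign[[as.character(s)]] %||% integer(0)
      build_sentence(surfaces[ids], types_of[ids],
                     spec$mean_sentence_length, ab$background)
    })

    test <- lapply(seq_len(spec$test_sentences), function(s) {
      k <- stats::rpois(1L, spec$entity_rate)
      ids <- integer(0)
      if (k > 0L && n_surf) {
        from_rare <- length(rare_pool) > 0 &
          stats::runif(k) < spec$rare_fraction
        ids <- ifelse(from_rare,
                      resample(rare_pool, k, replace = TRUE),
                      resample(common_pool, k, replace = TRUE))
      }
      build_sentence(surfaces[ids], types_of[ids],
                     spec$mean_sentence_length, ab$background)
    })
    types <- synth_types(spec)
    list(train = ner_corpus(train, label_inventory = types),
         test = ner_corpus(test, label_inventory = types))
  })
}

#' Generate a synthetic radical table
#'
#' Emulates the semantic clustering of real radicals: each entity type has a
#' dominant radical, and a character used mostly by that type's surfaces
#' carries the dominant radical with probability `radical_enrichment`
#' (otherwise a radical drawn uniformly). At enrichment 0 the assignment is
#' independent of type; at 1 the within-type radical purity is 100%.
#'
#' @param spec A [synth_spec()].
#' @param dict Optional [entity_dictionary()]; when supplied, enrichment is
#'   computed from which types use which characters. Without it the
#'   assignment is uniform.
#' @return A [radical_table()] covering the whole synthetic alphabet.
#' @export
gen_radicals <- function(spec, dict = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  ab <- synth_alphabets(spec)
  all_chars <- c(ab$entity, ab$background)
  types <- synth_types(spec)
  n_rad <- spec$n_types + 3L
  rad_names <- sprintf("rad%02d", seq_len(n_rad))
  with_seed(spec$seed + 2L, {
    assignment <- sample(rad_names, length(all_chars), replace = TRUE)
    names(assignment) <- all_chars
    if (!is.null(dict) && length(dict$entries) && spec$radical_enrichment > 0) {
      # majority type per character over the surfaces using it
      votes <- list()
      for (i in seq_along(dict$entries)) {
        for (ch in strsplit(names(dict$entries)[i], "")[[1L]]) {
          votes[[ch]] <- c(votes[[ch]], unname(dict$entries[[i]]))
        }
      }
      for (ch in names(votes)) {
        tab <- sort(table(votes[[ch]]), decreasing = TRUE)
        major <- match(names(tab)[1L], types)
        if (stats::runif(1L) < spec$radical_enrichment)
          assignment[ch] <- rad_names[major]   # type's dominant radical
      }
    }
    radical_table(all_chars, unname(assignment))
  })
}

#' Generate a complete synthetic study bundle
#'
#' Convenience wrapper calling [gen_dictionary()], [gen_corpus()] and
#' [gen_radicals()], then applying `dict_coverage`: the emitted dictionary
#' keeps a random `dict_coverage` fraction of the inventory surfaces (the
#' corpora are always generated from the full inventory).
#'
#' @param spec A [synth_spec()].
#' @param dir Optional output directory; when given, writes `train.conll`,
#'   `test.conll`, `dictionary.tsv`, `radicals.tsv` and `scheme.json`.
#' @return List with `train`, `test`, `dict` (emitted), `dict_full`,
#'   `scheme`, `radicals` and `spec`.
#' @export
gen_synthetic <- function(spec, dir = NULL) {
  inv <- gen_dictionary(spec)
  corp <- gen_corpus(spec, inv$dict)
  radicals <- gen_radicals(spec, inv$dict)
  dict <- inv$dict
  if (spec$dict_coverage < 1 && length(dict$entries)) {
    keep <- with_seed(spec$seed + 3L,
                      sample.int(length(dict$entries),
                                 floor(spec$dict_coverage * length(dict$entries))))
    dict <- entity_dictionary(names(dict$entries)[keep],
                              unname(dict$entries)[keep],
                              type_order = dict$type_order)
  }
  out <- list(train = corp$train, test = corp$test, dict = dict,
              dict_full = inv$dict, scheme = inv$scheme,
              radicals = radicals, spec = spec)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_conll(corp$train, file.path(dir, "train.conll"))
    write_conll(corp$test, file.path(dir, "test.conll"))
    writeLines(enc2utf8(paste(names(dict$entries), unname(dict$entries),
                              sep = "\t")),
               file.path(dir, "dictionary.tsv"), useBytes = TRUE)
    writeLines(enc2utf8(paste(names(radicals$mapping),
                              radicals$radical_names[radicals$mapping + 1L],
                              sep = "\t")),
               file.path(dir, "radicals.tsv"), useBytes = TRUE)
    jsonlite::write_json(lapply(out$scheme$codes, as.integer),
                         file.path(dir, "scheme.json"))
  }
  out
}
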