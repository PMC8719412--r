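#' Training configuration
#'
#' Defaults follow the reference training protocol: batch size 32, up to 300
#' epochs, Adam with initial learning rate 0.0005, dropout 0.5, sequences
#' padded/truncated at 250 characters, loss ratio `alpha : beta = 2 : 3`,
#' character/radical embedding widths 100/50 and 128 BiLSTM hidden units per
#' direction. Early stopping is off by default; set `early_stop_patience` to
#' an integer to hold out 10% of the training sentences and stop when their
#' loss has not improved for that many epochs.
#'
#' @param batch_size Mini-batch size.
#' @param epochs Maximum number of epochs.
#' @param learning_rate Adam step size.
#' @param max_len Maximum sentence length; longer sentences are truncated.
#' @param seed Integer seed controlling parameter initialization, shuffling
#'   and dropout.
#' @param loss_weights A [loss_weights()].
#' @param early_stop_patience Optional integer patience; `NULL` disables
#'   early stopping.
#' @param char_dim,radical_dim,hidden_size,dropout Model size parameters,
#'   passed to [new_tagger_model()].
#' @param use_dictionary Feed dictionary features (`TRUE`) or zeros (the
#'   ablation, `FALSE`).
#' @param verbose Print one line per epoch.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 32L, epochs = 300L,
                         learning_rate = 5e-4, max_len = 250L, seed = 42L,
                         loss_weights = dictagger::loss_weights(),
                         early_stop_patience = NULL,
                         char_dim = 100L, radical_dim = 50L,
                         hidden_size = 128L, dropout = 0.5,
                         use_dictionary = TRUE, verbose = FALSE) {
  stopifnot(batch_size >= 1L, epochs >= 1L, learning_rate > 0, max_len >= 1L,
            inherits(loss_weights, "loss_weights"))
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 max_len = as.integer(max_len),
                 seed = as.integer(seed),
                 loss_weights = loss_weights,
                 early_stop_patience = early_stop_patience,
                 char_dim = as.integer(char_dim),
                 radical_dim = as.integer(radical_dim),
                 hidden_size = as.integer(hidden_size),
                 dropout = dropout,
                 use_dictionary = isTRUE(use_dictionary),
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

truncate_sentence <- function(s, max_len) {
  if (length(s$chars) <= max_len) return(s)
  pad_truncate(s, max_len)
}

#' Train the multi-task tagger
#'
#' Minimizes the joint objective `alpha * loss1 + beta * loss2` (segmentation
#' cross-entropy plus CRF negative log-likelihood) over length-bucketed
#' mini-batches with Adam. The run is fully reproducible given `cfg$seed`:
#' the seed drives parameter initialization, batch shuffling and dropout.
#'
#' @param corpus Training [ner_corpus()] (non-empty).
#' @param dict An [entity_dictionary()].
#' @param scheme A [type_code_scheme()] covering the dictionary's types.
#' @param radicals A [radical_table()].
#' @param cfg A [train_config()].
#' @return A trained `dictagger_model`; `model$history` holds per-epoch
#'   `loss1`, `loss2` and combined `loss`.
#' @export
train_tagger <- function(corpus, dict, scheme, radicals,
                         cfg = train_config()) {
  stopifnot(inherits(corpus, "ner_corpus"), inherits(cfg, "train_config"))
  if (!length(corpus$sentences)) stop("train_tagger: empty corpus")
  set.seed(cfg$seed)
  sentences <- lapply(corpus$sentences, truncate_sentence,
                      max_len = cfg$max_len)
  vocab <- unique(unlist(lapply(sentences, function(s)
    s$chars[s$attention_mask == 1L]), use.names = FALSE))
  model <- new_tagger_model(
    types = corpus$label_inventory, vocab_chars = vocab,
    dict = dict, scheme = scheme, radicals = radicals,
    char_dim = cfg$char_dim, radical_dim = cfg$radical_dim,
    hidden_size = cfg$hidden_size, dropout = cfg$dropout,
    use_dictionary = cfg$use_dictionary,
    seed = sample.int(.Machine$integer.max, 1L))

  dev_idx <- integer(0)
  if (!is.null(cfg$early_stop_patience)) {
    n_dev <- max(1L, floor(0.1 * length(sentences)))
    dev_idx <- sample.int(length(sentences), n_dev)
  }
  train_idx <- setdiff(seq_along(sentences), dev_idx)
  if (!length(train_idx)) stop("train_tagger: no training sentences left")

  prepped <- lapply(sentences, function(s) prep_sentence(model, s))
  lengths <- vapply(prepped, `[[`, integer(1), "n")
  state <- adam_init(model$params)
  w <- cfg$loss_weights
  history <- data.frame(epoch = integer(0), loss1 = numeric(0),
                        loss2 = numeric(0), loss = numeric(0),
                        dev_loss = numeric(0))
  best_dev <- Inf; wait <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    batches <- make_batches(lengths[train_idx], cfg$batch_size)
    e1 <- 0; e2 <- 0; nb <- 0L
    for (batch in batches) {
      res <- batch_pass(model, prepped, train_idx[batch], w,
                        dropout = cfg$dropout, compute_grads = TRUE)
      if (!is.finite(res$loss))
        stop(sprintf("train_tagger: non-finite loss at epoch %d (loss1 = %g, loss2 = %g); aborting",
                     epoch, res$loss1, res$loss2))
      upd <- adam_update(model$params, res$grads, state, cfg$learning_rate)
      model$params <- upd$params
      state <- upd$state
      e1 <- e1 + res$loss1; e2 <- e2 + res$loss2; nb <- nb + 1L
    }
    dev_loss <- NA_real_
    if (length(dev_idx)) {
      dres <- batch_pass(model, prepped, dev_idx, w, dropout = 0,
                         compute_grads = FALSE)
      dev_loss <- dres$loss
    }
    history <- rbind(history,
                     data.frame(epoch = epoch, loss1 = e1 / nb, loss2 = e2 / nb,
                                loss = w$alpha * e1 / nb + w$beta * e2 / nb,
                                dev_loss = dev_loss))
    if (cfg$verbose)
      message(sprintf("epoch %3d  loss1 %.4f  loss2 %.4f  L %.4f%s",
                      epoch, e1 / nb, e2 / nb,
                      w$alpha * e1 / nb + w$beta * e2 / nb,
                      if (is.na(dev_loss)) "" else sprintf("  dev %.4f", dev_loss)))
    if (length(dev_idx)) {
      if (dev_loss < best_dev - 1e-8) { best_dev <- dev_loss; wait <- 0L }
      else {
        wait <- wait + 1L
        if (wait >= cfg$early_stop_patience) break
      }
    }
  }
  model$history <- history
  model$config <- cfg
  model
}

#' Predict BIO tags for sentences
#'
#' Runs the shared encoder and Viterbi-decodes the CRF head; the
#' segmentation head is not used at inference. Dropout is disabled. Padding
#' is stripped from the outputs.
#'
#' @param model A trained `dictagger_model`.
#' @param x A [ner_corpus()], a list of [tagged_sentence()]s, or a character
#'   vector of sentence strings (which are split into characters and tagged
#'   from scratch).
#' @param batch_size Sentences per forward batch.
#' @return A [ner_corpus()] whose sentences carry the predicted tags.
#' @export
predict_corpus <- function(model, x, batch_size = 64L) {
  stopifnot(inherits(model, "dictagger_model"))
  sentences <- if (inherits(x, "ner_corpus")) {
    unknown <- setdiff(x$label_inventory, model$types)
    if (length(unknown))
      stop(sprintf("predict_corpus: corpus uses entity types unknown to the model: %s",
                   paste(unknown, collapse = ", ")))
    x$sentences
  } else if (is.character(x)) {
    lapply(x[nzchar(x)], function(s) {
      chars <- strsplit(s, "")[[1L]]
      tagged_sentence(chars, rep("O", length(chars)))
    })
  } else x
  if (!length(sentences))
    return(ner_corpus(list(), label_inventory = model$types))
  sentences <- lapply(sentences, function(s) {
    real <- s$attention_mask == 1L
    tagged_sentence(s$chars[real], s$tags[real])
  })
  prepped <- lapply(sentences, function(s) {
    ps <- prep_sentence(model, s)
    ps$tag_ids <- rep(1L, ps$n)   # gold tags unused at inference
    ps
  })
  transitions <- model_crf(model)
  out <- vector("list", length(sentences))
  batches <- make_batches(vapply(prepped, `[[`, integer(1), "n"),
                          batch_size, shuffle = FALSE)
  for (batch in batches) {
    em <- batch_emissions(model, prepped, batch)
    for (j in seq_along(batch)) {
      b <- batch[j]
      vit <- viterbi_decode(em[[j]], transitions)
      out[[b]] <- tagged_sentence(sentences[[b]]$chars,
                                  model$labels[vit$path])
    }
  }
  ner_corpus(out, label_inventory = model$types)
}

#' @export
predict.dictagger_model <- function(object, newdata, ...) {
  predict_corpus(object, newdata, ...)
}

# emissions for a batch of prepared sentences, dropout off; returns a list of
# n_b x L matrices aligned with `idx`
batch_emissions <- function(model, prepped, idx) {
  p <- model$params
  B <- length(idx)
  ns <- vapply(prepped[idx], `[[`, integer(1), "n")
  T_max <- max(ns)
  H <- model$dims$hidden_size
  CI <- matrix(1L, B, T_max); RI <- matrix(0L, B, T_max)
  M <- matrix(0, B, T_max)
  for (b in seq_len(B)) {
    s <- prepped[[idx[b]]]
    CI[b, seq_len(s$n)] <- s$char_ids
    RI[b, seq_len(s$n)] <- s$rad_ids
    M[b, seq_len(s$n)] <- 1
  }
  X <- vector("list", T_max)
  for (t in seq_len(T_max)) {
    dict_t <- matrix(0, B, DICT_DIM)
    for (b in seq_len(B)) {
      s <- prepped[[idx[b]]]
      if (t <= s$n) dict_t[b, ] <- s$dict[t, ]
    }
    X[[t]] <- cbind(p$E_char[CI[, t], , drop = FALSE],
                    p$E_rad[RI[, t] + 1L, , drop = FALSE],
                    dict_t)
  }
  steps <- seq_len(T_max)
  fw <- lstm_forward_batch(p$fwd, X, M, steps, keep_cache = FALSE)
  bw <- lstm_forward_batch(p$bwd, X, M, rev(steps), keep_cache = FALSE)
  lapply(seq_len(B), function(b) {
    n <- ns[b]
    emis <- matrix(0, n, model$dims$n_labels)
    for (t in seq_len(n)) {
      enc <- cbind(fw$H[[t]][b, , drop = FALSE], bw$H[[t]][b, , drop = FALSE])
      emis[t, ] <- drop(add_bias(enc %*% t(p$em_W), p$em_b))
    }
    emis
  })
}
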