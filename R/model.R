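UNK_CHAR_TOKEN <- "<UNK>"

# label inventory -> BIO label strings; "O" is label 1, then B-/I- per type
bio_labels <- function(types) {
  c("O", as.vector(rbind(paste0("B-", types), paste0("I-", types))))
}

#' Construct an untrained multi-task tagger model
#'
#' The model holds the character and radical embedding tables, the shared
#' bidirectional LSTM encoder (one [lstm_params()] per direction), the
#' binary segmentation head (a linear map of the encoder output to one score
#' per token) and the CRF recognition head (a linear emission projection plus
#' [crf_params()] transitions). Both heads consume the same shared encoder
#' output. The feature resources used to build inputs (dictionary, code
#' scheme, radical table, character vocabulary) are carried along so that
#' prediction uses exactly the training-time features.
#'
#' @param types Ordered character vector of entity-type names.
#' @param vocab_chars Character vector of the known characters (PAD and UNK
#'   entries are added internally).
#' @param dict An [entity_dictionary()].
#' @param scheme A [type_code_scheme()] covering the dictionary's types.
#' @param radicals A [radical_table()].
#' @param char_dim,radical_dim Embedding widths (defaults 100 and 50).
#' @param hidden_size Hidden units per LSTM direction (default 128).
#' @param dropout Dropout rate applied to the assembled input features and to
#'   the encoder output during training (default 0.5); disabled at inference.
#' @param use_dictionary When `FALSE` the 30 dictionary feature dimensions
#'   are fed as zeros (the no-gazetteer ablation); the architecture is
#'   unchanged.
#' @param seed Integer seed for parameter initialization.
#' @return An object of class `dictagger_model`.
#' @export
new_tagger_model <- function(types, vocab_chars, dict, scheme, radicals,
                             char_dim = 100L, radical_dim = 50L,
                             hidden_size = 128L, dropout = 0.5,
                             use_dictionary = TRUE, seed = 1L) {
  stopifnot(length(types) >= 1L, dropout >= 0, dropout < 1)
  missing_codes <- setdiff(unique(unname(dict$entries)), names(scheme$codes))
  if (length(missing_codes))
    stop(sprintf("new_tagger_model: dictionary type(s) without a code: %s",
                 paste(missing_codes, collapse = ", ")))
  char_vocab <- c(PAD_CHAR, UNK_CHAR_TOKEN,
                  setdiff(unique(vocab_chars), c(PAD_CHAR, UNK_CHAR_TOKEN)))
  labels <- bio_labels(types)
  L <- length(labels)
  input_dim <- char_dim + radical_dim + DICT_DIM
  n_rad <- length(radicals$radical_names)
  params <- with_seed(seed, {
    bc <- sqrt(3 / char_dim); br <- sqrt(3 / radical_dim)
    list(
      E_char = matrix(stats::runif(length(char_vocab) * char_dim, -bc, bc),
                      length(char_vocab), char_dim),
      E_rad = matrix(stats::runif(n_rad * radical_dim, -br, br),
                     n_rad, radical_dim),
      fwd = lstm_params(input_dim, hidden_size),
      bwd = lstm_params(input_dim, hidden_size),
      seg_w = stats::runif(2L * hidden_size, -0.1, 0.1),
      seg_b = 0,
      em_W = matrix(stats::runif(L * 2L * hidden_size,
                                 -sqrt(6 / (L + 2 * hidden_size)),
                                 sqrt(6 / (L + 2 * hidden_size))),
                    L, 2L * hidden_size),
      em_b = numeric(L),
      trans_w = matrix(0, L + 1L, L),
      trans_b = matrix(0, L + 1L, L)
    )
  })
  structure(list(
    params = params,
    types = as.character(types),
    labels = labels,
    char_vocab = char_vocab,
    dict = dict, scheme = scheme, radicals = radicals,
    dims = list(char_dim = as.integer(char_dim),
                radical_dim = as.integer(radical_dim),
                hidden_size = as.integer(hidden_size),
                input_dim = as.integer(input_dim),
                n_labels = L),
    dropout = dropout,
    use_dictionary = isTRUE(use_dictionary),
    history = NULL
  ), class = "dictagger_model")
}

#' @export
print.dictagger_model <- function(x, ...) {
  d <- x$dims
  cat(sprintf(paste0("<dictagger_model> %d types, %d labels | char %d + radical %d",
                     " + dict %d -> BiLSTM %dx2 | dictionary %s\n"),
              length(x$types), d$n_labels, d$char_dim, d$radical_dim,
              DICT_DIM, d$hidden_size,
              if (x$use_dictionary) "on" else "off"))
  if (!is.null(x$history))
    cat(sprintf("  trained %d epochs; final loss %.4f\n",
                nrow(x$history), x$history$loss[nrow(x$history)]))
  invisible(x)
}

# CRF transition parameters of a model, as a crf_params object
model_crf <- function(model) {
  crf_params(model$dims$n_labels, model$params$trans_w, model$params$trans_b)
}

# flatten the nested parameter list into named numeric leaves:
# "E_char", "fwd.W_xi", ..., used by the optimizer and the gradient checker
param_keys <- function(params) {
  keys <- character(0)
  for (nm in names(params)) {
    p <- params[[nm]]
    if (inherits(p, "lstm_params")) {
      keys <- c(keys, paste0(nm, ".", setdiff(names(p),
                                              c("hidden_size", "input_dim"))))
    } else keys <- c(keys, nm)
  }
  keys
}

get_param <- function(params, key) {
  parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
  if (length(parts) == 2L) params[[parts[1L]]][[parts[2L]]] else params[[key]]
}

set_param <- function(params, key, value) {
  parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
  if (length(parts) == 2L) params[[parts[1L]]][[parts[2L]]] <- value
  else params[[key]] <- value
  params
}

#' Save a trained model checkpoint
#'
#' Writes the serialized model next to a JSON sidecar recording the label
#' inventory, feature dimensions and training configuration; the sidecar is
#' compared on load so that incompatible checkpoints fail loudly.
#'
#' @param model A `dictagger_model`.
#' @param path Checkpoint path; the sidecar is written to
#'   `paste0(path, ".json")`.
#' @return Invisibly, `path`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "dictagger_model"))
  saveRDS(model, path)
  sidecar <- list(labels = model$labels, types = model$types,
                  dims = model$dims, dropout = model$dropout,
                  use_dictionary = model$use_dictionary,
                  package_class = "dictagger_model")
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Path given to [save_checkpoint()].
#' @return The restored `dictagger_model`.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop(sprintf("load_checkpoint: no such file: %s", path))
  model <- readRDS(path)
  if (!inherits(model, "dictagger_model"))
    stop("load_checkpoint: file does not contain a dictagger_model")
  side_path <- paste0(path, ".json")
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    if (!identical(as.character(side$labels), model$labels) ||
        !identical(as.integer(side$dims$n_labels), model$dims$n_labels) ||
        !identical(as.integer(side$dims$hidden_size), model$dims$hidden_size))
      stop("load_checkpoint: sidecar configuration does not match the checkpoint (incompatible label inventory or dimensions)")
  }
  model
}
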