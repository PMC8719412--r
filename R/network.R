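logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Construct one direction's LSTM parameter set
#'
#' Gate weights follow the standard LSTM cell: input gate `i`, forget gate
#' `f`, cell candidate `c` and output gate `o`, each with an input-to-hidden
#' matrix `W_x*` (hidden x input), a hidden-to-hidden matrix `W_h*` (hidden x
#' hidden) and a bias `b_*`. Weights are initialized uniform with a
#' fan-based bound; the forget-gate bias starts at 1 so early training does
#' not wash out the cell state.
#'
#' @param input_dim Width of the input vectors.
#' @param hidden_size Number of hidden units (default 128).
#' @return An object of class `lstm_params`.
#' @export
lstm_params <- function(input_dim, hidden_size = 128L) {
  stopifnot(input_dim >= 1L, hidden_size >= 1L)
  wx <- function() matrix(stats::runif(hidden_size * input_dim,
                                       -sqrt(6 / (hidden_size + input_dim)),
                                       sqrt(6 / (hidden_size + input_dim))),
                          hidden_size, input_dim)
  wh <- function() matrix(stats::runif(hidden_size * hidden_size,
                                       -sqrt(6 / (2 * hidden_size)),
                                       sqrt(6 / (2 * hidden_size))),
                          hidden_size, hidden_size)
  structure(list(W_xi = wx(), W_hi = wh(), b_i = numeric(hidden_size),
                 W_xf = wx(), W_hf = wh(), b_f = rep(1, hidden_size),
                 W_xc = wx(), W_hc = wh(), b_c = numeric(hidden_size),
                 W_xo = wx(), W_ho = wh(), b_o = numeric(hidden_size),
                 hidden_size = as.integer(hidden_size),
                 input_dim = as.integer(input_dim)),
            class = "lstm_params")
}

#' One LSTM cell step
#'
#' Computes, with `s()` the element-wise sigmoid and `*` element-wise
#' multiplication:
#' \deqn{i = s(W_{xi} x + W_{hi} h + b_i), \quad
#'       f = s(W_{xf} x + W_{hf} h + b_f)}
#' \deqn{c_t = f * c_{t-1} + i * \tanh(W_{xc} x + W_{hc} h + b_c)}
#' \deqn{o = s(W_{xo} x + W_{ho} h + b_o), \quad h_t = o * \tanh(c_t)}
#'
#' @param x_t Input vector (length `input_dim`).
#' @param h_prev Previous hidden state (length `hidden_size`).
#' @param c_prev Previous cell state (length `hidden_size`).
#' @param params An [lstm_params()].
#' @return List with elements `h` and `c`, the new hidden and cell states.
#' @export
lstm_step <- function(x_t, h_prev, c_prev, params) {
  if (length(x_t) != params$input_dim)
    stop("lstm_step: x_t has wrong width")
  if (length(h_prev) != params$hidden_size ||
      length(c_prev) != params$hidden_size)
    stop("lstm_step: state vectors have wrong width")
  i <- sigmoid(drop(params$W_xi %*% x_t + params$W_hi %*% h_prev) + params$b_i)
  f <- sigmoid(drop(params$W_xf %*% x_t + params$W_hf %*% h_prev) + params$b_f)
  g <- tanh(drop(params$W_xc %*% x_t + params$W_hc %*% h_prev) + params$b_c)
  o <- sigmoid(drop(params$W_xo %*% x_t + params$W_ho %*% h_prev) + params$b_o)
  c_t <- f * c_prev + i * g
  list(h = o * tanh(c_t), c = c_t)
}

#' Encode a sentence with the shared bidirectional LSTM
#'
#' Runs the forward- and backward-direction LSTMs from zero initial states
#' and concatenates their hidden states per position, so row `t` is
#' `[h_fwd_t ; h_bwd_t]` of width `2 * hidden_size`.
#'
#' @param inputs Numeric matrix `n` x `input_dim` (one row per position,
#'   from [assemble_input()]).
#' @param model A tagger model (see [new_tagger_model()]) — its `fwd` and
#'   `bwd` LSTM parameter sets are used.
#' @return Numeric matrix `n` x `2 * hidden_size`.
#' @export
bilstm_encode <- function(inputs, model) {
  stopifnot(is.matrix(inputs), nrow(inputs) >= 1L)
  p <- model$params
  H <- p$fwd$hidden_size
  n <- nrow(inputs)
  hf <- matrix(0, n, H); hb <- matrix(0, n, H)
  h <- numeric(H); cc <- numeric(H)
  for (t in seq_len(n)) {
    st <- lstm_step(inputs[t, ], h, cc, p$fwd)
    h <- st$h; cc <- st$c
    hf[t, ] <- h
  }
  h <- numeric(H); cc <- numeric(H)
  for (t in rev(seq_len(n))) {
    st <- lstm_step(inputs[t, ], h, cc, p$bwd)
    h <- st$h; cc <- st$c
    hb[t, ] <- h
  }
  cbind(hf, hb)
}

#' Per-token entity probabilities from the segmentation head
#'
#' A linear map of the shared encoder output to one score per token, passed
#' through the sigmoid: the probability that the token is part of an entity.
#'
#' @param encoded Matrix from [bilstm_encode()].
#' @param model A tagger model.
#' @return Numeric vector of probabilities strictly inside (0, 1).
#' @export
seg_forward <- function(encoded, model) {
  p <- model$params
  sigmoid(drop(encoded %*% p$seg_w) + p$seg_b)
}

#' Binary cross-entropy loss of the segmentation head
#'
#' For one-hot true distribution `p` from the 0/1 segmentation labels and
#' predicted distribution `q`, sums `-[p(1) log q(1) + p(0) log q(0)]` over
#' the masked (real) positions. Probabilities are clamped to
#' `[1e-12, 1 - 1e-12]` for numerical safety.
#'
#' @param probs Predicted per-token probabilities.
#' @param seg_labels 0/1 gold segmentation labels, same length.
#' @param mask 0/1 attention mask, same length; padding (0) is excluded.
#' @return Non-negative scalar loss.
#' @export
seg_bce_loss <- function(probs, seg_labels, mask = rep(1L, length(probs))) {
  n <- length(probs)
  if (length(seg_labels) != n || length(mask) != n)
    stop("seg_bce_loss: probs, seg_labels and mask must align")
  q <- pmin(pmax(probs, 1e-12), 1 - 1e-12)
  ll <- seg_labels * log(q) + (1 - seg_labels) * log(1 - q)
  -sum(ll[mask == 1L])
}

#' Construct linear-chain CRF transition parameters
#'
#' The potential of a label step is
#' `exp(transition(y_prev, y) + emission(t, y))`; transitions carry both a
#' weight and a bias matrix over label pairs (their sum is the effective
#' transition score). Row `L + 1` of each matrix is the dedicated START
#' state, contributing the transition into the first label; there is no STOP
#' transition.
#'
#' @param n_labels Number of labels L.
#' @param transition_weights Optional `(L + 1)` x `L` matrix (defaults to 0).
#' @param transition_bias Optional `(L + 1)` x `L` matrix (defaults to 0).
#' @return An object of class `crf_params`.
#' @export
crf_params <- function(n_labels, transition_weights = NULL,
                       transition_bias = NULL) {
  n_labels <- as.integer(n_labels)
  stopifnot(n_labels >= 1L)
  if (is.null(transition_weights))
    transition_weights <- matrix(0, n_labels + 1L, n_labels)
  if (is.null(transition_bias))
    transition_bias <- matrix(0, n_labels + 1L, n_labels)
  for (m in list(transition_weights, transition_bias))
    if (!is.matrix(m) || nrow(m) != n_labels + 1L || ncol(m) != n_labels ||
        !all(is.finite(m)))
      stop("crf_params: transition matrices must be finite (L + 1) x L")
  structure(list(transition_weights = transition_weights,
                 transition_bias = transition_bias,
                 n_labels = n_labels),
            class = "crf_params")
}

crf_trans <- function(transitions) {
  transitions$transition_weights + transitions$transition_bias
}

check_path <- function(path, n, L) {
  path <- as.integer(path)
  if (length(path) != n) stop("crf: path length must equal emissions length")
  if (any(path < 1L | path > L)) stop("crf: label index out of range")
  path
}

#' Score of one label path under the CRF
#'
#' The unnormalized log-score: the sum over positions of
#' `transition(y_prev, y_t) + emission(t, y_t)`, where the transition into
#' the first position comes from the START row.
#'
#' @param emissions Numeric matrix `n` x `L` of per-position label scores.
#' @param transitions A [crf_params()].
#' @param path Integer vector of 1-based label indices, length `n`.
#' @return Scalar log-score.
#' @export
crf_score <- function(emissions, transitions, path) {
  n <- nrow(emissions); L <- ncol(emissions)
  path <- check_path(path, n, L)
  tr <- crf_trans(transitions)
  start_row <- L + 1L
  sc <- tr[start_row, path[1L]] + emissions[1L, path[1L]]
  if (n > 1L) {
    for (t in 2:n)
      sc <- sc + tr[path[t - 1L], path[t]] + emissions[t, path[t]]
  }
  sc
}

#' Log-partition function of the CRF
#'
#' The log of the sum of `exp(score)` over all `L^n` label paths, computed
#' by the forward algorithm in log space (log-sum-exp recursion).
#'
#' @inheritParams crf_score
#' @return Scalar log-partition value.
#' @export
crf_log_partition <- function(emissions, transitions) {
  n <- nrow(emissions); L <- ncol(emissions)
  tr <- crf_trans(transitions)
  alpha <- tr[L + 1L, ] + emissions[1L, ]
  if (n > 1L) {
    for (t in 2:n) {
      # alpha_new[y] = logsumexp_prev(alpha[prev] + tr[prev, y]) + emis[t, y]
      m <- apply(alpha + tr[seq_len(L), , drop = FALSE], 2L, logsumexp)
      alpha <- m + emissions[t, ]
    }
  }
  logsumexp(alpha)
}

#' Negative log-likelihood of a gold path under the CRF
#'
#' `crf_log_partition(...) - crf_score(..., gold_path)`; the minimized form
#' of the CRF's conditional log-likelihood.
#'
#' @inheritParams crf_score
#' @param gold_path Integer vector of gold label indices.
#' @return Non-negative scalar loss (0 only when the gold path carries all
#'   probability mass).
#' @export
crf_nll <- function(emissions, transitions, gold_path) {
  crf_log_partition(emissions, transitions) -
    crf_score(emissions, transitions, gold_path)
}

#' Viterbi decoding of the best label path
#'
#' Dynamic program over `transition + emission` scores. Ties are broken
#' toward the lowest label index at each backpointer, so decoding is
#' deterministic. The returned score always equals [crf_score()] of the
#' returned path.
#'
#' @inheritParams crf_score
#' @return List with `path` (integer label indices) and `score`.
#' @export
viterbi_decode <- function(emissions, transitions) {
  n <- nrow(emissions); L <- ncol(emissions)
  tr <- crf_trans(transitions)
  delta <- tr[L + 1L, ] + emissions[1L, ]
  back <- matrix(0L, n, L)
  if (n > 1L) {
    for (t in 2:n) {
      cand <- delta + tr[seq_len(L), , drop = FALSE]  # prev x next
      best_prev <- apply(cand, 2L, which.max)          # first max = lowest index
      delta <- cand[cbind(best_prev, seq_len(L))] + emissions[t, ]
      back[t, ] <- best_prev
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta)
  if (n > 1L) {
    for (t in n:2) path[t - 1L] <- back[t, path[t]]
  }
  list(path = path, score = max(delta))
}

#' Multi-task loss weights
#'
#' The joint objective is `L = alpha * loss1 + beta * loss2` with `loss1`
#' the segmentation cross-entropy and `loss2` the CRF negative
#' log-likelihood. The default ratio is `alpha : beta = 2 : 3`
#' (`alpha = 0.4`, `beta = 0.6`).
#'
#' @param alpha Non-negative weight of the segmentation loss.
#' @param beta Non-negative weight of the recognition loss.
#' @return An object of class `loss_weights`.
#' @export
loss_weights <- function(alpha = 0.4, beta = 0.6) {
  if (alpha < 0 || beta < 0 || alpha + beta <= 0)
    stop("loss_weights: need alpha, beta >= 0 and alpha + beta > 0")
  structure(list(alpha = alpha, beta = beta), class = "loss_weights")
}

#' Weighted combination of the two task losses
#'
#' @param loss1 Segmentation (cross-entropy) loss.
#' @param loss2 Recognition (CRF negative log-likelihood) loss.
#' @param w A [loss_weights()].
#' @return `w$alpha * loss1 + w$beta * loss2`.
#' @export
combined_loss <- function(loss1, loss2, w = loss_weights()) {
  if (!is.finite(loss1) || !is.finite(loss2))
    stop("combined_loss: losses must be finite")
  w$alpha * loss1 + w$beta * loss2
}
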