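# Internal training machinery: batched BiLSTM forward/backward passes with
# masking, CRF forward-backward gradients, and Adam. Sentences in a batch are
# right-padded to the batch's maximum length; the mask guarantees that padded
# positions contribute nothing to losses or gradients (verified by the
# finite-difference gradient checks in the test suite).

add_bias <- function(A, b) A + rep(b, each = nrow(A))

# per-sentence feature indices computed once per corpus
prep_sentence <- function(model, sentence) {
  real <- sentence$attention_mask == 1L
  chars <- sentence$chars[real]
  tags <- sentence$tags[real]
  ci <- match(chars, model$char_vocab)
  ci[is.na(ci)] <- 2L                       # UNK row
  ri <- radicals_of(chars, model$radicals)
  dict_feats <- if (model$use_dictionary) {
    encode_sentence_dict(chars, model$dict, model$scheme)
  } else matrix(0L, length(chars), DICT_DIM)
  tag_ids <- match(tags, model$labels)
  if (anyNA(tag_ids))
    stop(sprintf("prep_sentence: tag '%s' not in the model's label inventory",
                 tags[which(is.na(tag_ids))[1L]]))
  list(char_ids = ci, rad_ids = ri, dict = dict_feats,
       seg = sentence$seg_labels[real], tag_ids = tag_ids,
       n = length(chars))
}

prep_corpus <- function(model, corpus) {
  lapply(corpus$sentences, function(s) prep_sentence(model, s))
}

# length-bucketed batches; batch order shuffled by the caller's RNG
make_batches <- function(lengths, batch_size, shuffle = TRUE) {
  ord <- order(lengths)
  batches <- split(ord, ceiling(seq_along(ord) / batch_size))
  if (shuffle && length(batches) > 1L)
    batches <- batches[sample.int(length(batches))]
  batches
}

# one direction's masked, batched LSTM scan; time order given by `steps`
lstm_forward_batch <- function(p, X, M, steps, keep_cache = TRUE) {
  B <- nrow(X[[1L]]); H <- p$hidden_size
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  Hs <- vector("list", length(X))
  cache <- if (keep_cache) vector("list", length(X)) else NULL
  for (t in steps) {
    Xt <- X[[t]]; m <- M[, t]
    a_i <- add_bias(Xt %*% t(p$W_xi) + h %*% t(p$W_hi), p$b_i)
    a_f <- add_bias(Xt %*% t(p$W_xf) + h %*% t(p$W_hf), p$b_f)
    a_c <- add_bias(Xt %*% t(p$W_xc) + h %*% t(p$W_hc), p$b_c)
    a_o <- add_bias(Xt %*% t(p$W_xo) + h %*% t(p$W_ho), p$b_o)
    gi <- 1 / (1 + exp(-a_i)); gf <- 1 / (1 + exp(-a_f))
    gg <- tanh(a_c);           go <- 1 / (1 + exp(-a_o))
    c_cand <- gf * cc + gi * gg
    tanh_c <- tanh(c_cand)
    h_cand <- go * tanh_c
    c_new <- m * c_cand + (1 - m) * cc
    h_new <- m * h_cand + (1 - m) * h
    if (keep_cache)
      cache[[t]] <- list(i = gi, f = gf, g = gg, o = go, tanh_c = tanh_c,
                         hp = h, cp = cc, m = m)
    h <- h_new; cc <- c_new
    Hs[[t]] <- h
  }
  list(H = Hs, cache = cache)
}

zero_like_lstm <- function(p) {
  z <- lapply(p[c("W_xi", "W_hi", "b_i", "W_xf", "W_hf", "b_f",
                  "W_xc", "W_hc", "b_c", "W_xo", "W_ho", "b_o")],
              function(x) x * 0)
  z
}

# backward scan through one direction; dH is the list of d(loss)/d(h_t)
lstm_backward_batch <- function(p, X, cache, dH, steps) {
  B <- nrow(X[[1L]]); H <- p$hidden_size
  g <- zero_like_lstm(p)
  dX <- vector("list", length(X))
  dh_carry <- matrix(0, B, H); dc_carry <- matrix(0, B, H)
  for (t in rev(steps)) {
    cc <- cache[[t]]
    m <- cc$m
    dh <- dH[[t]] + dh_carry
    dh_cand <- m * dh
    dh_prev_part <- (1 - m) * dh
    dc_cand <- m * dc_carry
    dc_prev_part <- (1 - m) * dc_carry
    do_ <- dh_cand * cc$tanh_c
    dc_cand <- dc_cand + dh_cand * cc$o * (1 - cc$tanh_c^2)
    di <- dc_cand * cc$g
    df <- dc_cand * cc$cp
    dg <- dc_cand * cc$i
    dc_prev <- dc_cand * cc$f + dc_prev_part
    da_i <- di * cc$i * (1 - cc$i)
    da_f <- df * cc$f * (1 - cc$f)
    da_c <- dg * (1 - cc$g^2)
    da_o <- do_ * cc$o * (1 - cc$o)
    Xt <- X[[t]]; Hp <- cc$hp
    g$W_xi <- g$W_xi + crossprod(da_i, Xt)
    g$W_hi <- g$W_hi + crossprod(da_i, Hp)
    g$b_i <- g$b_i + colSums(da_i)
    g$W_xf <- g$W_xf + crossprod(da_f, Xt)
    g$W_hf <- g$W_hf + crossprod(da_f, Hp)
    g$b_f <- g$b_f + colSums(da_f)
    g$W_xc <- g$W_xc + crossprod(da_c, Xt)
    g$W_hc <- g$W_hc + crossprod(da_c, Hp)
    g$b_c <- g$b_c + colSums(da_c)
    g$W_xo <- g$W_xo + crossprod(da_o, Xt)
    g$W_ho <- g$W_ho + crossprod(da_o, Hp)
    g$b_o <- g$b_o + colSums(da_o)
    dX[[t]] <- da_i %*% p$W_xi + da_f %*% p$W_xf +
      da_c %*% p$W_xc + da_o %*% p$W_xo
    dh_carry <- da_i %*% p$W_hi + da_f %*% p$W_hf +
      da_c %*% p$W_hc + da_o %*% p$W_ho + dh_prev_part
    dc_carry <- dc_prev
  }
  list(dX = dX, grads = g)
}

# CRF forward-backward for one sentence: NLL and its gradients with respect
# to the emissions and the effective transition matrix (marginals minus gold)
crf_grad <- function(emis, tr, gold) {
  n <- nrow(emis); L <- ncol(emis)
  trL <- tr[seq_len(L), , drop = FALSE]
  la <- matrix(0, n, L)
  la[1L, ] <- tr[L + 1L, ] + emis[1L, ]
  if (n > 1L) for (t in 2:n)
    la[t, ] <- apply(la[t - 1L, ] + trL, 2L, logsumexp) + emis[t, ]
  logZ <- logsumexp(la[n, ])
  lb <- matrix(0, n, L)
  if (n > 1L) for (t in (n - 1L):1L)
    lb[t, ] <- apply(t(trL) + (emis[t + 1L, ] + lb[t + 1L, ]), 2L, logsumexp)
  marg <- exp(la + lb - logZ)
  d_emis <- marg
  d_emis[cbind(seq_len(n), gold)] <- d_emis[cbind(seq_len(n), gold)] - 1
  d_tr <- matrix(0, L + 1L, L)
  d_tr[L + 1L, ] <- marg[1L, ]
  d_tr[L + 1L, gold[1L]] <- d_tr[L + 1L, gold[1L]] - 1
  score <- tr[L + 1L, gold[1L]] + emis[1L, gold[1L]]
  if (n > 1L) for (t in 2:n) {
    pair <- exp(matrix(la[t - 1L, ], L, L) + trL +
                  rep(emis[t, ] + lb[t, ], each = L) - logZ)
    d_tr[seq_len(L), ] <- d_tr[seq_len(L), ] + pair
    d_tr[gold[t - 1L], gold[t]] <- d_tr[gold[t - 1L], gold[t]] - 1
    score <- score + tr[gold[t - 1L], gold[t]] + emis[t, gold[t]]
  }
  list(nll = logZ - score, d_emis = d_emis, d_tr = d_tr)
}

# dropout mask with inverted scaling, or NULL when rate is 0
drop_mask <- function(nr, nc, rate) {
  if (rate <= 0) return(NULL)
  matrix(stats::rbinom(nr * nc, 1L, 1 - rate) / (1 - rate), nr, nc)
}

# Full forward (and optional backward) pass over one batch of prepared
# sentences. Returns mean per-sentence losses and, when compute_grads, the
# gradient of  (alpha * loss1 + beta * loss2) / B  in the same nested layout
# as model$params.
batch_pass <- function(model, prepped, idx, w, dropout = model$dropout,
                       compute_grads = TRUE) {
  p <- model$params
  B <- length(idx)
  ns <- vapply(prepped[idx], `[[`, integer(1), "n")
  T_max <- max(ns)
  H <- model$dims$hidden_size
  D <- model$dims$input_dim
  L <- model$dims$n_labels
  cd <- model$dims$char_dim; rd <- model$dims$radical_dim

  CI <- matrix(1L, B, T_max)                # PAD row
  RI <- matrix(0L, B, T_max)                # unknown radical
  M <- matrix(0, B, T_max)
  SEG <- matrix(0, B, T_max)
  for (b in seq_len(B)) {
    s <- prepped[[idx[b]]]
    CI[b, seq_len(s$n)] <- s$char_ids
    RI[b, seq_len(s$n)] <- s$rad_ids
    M[b, seq_len(s$n)] <- 1
    SEG[b, seq_len(s$n)] <- s$seg
  }

  X <- vector("list", T_max)
  DMx <- vector("list", T_max)
  for (t in seq_len(T_max)) {
    dict_t <- matrix(0, B, DICT_DIM)
    for (b in seq_len(B)) {
      s <- prepped[[idx[b]]]
      if (t <= s$n) dict_t[b, ] <- s$dict[t, ]
    }
    xt <- cbind(p$E_char[CI[, t], , drop = FALSE],
                p$E_rad[RI[, t] + 1L, , drop = FALSE],
                dict_t)
    dm <- drop_mask(B, D, dropout)
    if (!is.null(dm)) { DMx[[t]] <- dm; xt <- xt * dm }
    X[[t]] <- xt
  }

  steps <- seq_len(T_max)
  fw <- lstm_forward_batch(p$fwd, X, M, steps, keep_cache = compute_grads)
  bw <- lstm_forward_batch(p$bwd, X, M, rev(steps), keep_cache = compute_grads)

  ENC <- vector("list", T_max)
  DMe <- vector("list", T_max)
  for (t in steps) {
    enc <- cbind(fw$H[[t]], bw$H[[t]])
    dm <- drop_mask(B, 2L * H, dropout)
    if (!is.null(dm)) { DMe[[t]] <- dm; enc <- enc * dm }
    ENC[[t]] <- enc
  }

  # segmentation head
  seg_sum <- 0
  PL <- vector("list", T_max)               # d(loss1)/d(logit), unscaled
  for (t in steps) {
    prob <- 1 / (1 + exp(-(drop(ENC[[t]] %*% p$seg_w) + p$seg_b)))
    q <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
    m <- M[, t]
    seg_sum <- seg_sum -
      sum(m * (SEG[, t] * log(q) + (1 - SEG[, t]) * log(1 - q)))
    PL[[t]] <- m * (prob - SEG[, t])
  }

  # emissions and per-sentence CRF
  EM <- vector("list", T_max)
  for (t in steps) EM[[t]] <- add_bias(ENC[[t]] %*% t(p$em_W), p$em_b)
  tr <- p$trans_w + p$trans_b
  nll_sum <- 0
  dEM <- if (compute_grads) lapply(steps, function(t) matrix(0, B, L)) else NULL
  d_tr <- matrix(0, L + 1L, L)
  for (b in seq_len(B)) {
    s <- prepped[[idx[b]]]
    emis <- matrix(0, s$n, L)
    for (t in seq_len(s$n)) emis[t, ] <- EM[[t]][b, ]
    cg <- crf_grad(emis, tr, s$tag_ids)
    nll_sum <- nll_sum + cg$nll
    if (compute_grads) {
      for (t in seq_len(s$n)) dEM[[t]][b, ] <- cg$d_emis[t, ]
      d_tr <- d_tr + cg$d_tr
    }
  }

  loss1 <- seg_sum / B
  loss2 <- nll_sum / B
  loss <- w$alpha * loss1 + w$beta * loss2
  if (!compute_grads)
    return(list(loss = loss, loss1 = loss1, loss2 = loss2))

  a_eff <- w$alpha / B
  b_eff <- w$beta / B
  grads <- list(E_char = p$E_char * 0, E_rad = p$E_rad * 0,
                fwd = NULL, bwd = NULL,
                seg_w = p$seg_w * 0, seg_b = 0,
                em_W = p$em_W * 0, em_b = p$em_b * 0,
                trans_w = b_eff * d_tr, trans_b = b_eff * d_tr)

  dENC <- vector("list", T_max)
  for (t in steps) {
    dl <- a_eff * PL[[t]]
    dem <- b_eff * dEM[[t]]
    grads$seg_w <- grads$seg_w + colSums(ENC[[t]] * dl)
    grads$seg_b <- grads$seg_b + sum(dl)
    grads$em_W <- grads$em_W + crossprod(dem, ENC[[t]])
    grads$em_b <- grads$em_b + colSums(dem)
    denc <- outer(dl, p$seg_w) + dem %*% p$em_W
    if (!is.null(DMe[[t]])) denc <- denc * DMe[[t]]
    dENC[[t]] <- denc
  }

  dHf <- lapply(dENC, function(x) x[, seq_len(H), drop = FALSE])
  dHb <- lapply(dENC, function(x) x[, H + seq_len(H), drop = FALSE])
  back_f <- lstm_backward_batch(p$fwd, X, fw$cache, dHf, steps)
  back_b <- lstm_backward_batch(p$bwd, X, bw$cache, dHb, rev(steps))
  grads$fwd <- back_f$grads
  grads$bwd <- back_b$grads

  for (t in steps) {
    dx <- back_f$dX[[t]] + back_b$dX[[t]]
    if (!is.null(DMx[[t]])) dx <- dx * DMx[[t]]
    dc <- dx[, seq_len(cd), drop = FALSE]
    dr <- dx[, cd + seq_len(rd), drop = FALSE]
    rc <- rowsum(dc, CI[, t])
    grads$E_char[as.integer(rownames(rc)), ] <-
      grads$E_char[as.integer(rownames(rc)), ] + rc
    rr <- rowsum(dr, RI[, t] + 1L)
    grads$E_rad[as.integer(rownames(rr)), ] <-
      grads$E_rad[as.integer(rownames(rr)), ] + rr
  }

  list(loss = loss, loss1 = loss1, loss2 = loss2, grads = grads)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  keys <- param_keys(params)
  state <- list(t = 0L, m = list(), v = list())
  for (k in keys) {
    z <- get_param(params, k) * 0
    state$m[[k]] <- z
    state$v[[k]] <- z
  }
  state
}

adam_update <- function(params, grads, state, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in param_keys(params)) {
    g <- get_param(grads, k)
    m <- beta1 * state$m[[k]] + (1 - beta1) * g
    v <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    state$m[[k]] <- m
    state$v[[k]] <- v
    step <- lr * (m / bc1) / (sqrt(v / bc2) + eps)
    params <- set_param(params, k, get_param(params, k) - step)
  }
  list(params = params, state = state)
}
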