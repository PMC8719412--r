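zero_lstm <- function(input_dim, hidden) {
  p <- lstm_params(input_dim, hidden)
  for (nm in c("W_xi", "W_hi", "W_xf", "W_hf", "W_xc", "W_hc", "W_xo", "W_ho"))
    p[[nm]] <- p[[nm]] * 0
  for (nm in c("b_i", "b_f", "b_c", "b_o")) p[[nm]] <- p[[nm]] * 0
  p
}

test_that("lstm_step with zero parameters reduces to analytic gate values", {
  p <- zero_lstm(3L, 2L)
  st <- lstm_step(c(1, -1, 2), c(0, 0), c(0, 0), p)
  expect_equal(st$c, c(0, 0))
  expect_equal(st$h, c(0, 0))
  # gates are all 0.5, tanh branch 0: c_t = 0.5 * c_prev
  cp <- c(0.8, -1.2)
  st2 <- lstm_step(c(1, -1, 2), c(0, 0), cp, p)
  expect_equal(st2$c, 0.5 * cp)
  expect_equal(st2$h, 0.5 * tanh(0.5 * cp))
})

test_that("lstm_step matches an independent scalar transcription of the cell", {
  set.seed(53)
  for (rep in 1:10) {
    p <- lstm_params(1L, 1L)
    for (nm in c("W_xi", "W_hi", "W_xf", "W_hf", "W_xc", "W_hc", "W_xo", "W_ho"))
      p[[nm]] <- matrix(rnorm(1), 1, 1)
    for (nm in c("b_i", "b_f", "b_c", "b_o")) p[[nm]] <- rnorm(1)
    x <- rnorm(1); h <- rnorm(1); cc <- rnorm(1)
    st <- lstm_step(x, h, cc, p)
    sig <- function(z) 1 / (1 + exp(-z))
    i <- sig(p$W_xi[1] * x + p$W_hi[1] * h + p$b_i)
    f <- sig(p$W_xf[1] * x + p$W_hf[1] * h + p$b_f)
    ct <- f * cc + i * tanh(p$W_xc[1] * x + p$W_hc[1] * h + p$b_c)
    o <- sig(p$W_xo[1] * x + p$W_ho[1] * h + p$b_o)
    expect_equal(st$c, ct, tolerance = 1e-10)
    expect_equal(st$h, o * tanh(ct), tolerance = 1e-10)
  }
})

test_that("bilstm_encode concatenates directions and respects sequence reversal", {
  ts <- tiny_setup()
  model <- ts$model
  H <- model$dims$hidden_size
  X <- matrix(rnorm(5 * model$dims$input_dim), 5)
  enc <- bilstm_encode(X, model)
  expect_equal(dim(enc), c(5L, 2L * H))

  # single position: both directions see one step
  enc1 <- bilstm_encode(X[1, , drop = FALSE], model)
  expect_equal(dim(enc1), c(1L, 2L * H))

  # swapping the direction parameters and reversing the input reverses and
  # swaps the two halves of the encoding
  swapped <- model
  swapped$params$fwd <- model$params$bwd
  swapped$params$bwd <- model$params$fwd
  enc_rev <- bilstm_encode(X[5:1, , drop = FALSE], swapped)
  expect_equal(enc_rev[5:1, c((H + 1):(2 * H), 1:H)], enc, tolerance = 1e-12)

  # zero-parameter model encodes everything to zero
  zp <- model
  zp$params$fwd <- zero_lstm(model$dims$input_dim, H)
  zp$params$bwd <- zero_lstm(model$dims$input_dim, H)
  expect_true(all(bilstm_encode(X, zp) == 0))
})

test_that("seg_forward is a sigmoid of a linear readout", {
  ts <- tiny_setup()
  model <- ts$model
  enc <- matrix(rnorm(6 * 2 * model$dims$hidden_size), 6)
  probs <- seg_forward(enc, model)
  expect_true(all(probs > 0 & probs < 1))
  expect_equal(probs,
               1 / (1 + exp(-(drop(enc %*% model$params$seg_w) +
                                model$params$seg_b))))
  zp <- model
  zp$params$seg_w <- model$params$seg_w * 0
  zp$params$seg_b <- 0
  expect_equal(seg_forward(enc, zp), rep(0.5, 6))
})

test_that("seg_bce_loss matches the hand-summed cross entropy and its limits", {
  y <- c(1L, 0L, 1L, 0L)
  expect_equal(seg_bce_loss(c(1, 0, 1, 0), y), 0, tolerance = 1e-9)
  expect_equal(seg_bce_loss(rep(0.5, 4), y), 4 * log(2))
  # padding is excluded
  expect_equal(seg_bce_loss(rep(0.5, 4), y, mask = c(1, 1, 0, 0)), 2 * log(2))
  set.seed(59)
  for (rep in 1:20) {
    n <- sample(1:10, 1)
    q <- runif(n, 0.01, 0.99)
    y <- rbinom(n, 1, 0.5)
    m <- rbinom(n, 1, 0.8)
    hand <- -sum((y * log(q) + (1 - y) * log(1 - q))[m == 1])
    expect_equal(seg_bce_loss(q, y, m), hand, tolerance = 1e-12)
  }
  expect_error(seg_bce_loss(c(0.5, 0.5), 1L), "align")
})

test_that("crf_score degenerate cases and enumeration-based probabilities", {
  set.seed(61)
  L <- 3L
  tr0 <- crf_params(L)
  em1 <- matrix(rnorm(L), 1, L)
  expect_equal(crf_score(em1, tr0, 2L), em1[1, 2])
  # all-zero parameters score every path 0
  em0 <- matrix(0, 3, L)
  expect_equal(crf_score(em0, tr0, c(1L, 3L, 2L)), 0)
  expect_error(crf_score(em1, tr0, 5L), "out of range")

  # exp(score) / partition is a proper path probability
  inst <- rand_crf_instance()
  all_paths <- enumerate_crf_scores(inst$emissions, inst$transitions)
  logZ <- crf_log_partition(inst$emissions, inst$transitions)
  probs <- exp(all_paths$scores - logZ)
  expect_equal(sum(probs), 1, tolerance = 1e-8)
  j <- sample.int(nrow(all_paths$paths), 1)
  expect_equal(exp(crf_score(inst$emissions, inst$transitions,
                             all_paths$paths[j, ]) - logZ),
               probs[j], tolerance = 1e-10)
})

test_that("forward-algorithm partition matches brute-force enumeration", {
  set.seed(67)
  L <- 4L
  em <- matrix(rnorm(L), 1, L)
  expect_equal(crf_log_partition(em, crf_params(L)),
               log(sum(exp(em))), tolerance = 1e-12)
  # all-zero scores: L^n equally weighted paths
  expect_equal(crf_log_partition(matrix(0, 3, L), crf_params(L)), 3 * log(L))
  for (rep in 1:50) {
    inst <- rand_crf_instance()
    enum <- enumerate_crf_scores(inst$emissions, inst$transitions)
    m <- max(enum$scores)
    expect_equal(crf_log_partition(inst$emissions, inst$transitions),
                 m + log(sum(exp(enum$scores - m))), tolerance = 1e-8)
  }
})

test_that("crf_nll is a proper negative log-probability", {
  set.seed(71)
  # single-label inventory: only one path, loss exactly 0
  em <- matrix(rnorm(4), 4, 1)
  expect_equal(crf_nll(em, crf_params(1L), rep(1L, 4)), 0, tolerance = 1e-12)
  for (rep in 1:20) {
    inst <- rand_crf_instance()
    n <- nrow(inst$emissions); L <- ncol(inst$emissions)
    gold <- sample.int(L, n, replace = TRUE)
    nll <- crf_nll(inst$emissions, inst$transitions, gold)
    expect_gte(nll, -1e-10)
    enum <- enumerate_crf_scores(inst$emissions, inst$transitions)
    logZ <- max(enum$scores) + log(sum(exp(enum$scores - max(enum$scores))))
    gold_score <- crf_score(inst$emissions, inst$transitions, gold)
    expect_equal(nll, logZ - gold_score, tolerance = 1e-8)
  }
})

test_that("viterbi_decode returns the enumeration maximum with consistent score", {
  set.seed(73)
  em <- matrix(rnorm(3), 1, 3)
  v <- viterbi_decode(em, crf_params(3L))
  expect_equal(v$path, which.max(em))
  for (rep in 1:50) {
    n <- sample.int(5L, 1L); L <- sample.int(4L, 1L)
    inst <- list(emissions = matrix(rnorm(n * L, sd = 2), n, L),
                 transitions = crf_params(L,
                                          matrix(rnorm((L + 1) * L), L + 1, L)))
    v <- viterbi_decode(inst$emissions, inst$transitions)
    enum <- enumerate_crf_scores(inst$emissions, inst$transitions)
    expect_equal(v$score, max(enum$scores), tolerance = 1e-10)
    expect_equal(crf_score(inst$emissions, inst$transitions, v$path), v$score,
                 tolerance = 1e-10)
    expect_lte(v$score,
               crf_log_partition(inst$emissions, inst$transitions) + 1e-10)
  }
})

test_that("viterbi path is invariant to a constant added to one position's emissions", {
  set.seed(79)
  inst <- list(emissions = matrix(rnorm(12), 4, 3),
               transitions = crf_params(3L, matrix(rnorm(12), 4, 3)))
  v1 <- viterbi_decode(inst$emissions, inst$transitions)
  shifted <- inst$emissions
  shifted[2, ] <- shifted[2, ] + 7.3
  v2 <- viterbi_decode(shifted, inst$transitions)
  expect_identical(v1$path, v2$path)
  expect_equal(v2$score, v1$score + 7.3, tolerance = 1e-10)
})

test_that("combined_loss is the weighted sum with the 2:3 default and is linear", {
  w <- loss_weights()
  expect_equal(w$alpha, 0.4)
  expect_equal(w$beta, 0.6)
  expect_equal(combined_loss(5, 10, w), 0.4 * 5 + 0.6 * 10)
  expect_equal(combined_loss(3, 7, loss_weights(alpha = 0, beta = 1)), 7)
  set.seed(83)
  a <- runif(1, 0.1, 2); b <- runif(1, 0.1, 2)
  w2 <- loss_weights(a, b)
  l1 <- runif(2, 0, 5); l2 <- runif(2, 0, 5)
  expect_equal(combined_loss(l1[1] + l1[2], l2[1] + l2[2], w2),
               combined_loss(l1[1], l2[1], w2) + combined_loss(l1[2], l2[2], w2),
               tolerance = 1e-12)
  expect_error(loss_weights(0, 0), "alpha")
  expect_error(combined_loss(Inf, 1), "finite")
})

test_that("analytic gradients of the joint loss match finite differences", {
  ts <- tiny_setup()
  model <- ts$model
  prepped <- lapply(ts$syn$train$sentences,
                    function(s) dictagger:::prep_sentence(model, s))
  w <- loss_weights(0.4, 0.6)
  idx <- 1:4
  res <- dictagger:::batch_pass(model, prepped, idx, w, dropout = 0,
                                compute_grads = TRUE)
  eps <- 1e-6
  set.seed(89)
  loss_at <- function(params) {
    m <- model; m$params <- params
    dictagger:::batch_pass(m, prepped, idx, w, dropout = 0,
                           compute_grads = FALSE)$loss
  }
  for (k in dictagger:::param_keys(model$params)) {
    p0 <- dictagger:::get_param(model$params, k)
    g <- dictagger:::get_param(res$grads, k)
    for (j in sample(length(p0), min(3L, length(p0)))) {
      pp <- p0; pp[j] <- pp[j] + eps
      pm <- p0; pm[j] <- pm[j] - eps
      num <- (loss_at(dictagger:::set_param(model$params, k, pp)) -
                loss_at(dictagger:::set_param(model$params, k, pm))) / (2 * eps)
      expect_equal(g[j], num, tolerance = 1e-4,
                   label = sprintf("analytic gradient of %s[%d]", k, j))
    }
  }
})

test_that("the CRF head's loss and gradients ignore the segmentation head's parameters", {
  ts <- tiny_setup()
  model <- ts$model
  prepped <- lapply(ts$syn$train$sentences,
                    function(s) dictagger:::prep_sentence(model, s))
  w <- loss_weights(0.4, 0.6)
  r1 <- dictagger:::batch_pass(model, prepped, 1:4, w, dropout = 0)
  perturbed <- model
  perturbed$params$seg_w <- model$params$seg_w + rnorm(length(model$params$seg_w))
  perturbed$params$seg_b <- model$params$seg_b + 1
  r2 <- dictagger:::batch_pass(perturbed, prepped, 1:4, w, dropout = 0)
  expect_equal(r1$loss2, r2$loss2, tolerance = 1e-12)   # CRF loss untouched
  # with alpha = 0 every non-seg gradient is independent of the seg head
  w0 <- loss_weights(0, 1)
  g1 <- dictagger:::batch_pass(model, prepped, 1:4, w0, dropout = 0)$grads
  g2 <- dictagger:::batch_pass(perturbed, prepped, 1:4, w0, dropout = 0)$grads
  for (k in setdiff(dictagger:::param_keys(model$params), c("seg_w", "seg_b")))
    expect_equal(dictagger:::get_param(g1, k), dictagger:::get_param(g2, k),
                 tolerance = 1e-12)
  expect_true(all(g1$seg_w == 0) && g1$seg_b == 0)
})
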