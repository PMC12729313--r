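test_that("input projection matches an affine+ReLU oracle", {
  set.seed(21)
  B <- 3; T <- 4; D <- 5; d_h <- 6
  X <- array(rnorm(B * T * D), c(B, T, D))
  W <- matrix(rnorm(D * d_h), D, d_h)
  b <- rnorm(d_h)
  H <- input_projection(X, W, b)
  expect_true(all(H >= 0))
  for (i in seq_len(B)) {
    for (t in seq_len(T)) {
      expect_equal(H[i, t, ], pmax(as.vector(X[i, t, ] %*% W) + b, 0),
                   tolerance = 1e-10)
    }
  }
  expect_equal(max(abs(input_projection(X, 0 * W, 0 * b))), 0)
  expect_equal(max(abs(input_projection(X, W, b - 100))), 0)
})

test_that("LSTM cell implements the six gate equations", {
  set.seed(22)
  d_h <- 4; d_in <- 3; B <- 2
  mkw <- function() {
    fan <- d_h + d_in
    list(W_f = matrix(rnorm(fan * d_h), fan, d_h),
         W_i = matrix(rnorm(fan * d_h), fan, d_h),
         W_C = matrix(rnorm(fan * d_h), fan, d_h),
         W_o = matrix(rnorm(fan * d_h), fan, d_h),
         b_f = rnorm(d_h), b_i = rnorm(d_h), b_C = rnorm(d_h),
         b_o = rnorm(d_h))
  }
  w <- mkw()
  x <- matrix(rnorm(B * d_in), B, d_in)
  st0 <- list(h = matrix(rnorm(B * d_h), B, d_h),
              C = matrix(rnorm(B * d_h), B, d_h))
  st <- lstm_cell_step(x, st0, w)
  for (i in seq_len(B)) {
    o <- oracle_lstm_cell(x[i, ], st0$h[i, ], st0$C[i, ], w)
    expect_equal(st$h[i, ], o$h, tolerance = 1e-6)
    expect_equal(st$C[i, ], o$C, tolerance = 1e-6)
  }
  # gate boundedness for arbitrary finite inputs
  expect_true(all(st$f > 0 & st$f < 1))
  expect_true(all(st$i > 0 & st$i < 1))
  expect_true(all(st$o > 0 & st$o < 1))
  expect_true(all(abs(st$Ctil) < 1))

  # all-zero weights: sigma(0) = 0.5, tanh(0) = 0 => candidate 0, h = C = 0
  zw <- lapply(w, function(m) m * 0)
  z <- lstm_cell_step(x, list(h = matrix(0, B, d_h), C = matrix(0, B, d_h)),
                      zw)
  expect_equal(max(abs(z$h)), 0)
  expect_equal(max(abs(z$C)), 0)

  # saturated forget gate with closed input gate: perfect memory
  mem <- zw
  mem$b_f <- rep(50, d_h)
  mem$b_i <- rep(-50, d_h)
  C_prev <- matrix(rnorm(B * d_h), B, d_h)
  m <- lstm_cell_step(x, list(h = matrix(0, B, d_h), C = C_prev), mem)
  expect_equal(m$C, C_prev, tolerance = 1e-8)

  expect_error(lstm_cell_step(x * NA, st0, w), "non-finite")
})

test_that("BiLSTM concatenates directions and is time-symmetric", {
  set.seed(23)
  hp <- tiny_hp(d_h = 3L)
  B <- 2; T <- 5; d_h <- 3
  params <- init_network(hp, D = 4, G = 2, seed = 5)
  # give both directions the same weights: forward on reversed input must
  # equal time-reversed backward output
  layer <- params$lstm[[1]]
  layer$bwd <- layer$fwd
  H <- array(rnorm(B * T * d_h), c(B, T, d_h))
  out <- bilstm_forward(H, list(layer))
  Hrev <- H[, T:1, , drop = FALSE]
  out_rev <- bilstm_forward(Hrev, list(layer))
  expect_equal(out_rev[, T:1, seq_len(d_h)], out[, , d_h + seq_len(d_h)],
               tolerance = 1e-10)
  # T = 1: both halves come from the same single step
  H1 <- H[, 1, , drop = FALSE]
  o1 <- bilstm_forward(H1, list(layer))
  expect_equal(o1[, 1, seq_len(d_h)], o1[, 1, d_h + seq_len(d_h)],
               tolerance = 1e-12)
  # eval-mode determinism
  expect_identical(bilstm_forward(H, list(layer)), out)
})

test_that("attention head: softmax weights over the mask only", {
  set.seed(24)
  B <- 3; T <- 6; w <- 4; d_a <- 5
  H <- array(rnorm(B * T * w), c(B, T, w))
  head <- list(W_a = matrix(rnorm(w * d_a), w, d_a), b_a = rnorm(d_a),
               v_a = rnorm(d_a))
  mask <- c(2L, 4L, 5L)
  res <- attention_head(H, head, mask)
  expect_equal(rowSums(res$weights), rep(1, B), tolerance = 1e-6)
  for (i in seq_len(B)) {
    o <- oracle_attention_head(H[i, , ], head$W_a, head$b_a, head$v_a, mask,
                               d_a)
    expect_equal(res$context[i, ], o$context, tolerance = 1e-6)
    expect_equal(res$weights[i, ], o$weights, tolerance = 1e-6)
  }
  # single-step mask returns that step with weight 1
  one <- attention_head(H, head, 3L)
  expect_equal(one$context, matrix(H[, 3, ], B), tolerance = 1e-12)
  expect_equal(as.vector(one$weights), rep(1, B))
  # identical hidden states -> uniform weights
  Hc <- H
  for (t in seq_len(T)) Hc[, t, ] <- H[, 1, ]
  unif <- attention_head(Hc, head, mask)
  expect_equal(unname(unif$weights), matrix(1 / 3, B, 3), tolerance = 1e-9)
  expect_error(attention_head(H, head, integer(0)), "no steps")
})

test_that("multi-scale attention: width, masking locality, head symmetry", {
  set.seed(25)
  hp <- hyperparameters(d_h = 4L, heads_per_scale = 4L,
                        scales = list(c(1, 3), c(3, 6), c(6, 10)))
  params <- init_network(hp, D = 6, G = 2, seed = 1)
  B <- 2; T <- 10; w <- 8
  H <- array(rnorm(B * T * w), c(B, T, w))
  C <- multi_scale_attention(H, params$attention, hp$scales, hp$d_a)
  expect_equal(ncol(C), 3L * 2L * 4L)
  # with d_h = 64 the width is 384
  expect_equal(3L * 2L * 64L, 384L)

  # scales covering lags 1-3 only of a T=5 window leave steps 1..2 unread
  hp2 <- hyperparameters(d_h = 4L, heads_per_scale = 2L,
                         scales = list(c(1, 2), c(1, 3)))
  p2 <- init_network(hp2, D = 6, G = 2, seed = 2)
  H5 <- array(rnorm(B * 5 * w), c(B, 5, w))
  C0 <- multi_scale_attention(H5, p2$attention, hp2$scales, hp2$d_a)
  H5p <- H5
  H5p[, 1:2, ] <- H5p[, 1:2, ] + 100
  expect_equal(multi_scale_attention(H5p, p2$attention, hp2$scales, hp2$d_a),
               C0, tolerance = 1e-9)
  # perturbing a masked step does change the context
  H5q <- H5
  H5q[, 5, ] <- H5q[, 5, ] + 1
  expect_gt(max(abs(multi_scale_attention(H5q, p2$attention, hp2$scales,
                                          hp2$d_a) - C0)), 1e-6)

  # identical head parameters -> identical head contexts within the scale
  att <- params$attention
  for (h in 2:4) att[[1]]$heads[[h]] <- att[[1]]$heads[[1]]
  res <- asircast:::multi_scale_attention_cached(H, att, hp$scales, hp$d_a)
  ctxs <- lapply(res$scales_cache[[1]]$heads, `[[`, "context")
  for (h in 2:4) expect_equal(ctxs[[h]], ctxs[[1]], tolerance = 1e-12)
})

test_that("group heads run G independent affine maps off a shared layer", {
  set.seed(26)
  B <- 4; aw <- 6; d_sh <- 5; G <- 3
  shared <- list(W = matrix(rnorm(aw * d_sh), aw, d_sh), b = rnorm(d_sh))
  heads <- list(W = matrix(rnorm(d_sh * G), d_sh, G), b = rnorm(G))
  Ca <- matrix(rnorm(B * aw), B, aw)
  gh <- group_heads(Ca, shared, heads)
  Hsh <- pmax(Ca %*% shared$W + matrix(shared$b, B, d_sh, byrow = TRUE), 0)
  for (g in seq_len(G)) {
    expect_equal(gh$yhat[, g],
                 as.vector(Hsh %*% heads$W[, g]) + heads$b[g],
                 tolerance = 1e-10)
  }
  # zero weights -> bias; duplicated head weights -> identical predictions
  h0 <- heads
  h0$W[] <- 0
  expect_equal(group_heads(Ca, shared, h0)$yhat,
               matrix(h0$b, B, G, byrow = TRUE), ignore_attr = TRUE)
  h2 <- heads
  h2$W[, 2] <- h2$W[, 1]
  h2$b[2] <- h2$b[1]
  gh2 <- group_heads(Ca, shared, h2)
  expect_equal(gh2$yhat[, 1], gh2$yhat[, 2])
})

test_that("residual fusion obeys the alpha limits", {
  set.seed(27)
  B <- 3; T <- 4; D <- 5; G <- 2
  X <- array(rnorm(B * T * D), c(B, T, D))
  yd <- matrix(rnorm(B * G), B, G)
  Wr <- matrix(rnorm(D * G), D, G)
  expect_equal(residual_fusion(X, yd, Wr, 1)$yhat, yd)
  r0 <- residual_fusion(X, yd, Wr, 0)
  expect_equal(r0$yhat, r0$X_avg %*% Wr)
  # constant-in-time input: X_avg equals the constant vector
  Xc <- X
  for (t in seq_len(T)) Xc[, t, ] <- X[, 1, ]
  expect_equal(residual_fusion(Xc, yd, Wr, 0.3)$X_avg, matrix(X[, 1, ], B),
               tolerance = 1e-12)
})

test_that("ensemble prediction is the unweighted member mean", {
  pf <- function(m, X) matrix(m, 2, 3)
  expect_equal(ensemble_predict(list(0, 1, 2), NULL, pf), matrix(1, 2, 3))
  expect_equal(ensemble_predict(list(5), NULL, pf), matrix(5, 2, 3))
  expect_error(ensemble_predict(list(), NULL, pf), "empty")
})

test_that("vectorized model matches the scalar full-equation oracle", {
  set.seed(28)
  hp <- tiny_hp()
  T <- 3; D <- 6; G <- 2
  params <- init_network(hp, D, G, seed = 9)
  X <- array(rnorm(2 * T * D), c(2, T, D))
  fw <- network_forward(params, hp, X)
  for (i in 1:2) {
    o <- oracle_full_forward(matrix(X[i, , ], T, D), params, hp, T, D, G)
    expect_equal(fw$yhat[i, ], o, tolerance = 1e-5)
  }
})

test_that("analytic gradients agree with central differences", {
  set.seed(29)
  hp <- hyperparameters(d_h = 3L, n_lstm_layers = 2L, dropout = 0,
                        heads_per_scale = 2L, scales = list(c(1, 2), c(2, 4)),
                        d_a = 3L, d_shared = 4L, use_batchnorm = TRUE)
  B <- 3; T <- 4; D <- 5; G <- 2
  X <- array(rnorm(B * T * D), c(B, T, D))
  Y <- matrix(rnorm(B * G), B, G)
  params <- init_network(hp, D, G, seed = 31)
  loss_fn <- function(pp) {
    mean((network_forward(pp, hp, X, training = TRUE)$yhat - Y)^2)
  }
  fw <- network_forward(params, hp, X, training = TRUE, keep_cache = TRUE)
  dY <- 2 * (fw$yhat - Y) / length(Y)
  bw <- network_backward(params, hp, fw$cache, dY)
  flat <- asircast:::flatten_params(params)
  g <- asircast:::flatten_params(bw$grads)$vec
  eps <- 1e-6
  num <- vapply(seq_along(flat$vec), function(i) {
    v1 <- flat$vec; v1[i] <- v1[i] + eps
    v2 <- flat$vec; v2[i] <- v2[i] - eps
    (loss_fn(asircast:::unflatten_params(params, flat, v1)) -
       loss_fn(asircast:::unflatten_params(params, flat, v2))) / (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(num - g)), 1e-4)
  # input gradients (consumed by the SHAP explainer)
  numx <- array(0, dim(X))
  for (i in seq_along(X)) {
    X1 <- X; X1[i] <- X1[i] + eps
    X2 <- X; X2[i] <- X2[i] - eps
    f1 <- mean((network_forward(params, hp, X1, training = TRUE)$yhat - Y)^2)
    f2 <- mean((network_forward(params, hp, X2, training = TRUE)$yhat - Y)^2)
    numx[i] <- (f1 - f2) / (2 * eps)
  }
  expect_lt(max(abs(numx - bw$dX)), 1e-4)
})

test_that("a least-squares residual pathway alone solves linear panels", {
  fx <- std_split(seed = 7, trend = "linear", noise_sd = 0)
  Xtr <- apply(fx$train$inputs, c(1, 3), mean)
  Xte <- apply(fx$test$inputs, c(1, 3), mean)
  W <- pinv_solve(Xtr, fx$train$targets)
  pred <- Xte %*% W
  r2 <- 1 - sum((fx$test$targets - pred)^2) /
    sum((fx$test$targets - mean(fx$test$targets))^2)
  expect_gte(r2, 0.99)
})
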