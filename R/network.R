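#' Network hyperparameters
#'
#' The tunable configuration of the dual-pathway forecaster. Defaults are the
#' optimum reported for the method: hidden width 64, two BiLSTM layers,
#' dropout 0.15, learning rate 0.002, four attention heads per scale, and
#' three temporal scales covering short (lags 1-3), medium (lags 3-6) and
#' long (lags 6-10) ranges counted back from the most recent window step.
#'
#' @param d_h hidden width per LSTM direction.
#' @param n_lstm_layers number of stacked (Bi)LSTM layers.
#' @param dropout inter-layer dropout fraction in `[0, 1)`.
#' @param learning_rate Adam step size.
#' @param heads_per_scale attention heads within each scale.
#' @param d_a attention projection width (defaults to `d_h`); the softmax
#'   scaling factor d_k equals `d_a`.
#' @param scales list of `c(lag_min, lag_max)` pairs; lag 1 is the most
#'   recent step of the input window.
#' @param ensemble_size number of ensemble members (distinct init seeds).
#' @param d_shared width of the shared pre-head layer (defaults to `d_h`).
#' @param bidirectional run a backward LSTM pass and concatenate (TRUE for
#'   the full model; FALSE gives the unidirectional ablation).
#' @param attention use multi-scale attention (FALSE routes the last time
#'   step's hidden state directly to the shared layer).
#' @param use_batchnorm batch-normalize the input projection.
#' @return an object of class `asir_hyperparameters`.
#' @export
hyperparameters <- function(d_h = 64L, n_lstm_layers = 2L, dropout = 0.15,
                            learning_rate = 0.002, heads_per_scale = 4L,
                            d_a = NULL,
                            scales = list(c(1, 3), c(3, 6), c(6, 10)),
                            ensemble_size = 3L, d_shared = NULL,
                            bidirectional = TRUE, attention = TRUE,
                            use_batchnorm = TRUE) {
  if (dropout < 0 || dropout >= 1) abort_validation("dropout must be in [0, 1)")
  if (d_h < 1) abort_validation("d_h must be >= 1")
  structure(list(
    d_h = as.integer(d_h), n_lstm_layers = as.integer(n_lstm_layers),
    dropout = dropout, learning_rate = learning_rate,
    heads_per_scale = as.integer(heads_per_scale),
    d_a = as.integer(d_a %||% d_h), scales = scales,
    ensemble_size = as.integer(ensemble_size),
    d_shared = as.integer(d_shared %||% d_h),
    bidirectional = isTRUE(bidirectional), attention = isTRUE(attention),
    use_batchnorm = isTRUE(use_batchnorm)
  ), class = "asir_hyperparameters")
}

# Time indices (ascending) selected by a lag-range scale for window length T.
# Lag 1 is the last step, so lag l maps to index T + 1 - l.
scale_mask <- function(scale, T) {
  if (scale[1] < 1 || scale[2] > T || scale[1] > scale[2]) {
    abort_validation("scale (", scale[1], ",", scale[2],
                     ") must lie within [1, ", T, "]")
  }
  sort(T + 1L - seq.int(scale[1], scale[2]))
}

unif_init <- function(nr, nc, fan_in) {
  lim <- 1 / sqrt(fan_in)
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Initialize network parameters
#'
#' Standard uniform fan-in initialization, seeded; the LSTM forget-gate bias
#' starts at 1 (common practice so cells remember by default) and the fusion
#' weight alpha starts at 0.5 (logit 0).
#'
#' @param hp an [hyperparameters()] object.
#' @param D input feature dimension.
#' @param G number of output groups.
#' @param seed integer seed.
#' @return a nested parameter list of class `asir_network_params`.
#' @export
init_network <- function(hp, D, G, seed = 1L) {
  with_seed(seed, {
    d_h <- hp$d_h
    ndir <- if (hp$bidirectional) 2L else 1L
    w_seq <- ndir * d_h                      # width of the LSTM output per step
    params <- list()
    params$input <- list(W = unif_init(D, d_h, D), b = numeric(d_h),
                         gamma = rep(1, d_h), beta = numeric(d_h),
                         running_mean = numeric(d_h), running_var = rep(1, d_h))
    params$lstm <- vector("list", hp$n_lstm_layers)
    for (l in seq_len(hp$n_lstm_layers)) {
      d_in <- if (l == 1L) d_h else w_seq
      mk_dir <- function() {
        fan <- d_in + d_h
        list(W_f = unif_init(fan, d_h, fan), W_i = unif_init(fan, d_h, fan),
             W_C = unif_init(fan, d_h, fan), W_o = unif_init(fan, d_h, fan),
             b_f = rep(1, d_h), b_i = numeric(d_h),
             b_C = numeric(d_h), b_o = numeric(d_h))
      }
      params$lstm[[l]] <- if (hp$bidirectional) list(fwd = mk_dir(), bwd = mk_dir())
                          else list(fwd = mk_dir())
    }
    att_width <- if (hp$attention) length(hp$scales) * w_seq else w_seq
    if (hp$attention) {
      params$attention <- lapply(seq_along(hp$scales), function(s) {
        heads <- lapply(seq_len(hp$heads_per_scale), function(h) {
          list(W_a = unif_init(w_seq, hp$d_a, w_seq), b_a = numeric(hp$d_a),
               v_a = stats::runif(hp$d_a, -1 / sqrt(hp$d_a), 1 / sqrt(hp$d_a)))
        })
        list(heads = heads,
             W_proj = unif_init(hp$heads_per_scale * w_seq, w_seq,
                                hp$heads_per_scale * w_seq),
             b_proj = numeric(w_seq))
      })
    }
    params$shared <- list(W = unif_init(att_width, hp$d_shared, att_width),
                          b = numeric(hp$d_shared))
    params$heads <- list(W = unif_init(hp$d_shared, G, hp$d_shared),
                         b = numeric(G))
    params$residual <- list(W = unif_init(D, G, D))
    params$alpha_logit <- 0
    structure(params, class = "asir_network_params",
              dims = list(D = D, G = G, w_seq = w_seq, att_width = att_width))
  })
}

add_bias <- function(M, b) sweep(M, 2, b, "+")

#' Input projection layer
#'
#' Per-timestep affine map of the raw features into hidden space, optionally
#' batch-normalized over the flattened (batch x time) axis, then ReLU.
#'
#' @param X input array B x T x D.
#' @param W,b projection weight (D x d_h) and bias.
#' @param batchnorm `NULL` to disable, otherwise a list with `gamma`, `beta`,
#'   `running_mean`, `running_var`.
#' @param training use batch statistics (TRUE) or running statistics.
#' @return hidden array B x T x d_h with all entries >= 0.
#' @export
input_projection <- function(X, W, b, batchnorm = NULL, training = FALSE) {
  ip <- list(W = W, b = b)
  if (!is.null(batchnorm)) ip <- c(ip, batchnorm)
  proj_forward(X, ip, use_bn = !is.null(batchnorm), training = training)$H
}

proj_forward <- function(X, ip, use_bn, training, bn_momentum = 0.1,
                         bn_eps = 1e-5) {
  dms <- dim(X)
  B <- dms[1]; T <- dms[2]; D <- dms[3]
  d_h <- ncol(ip$W)
  Xmat <- array(aperm(X, c(1, 2, 3)), c(B * T, D))  # rows: (b, t) pairs
  Z <- add_bias(Xmat %*% ip$W, ip$b)
  cache <- list(Xmat = Xmat, use_bn = use_bn, training = training, B = B,
                T = T)
  if (use_bn) {
    if (training) {
      mu <- colMeans(Z)
      v <- colMeans(sweep(Z, 2, mu)^2)
      ip$running_mean <- (1 - bn_momentum) * ip$running_mean + bn_momentum * mu
      ip$running_var <- (1 - bn_momentum) * ip$running_var + bn_momentum * v
    } else {
      mu <- ip$running_mean
      v <- ip$running_var
    }
    invstd <- 1 / sqrt(v + bn_eps)
    Zn <- sweep(sweep(Z, 2, mu), 2, invstd, "*")
    Zb <- add_bias(sweep(Zn, 2, ip$gamma, "*"), ip$beta)
    cache$Zn <- Zn; cache$invstd <- invstd; cache$gamma <- ip$gamma
  } else {
    Zb <- Z
  }
  A <- relu(Zb)
  cache$relu_mask <- Zb > 0
  list(H = array(A, c(B, T, d_h)), cache = cache, updated_input = ip)
}

#' One LSTM cell step
#'
#' Applies the forget, input and output gates and the cell update to a batch:
#' `f = sigma(W_f [h, x] + b_f)`, `i = sigma(W_i [h, x] + b_i)`,
#' `Ctil = tanh(W_C [h, x] + b_C)`, `C' = f * C + i * Ctil`,
#' `o = sigma(W_o [h, x] + b_o)`, `h' = o * tanh(C')`.
#'
#' @param x_t input at this step, B x d_in.
#' @param state list with `h` and `C`, each B x d_h.
#' @param weights list with `W_f, W_i, W_C, W_o` (each `(d_h + d_in) x d_h`,
#'   acting on the concatenation `[h, x]`) and biases `b_f, b_i, b_C, b_o`.
#' @return list with the new `h`, `C` and the gate activations
#'   `f`, `i`, `Ctil`, `o`.
#' @export
lstm_cell_step <- function(x_t, state, weights) {
  if (any(!is.finite(x_t))) abort_validation("non-finite LSTM input")
  HX <- cbind(state$h, x_t)
  f <- sigmoid(add_bias(HX %*% weights$W_f, weights$b_f))
  i <- sigmoid(add_bias(HX %*% weights$W_i, weights$b_i))
  Ctil <- tanh(add_bias(HX %*% weights$W_C, weights$b_C))
  C <- f * state$C + i * Ctil
  o <- sigmoid(add_bias(HX %*% weights$W_o, weights$b_o))
  tanhC <- tanh(C)
  h <- o * tanhC
  list(h = h, C = C, f = f, i = i, Ctil = Ctil, o = o, tanhC = tanhC, HX = HX)
}

# One direction of one LSTM layer over the full sequence.
# order: increasing t for the forward direction, decreasing for backward.
lstm_dir_forward <- function(I, weights, order) {
  B <- dim(I)[1]; T <- dim(I)[2]; d_h <- ncol(weights$W_f)
  h <- matrix(0, B, d_h); C <- matrix(0, B, d_h)
  H <- array(0, c(B, T, d_h))
  steps <- vector("list", T)
  for (t in order) {
    st <- lstm_cell_step(slice3(I, t), list(h = h, C = C), weights)
    st$C_prev <- C
    H[, t, ] <- st$h
    steps[[t]] <- st
    h <- st$h; C <- st$C
  }
  list(H = H, steps = steps)
}

#' Stacked (Bi)LSTM forward pass
#'
#' Runs each layer's chronological pass (and, when bidirectional, the
#' reversed pass) and concatenates the per-step hidden states. Inter-layer
#' dropout (inverted scaling) is active only in training mode.
#'
#' @param H input array B x T x d_h (output of [input_projection()]).
#' @param layers list of per-layer weights as built by [init_network()]
#'   (each element has `fwd` and optionally `bwd`).
#' @param dropout inter-layer dropout fraction.
#' @param training logical; enables dropout.
#' @return array B x T x (n_dir * d_h).
#' @export
bilstm_forward <- function(H, layers, dropout = 0, training = FALSE) {
  bilstm_forward_cached(H, layers, dropout, training)$H
}

bilstm_forward_cached <- function(H, layers, dropout = 0, training = FALSE) {
  B <- dim(H)[1]; T <- dim(H)[2]
  caches <- vector("list", length(layers))
  I <- H
  for (l in seq_along(layers)) {
    lw <- layers[[l]]
    fwd <- lstm_dir_forward(I, lw$fwd, seq_len(T))
    if (!is.null(lw$bwd)) {
      bwd <- lstm_dir_forward(I, lw$bwd, rev(seq_len(T)))
      O <- array(0, c(B, T, 2L * ncol(lw$fwd$W_f)))
      d_h <- ncol(lw$fwd$W_f)
      O[, , seq_len(d_h)] <- fwd$H
      O[, , d_h + seq_len(d_h)] <- bwd$H
    } else {
      bwd <- NULL
      O <- fwd$H
    }
    mask <- NULL
    if (training && dropout > 0 && l < length(layers)) {
      mask <- array(stats::rbinom(length(O), 1, 1 - dropout) / (1 - dropout),
                    dim(O))
      O <- O * mask
    }
    caches[[l]] <- list(fwd = fwd, bwd = bwd, mask = mask, input = I)
    I <- O
  }
  list(H = I, caches = caches)
}

#' Single attention head
#'
#' Scores each unmasked step with `s_t = tanh(W_a h_t + b_a)`, turns the
#' scaled projections `s_t . v_a / sqrt(d_k)` into softmax weights over the
#' unmasked steps only, and returns the weighted sum of hidden states.
#'
#' @param Hseq hidden sequence, B x T x w.
#' @param head list with `W_a` (w x d_a), `b_a`, `v_a`.
#' @param mask integer vector of time indices the head may attend to.
#' @param d_k softmax scaling factor (defaults to `length(v_a)`).
#' @return list with `context` (B x w) and `weights` (B x length(mask)).
#' @export
attention_head <- function(Hseq, head, mask, d_k = length(head$v_a)) {
  if (!length(mask)) abort_validation("attention mask selects no steps")
  B <- dim(Hseq)[1]; w <- dim(Hseq)[3]
  m <- length(mask)
  S <- array(0, c(B, m, length(head$v_a)))
  logits <- matrix(0, B, m)
  for (j in seq_len(m)) {
    Ht <- slice3(Hseq, mask[j])
    Sj <- tanh(add_bias(Ht %*% head$W_a, head$b_a))
    S[, j, ] <- Sj
    logits[, j] <- (Sj %*% head$v_a) / sqrt(d_k)
  }
  logits <- logits - apply(logits, 1, max)
  A <- exp(logits)
  A <- A / rowSums(A)
  context <- matrix(0, B, w)
  for (j in seq_len(m)) {
    context <- context + A[, j] * slice3(Hseq, mask[j])
  }
  list(context = context, weights = A, S = S)
}

#' Multi-scale multi-head attention
#'
#' Each scale restricts its heads to a lag range of the window; the heads'
#' contexts are concatenated and projected back to the sequence width, and
#' the per-scale contexts are concatenated into the attention summary.
#'
#' @param Hseq hidden sequence, B x T x w.
#' @param att per-scale parameter list from [init_network()].
#' @param scales list of `c(lag_min, lag_max)` pairs.
#' @param d_k softmax scaling factor.
#' @return matrix B x (length(scales) * w).
#' @export
multi_scale_attention <- function(Hseq, att, scales, d_k) {
  multi_scale_attention_cached(Hseq, att, scales, d_k)$C
}

multi_scale_attention_cached <- function(Hseq, att, scales, d_k) {
  B <- dim(Hseq)[1]; T <- dim(Hseq)[2]; w <- dim(Hseq)[3]
  sc <- vector("list", length(scales))
  C <- matrix(0, B, length(scales) * w)
  for (s in seq_along(scales)) {
    mask <- scale_mask(scales[[s]], T)
    heads <- lapply(att[[s]]$heads, function(hd)
      attention_head(Hseq, hd, mask, d_k))
    CH <- do.call(cbind, lapply(heads, `[[`, "context"))
    cs <- add_bias(CH %*% att[[s]]$W_proj, att[[s]]$b_proj)
    C[, (s - 1L) * w + seq_len(w)] <- cs
    sc[[s]] <- list(mask = mask, heads = heads, CH = CH)
  }
  list(C = C, scales_cache = sc)
}

#' Shared layer and group-specific output heads
#'
#' A shared ReLU transformation of the attention summary followed by one
#' independent affine head per population group, evaluated in parallel.
#'
#' @param C_att attention summary, B x att_width.
#' @param shared list with `W` (att_width x d_shared) and `b`.
#' @param heads list with `W` (d_shared x G: column g is group g's weight
#'   vector) and `b` (length G).
#' @return list with `yhat` (B x G) and the shared representation `Hsh`.
#' @export
group_heads <- function(C_att, shared, heads) {
  pre <- add_bias(C_att %*% shared$W, shared$b)
  Hsh <- relu(pre)
  yhat <- add_bias(Hsh %*% heads$W, heads$b)
  list(yhat = yhat, Hsh = Hsh, pre = pre)
}

#' Dual-pathway residual fusion
#'
#' Fuses the deep prediction with a linear projection of the time-averaged
#' input: `Y = alpha * y_deep + (1 - alpha) * (X_avg W_res)`. Both pathway
#' outputs are returned separately for component-contribution analysis.
#'
#' @param X input array B x T x D.
#' @param y_deep deep-pathway prediction, B x G.
#' @param W_res residual projection, D x G.
#' @param alpha fusion weight in `[0, 1]`.
#' @return list with `yhat`, `y_resid` (the raw linear pathway `X_avg W_res`)
#'   and `X_avg`.
#' @export
residual_fusion <- function(X, y_deep, W_res, alpha) {
  X_avg <- apply(X, c(1, 3), mean)
  y_resid <- X_avg %*% W_res
  list(yhat = alpha * y_deep + (1 - alpha) * y_resid,
       y_resid = y_resid, X_avg = X_avg)
}

#' Average the predictions of an ensemble
#'
#' @param models list of trained models (or any objects accepted by
#'   `predict_fn`).
#' @param X input array B x T x D.
#' @param predict_fn function(model, X) returning a B x G matrix; defaults
#'   to the package's network prediction.
#' @return B x G matrix, the unweighted mean of member predictions.
#' @export
ensemble_predict <- function(models, X, predict_fn = NULL) {
  if (!length(models)) abort_validation("empty ensemble")
  predict_fn <- predict_fn %||% function(m, X)
    network_forward(m$params, m$hp, X)$yhat
  preds <- lapply(models, function(m) predict_fn(m, X))
  Reduce(`+`, preds) / length(preds)
}

#' Full network forward pass
#'
#' @param params an `asir_network_params` list.
#' @param hp the matching [hyperparameters()].
#' @param X input array B x T x D.
#' @param training logical; enables dropout and batch-statistics
#'   normalization.
#' @param keep_cache retain intermediate activations for backpropagation.
#' @return list with `yhat`, `y_deep`, `y_resid`, `alpha`, updated `params`
#'   (running statistics) and, if requested, `cache`.
#' @export
network_forward <- function(params, hp, X, training = FALSE,
                            keep_cache = FALSE) {
  if (length(dim(X)) != 3) abort_validation("X must be a B x T x D array")
  pf <- proj_forward(X, params$input, use_bn = hp$use_batchnorm,
                     training = training)
  params$input <- pf$updated_input
  bl <- bilstm_forward_cached(pf$H, params$lstm, dropout = hp$dropout,
                              training = training)
  T <- dim(X)[2]
  if (hp$attention) {
    ms <- multi_scale_attention_cached(bl$H, params$attention, hp$scales,
                                       d_k = hp$d_a)
    C_att <- ms$C
  } else {
    ms <- NULL
    w <- dim(bl$H)[3]
    C_att <- bl$H[, T, , drop = FALSE]
    dim(C_att) <- c(dim(X)[1], w)
  }
  gh <- group_heads(C_att, params$shared, params$heads)
  alpha <- sigmoid(params$alpha_logit)
  rf <- residual_fusion(X, gh$yhat, params$residual$W, alpha)
  out <- list(yhat = rf$yhat, y_deep = gh$yhat, y_resid = rf$y_resid,
              alpha = alpha, params = params)
  if (keep_cache) {
    out$cache <- list(X = X, proj = pf$cache, H_proj = pf$H, lstm = bl$caches,
                      Hseq = bl$H, ms = ms, C_att = C_att, gh = gh, rf = rf,
                      training = training)
  }
  out
}
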