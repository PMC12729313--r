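# Independent scalar ("brute force") oracles used to check the vectorized
# implementations. These are written with explicit loops and elementary
# arithmetic only, and must stay independent of the package's code paths.

osig <- function(z) 1 / (1 + exp(-z))

# One LSTM cell step for a single sample, scalar loops over hidden units.
oracle_lstm_cell <- function(x, h_prev, C_prev, w) {
  d_h <- length(h_prev)
  hx <- c(h_prev, x)
  f <- i <- Ctil <- o <- C <- h <- numeric(d_h)
  for (u in seq_len(d_h)) {
    f[u] <- osig(sum(w$W_f[, u] * hx) + w$b_f[u])
    i[u] <- osig(sum(w$W_i[, u] * hx) + w$b_i[u])
    Ctil[u] <- tanh(sum(w$W_C[, u] * hx) + w$b_C[u])
    C[u] <- f[u] * C_prev[u] + i[u] * Ctil[u]
    o[u] <- osig(sum(w$W_o[, u] * hx) + w$b_o[u])
    h[u] <- o[u] * tanh(C[u])
  }
  list(h = h, C = C, f = f, i = i, o = o, Ctil = Ctil)
}

# Attention head for one sample: H is a T x w matrix of hidden states.
oracle_attention_head <- function(H, W_a, b_a, v_a, mask, d_k) {
  m <- length(mask)
  logits <- numeric(m)
  for (j in seq_len(m)) {
    s <- tanh(as.vector(H[mask[j], ] %*% W_a) + b_a)
    logits[j] <- sum(s * v_a) / sqrt(d_k)
  }
  a <- exp(logits - max(logits))
  a <- a / sum(a)
  ctx <- numeric(ncol(H))
  for (j in seq_len(m)) ctx <- ctx + a[j] * H[mask[j], ]
  list(context = ctx, weights = a)
}

# The five regression metrics, formula by formula.
oracle_metrics <- function(y, yhat) {
  n <- length(y)
  mae <- sum(abs(y - yhat)) / n
  mse <- sum((y - yhat)^2) / n
  rmse <- sqrt(mse)
  mape <- sum(abs((y - yhat) / y)) / n
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(mae = mae, mse = mse, rmse = rmse, mape = mape, r2 = r2)
}

# PSO velocity/position update for one particle, scalar per dimension,
# including velocity and position clamping.
oracle_pso_update <- function(x, v, p_best, g_best, w, c1, c2, r1, r2,
                              lower, upper, clamp_frac) {
  nd <- length(x)
  v_new <- numeric(nd)
  x_new <- numeric(nd)
  for (d in seq_len(nd)) {
    vd <- w * v[d] + c1 * r1[d] * (p_best[d] - x[d]) +
      c2 * r2[d] * (g_best[d] - x[d])
    vmax <- clamp_frac * (upper[d] - lower[d])
    if (vd > vmax) vd <- vmax
    if (vd < -vmax) vd <- -vmax
    xd <- x[d] + vd
    if (xd > upper[d]) xd <- upper[d]
    if (xd < lower[d]) xd <- lower[d]
    v_new[d] <- vd
    x_new[d] <- xd
  }
  list(x = x_new, v = v_new)
}

# Straight-line scalar implementation of the whole forward pass for one
# sample (no batch normalization, single bidirectional layer, no dropout):
# input projection -> BiLSTM -> multi-scale attention -> shared layer ->
# group heads -> residual fusion.
oracle_full_forward <- function(x, params, hp, T, D, G) {
  d_h <- hp$d_h
  # Eq: H_input = ReLU(X W + b), per time step
  Hin <- matrix(0, T, d_h)
  for (t in seq_len(T)) {
    for (u in seq_len(d_h)) {
      z <- params$input$b[u]
      for (d in seq_len(D)) z <- z + x[t, d] * params$input$W[d, u]
      Hin[t, u] <- max(z, 0)
    }
  }
  run_dir <- function(w, order) {
    h <- numeric(d_h); C <- numeric(d_h)
    Hout <- matrix(0, T, d_h)
    for (t in order) {
      st <- oracle_lstm_cell(Hin[t, ], h, C, w)
      h <- st$h; C <- st$C
      Hout[t, ] <- h
    }
    Hout
  }
  Hf <- run_dir(params$lstm[[1]]$fwd, seq_len(T))
  Hb <- run_dir(params$lstm[[1]]$bwd, rev(seq_len(T)))
  H <- cbind(Hf, Hb)                      # T x 2 d_h
  w_seq <- 2 * d_h
  # multi-scale attention with per-scale head concat + projection
  C_att <- c()
  for (s in seq_along(hp$scales)) {
    lags <- hp$scales[[s]][1]:hp$scales[[s]][2]
    mask <- sort(T + 1 - lags)
    heads_ctx <- c()
    for (hh in seq_len(hp$heads_per_scale)) {
      hd <- params$attention[[s]]$heads[[hh]]
      ctx <- oracle_attention_head(H, hd$W_a, hd$b_a, hd$v_a, mask,
                                   hp$d_a)$context
      heads_ctx <- c(heads_ctx, ctx)
    }
    cs <- numeric(w_seq)
    for (u in seq_len(w_seq)) {
      z <- params$attention[[s]]$b_proj[u]
      for (d in seq_along(heads_ctx)) {
        z <- z + heads_ctx[d] * params$attention[[s]]$W_proj[d, u]
      }
      cs[u] <- z
    }
    C_att <- c(C_att, cs)
  }
  # shared ReLU layer then per-group heads
  Hsh <- numeric(hp$d_shared)
  for (u in seq_len(hp$d_shared)) {
    z <- params$shared$b[u]
    for (d in seq_along(C_att)) z <- z + C_att[d] * params$shared$W[d, u]
    Hsh[u] <- max(z, 0)
  }
  y_deep <- numeric(G)
  for (g in seq_len(G)) {
    z <- params$heads$b[g]
    for (u in seq_len(hp$d_shared)) z <- z + Hsh[u] * params$heads$W[u, g]
    y_deep[g] <- z
  }
  # residual fusion
  x_avg <- numeric(D)
  for (d in seq_len(D)) x_avg[d] <- sum(x[, d]) / T
  y_res <- numeric(G)
  for (g in seq_len(G)) {
    z <- 0
    for (d in seq_len(D)) z <- z + x_avg[d] * params$residual$W[d, g]
    y_res[g] <- z
  }
  alpha <- 1 / (1 + exp(-params$alpha_logit))
  alpha * y_deep + (1 - alpha) * y_res
}

# Shapley values via the permutation-average formulation: the average over
# all |F|! orderings of each feature's marginal contribution when added in
# that order. Independent of the subset-weight formulation.
oracle_shap_permutation <- function(model_fn, x, x_ref) {
  F <- length(x)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  phi <- numeric(F)
  all_p <- perms(seq_len(F))
  for (p in all_p) {
    z <- x_ref
    prev <- model_fn(z)
    for (j in p) {
      z[j] <- x[j]
      cur <- model_fn(z)
      phi[j] <- phi[j] + (cur - prev)
      prev <- cur
    }
  }
  phi / length(all_p)
}
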