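# Analytic backpropagation through the full network. Verified against
# central-difference numerical gradients in the test suite; any change here
# must keep that check green.

# Dimension-safe slice of a B x T x d array at time t, returning B x d.
slice3 <- function(A, t) {
  B <- dim(A)[1]; d <- dim(A)[3]
  M <- A[, t, , drop = FALSE]
  dim(M) <- c(B, d)
  M
}

# A parameter list of the same shape with every numeric leaf zeroed.
zero_like <- function(x) {
  if (is.numeric(x)) {
    y <- x
    y[] <- 0
    y
  } else if (is.list(x)) {
    out <- lapply(x, zero_like)
    attributes(out) <- attributes(x)
    out
  } else x
}

# Backward pass through one direction of one LSTM layer.
# `steps` is the per-time-step cache from lstm_dir_forward, `order` the
# processing order used in the forward pass.
lstm_dir_backward <- function(steps, weights, dHout, order) {
  T <- dim(dHout)[2]; B <- dim(dHout)[1]
  d_h <- ncol(weights$W_f)
  d_in <- nrow(weights$W_f) - d_h
  g <- zero_like(weights)
  dI <- array(0, c(B, T, d_in))
  dh_carry <- matrix(0, B, d_h)
  dC_carry <- matrix(0, B, d_h)
  for (t in rev(order)) {
    st <- steps[[t]]
    dh <- slice3(dHout, t) + dh_carry
    do_ <- dh * st$tanhC
    dC <- dC_carry + dh * st$o * (1 - st$tanhC^2)
    dCtil <- dC * st$i
    di <- dC * st$Ctil
    df <- dC * st$C_prev
    dC_carry <- dC * st$f
    dpre_f <- df * st$f * (1 - st$f)
    dpre_i <- di * st$i * (1 - st$i)
    dpre_o <- do_ * st$o * (1 - st$o)
    dpre_c <- dCtil * (1 - st$Ctil^2)
    g$W_f <- g$W_f + crossprod(st$HX, dpre_f)
    g$W_i <- g$W_i + crossprod(st$HX, dpre_i)
    g$W_C <- g$W_C + crossprod(st$HX, dpre_c)
    g$W_o <- g$W_o + crossprod(st$HX, dpre_o)
    g$b_f <- g$b_f + colSums(dpre_f)
    g$b_i <- g$b_i + colSums(dpre_i)
    g$b_C <- g$b_C + colSums(dpre_c)
    g$b_o <- g$b_o + colSums(dpre_o)
    dHX <- dpre_f %*% t(weights$W_f) + dpre_i %*% t(weights$W_i) +
      dpre_c %*% t(weights$W_C) + dpre_o %*% t(weights$W_o)
    dh_carry <- dHX[, seq_len(d_h), drop = FALSE]
    dI[, t, ] <- dHX[, d_h + seq_len(d_in), drop = FALSE]
  }
  list(grads = g, dI = dI)
}

#' Backpropagate through the network
#'
#' Computes gradients of a scalar loss with respect to every trainable
#' parameter and to the input tensor, given the upstream gradient `dY` of the
#' loss with respect to the fused prediction. The input gradient is what the
#' gradient-based Shapley explainer consumes.
#'
#' @param params the network parameters used in the forward pass.
#' @param hp the matching [hyperparameters()].
#' @param cache the cache from [network_forward()] with `keep_cache = TRUE`.
#' @param dY upstream gradient, B x G.
#' @return list with `grads` (same structure as `params`) and `dX`
#'   (B x T x D).
#' @export
network_backward <- function(params, hp, cache, dY) {
  X <- cache$X
  B <- dim(X)[1]; T <- dim(X)[2]; D <- dim(X)[3]
  grads <- zero_like(params)
  gh <- cache$gh; rf <- cache$rf
  alpha <- sigmoid(params$alpha_logit)

  # fusion: Y = alpha * y_deep + (1 - alpha) * y_resid
  d_deep <- alpha * dY
  d_resid <- (1 - alpha) * dY
  dalpha <- sum(dY * (gh$yhat - rf$y_resid))
  grads$alpha_logit <- dalpha * alpha * (1 - alpha)
  grads$residual$W <- crossprod(rf$X_avg, d_resid)
  dX_avg <- d_resid %*% t(params$residual$W)
  dX <- array(0, dim(X))
  for (t in seq_len(T)) dX[, t, ] <- dX[, t, ] + dX_avg / T

  # group heads and shared layer
  grads$heads$W <- crossprod(gh$Hsh, d_deep)
  grads$heads$b <- colSums(d_deep)
  dHsh <- d_deep %*% t(params$heads$W)
  dpre <- dHsh * (gh$pre > 0)
  grads$shared$W <- crossprod(cache$C_att, dpre)
  grads$shared$b <- colSums(dpre)
  dC_att <- dpre %*% t(params$shared$W)

  # attention (or last-step shortcut)
  w <- dim(cache$Hseq)[3]
  dH <- array(0, dim(cache$Hseq))
  if (hp$attention) {
    for (s in seq_along(hp$scales)) {
      sc <- cache$ms$scales_cache[[s]]
      dcs <- dC_att[, (s - 1L) * w + seq_len(w), drop = FALSE]
      grads$attention[[s]]$b_proj <- colSums(dcs)
      grads$attention[[s]]$W_proj <- crossprod(sc$CH, dcs)
      dCH <- dcs %*% t(params$attention[[s]]$W_proj)
      mask <- sc$mask
      m <- length(mask)
      for (h in seq_along(sc$heads)) {
        hc <- sc$heads[[h]]
        hd <- params$attention[[s]]$heads[[h]]
        dc <- dCH[, (h - 1L) * w + seq_len(w), drop = FALSE]
        A <- hc$weights
        dA <- matrix(0, B, m)
        for (j in seq_len(m)) {
          Ht <- slice3(cache$Hseq, mask[j])
          dA[, j] <- rowSums(dc * Ht)
          dH[, mask[j], ] <- dH[, mask[j], ] + A[, j] * dc
        }
        dL <- A * (dA - rowSums(A * dA))
        sq <- sqrt(hp$d_a)
        dva <- numeric(length(hd$v_a))
        gWa <- 0 * hd$W_a
        gba <- numeric(length(hd$b_a))
        for (j in seq_len(m)) {
          Sj <- matrix(hc$S[, j, ], B)
          dva <- dva + colSums(dL[, j] * Sj) / sq
          dSj <- (dL[, j] %o% hd$v_a) / sq
          dprej <- dSj * (1 - Sj^2)
          Ht <- slice3(cache$Hseq, mask[j])
          gWa <- gWa + crossprod(Ht, dprej)
          gba <- gba + colSums(dprej)
          dH[, mask[j], ] <- dH[, mask[j], ] + dprej %*% t(hd$W_a)
        }
        grads$attention[[s]]$heads[[h]]$W_a <- gWa
        grads$attention[[s]]$heads[[h]]$b_a <- gba
        grads$attention[[s]]$heads[[h]]$v_a <- dva
      }
    }
  } else {
    dH[, T, ] <- dH[, T, ] + dC_att
  }

  # LSTM stack, top layer first
  dI <- dH
  for (l in rev(seq_along(params$lstm))) {
    lc <- cache$lstm[[l]]
    if (!is.null(lc$mask)) dI <- dI * lc$mask
    lw <- params$lstm[[l]]
    d_h <- ncol(lw$fwd$W_f)
    if (!is.null(lc$bwd)) {
      dfwd <- dI[, , seq_len(d_h), drop = FALSE]
      dbwd <- dI[, , d_h + seq_len(d_h), drop = FALSE]
      bf <- lstm_dir_backward(lc$fwd$steps, lw$fwd, dfwd, seq_len(T))
      bb <- lstm_dir_backward(lc$bwd$steps, lw$bwd, dbwd, rev(seq_len(T)))
      grads$lstm[[l]]$fwd <- bf$grads
      grads$lstm[[l]]$bwd <- bb$grads
      dI <- bf$dI + bb$dI
    } else {
      bf <- lstm_dir_backward(lc$fwd$steps, lw$fwd, dI, seq_len(T))
      grads$lstm[[l]]$fwd <- bf$grads
      dI <- bf$dI
    }
  }

  # input projection (+ batch norm)
  pc <- cache$proj
  d_h <- ncol(params$input$W)
  dA <- array(dI, c(B * T, d_h))
  dZb <- dA * pc$relu_mask
  if (pc$use_bn) {
    grads$input$gamma <- colSums(dZb * pc$Zn)
    grads$input$beta <- colSums(dZb)
    dZn <- sweep(dZb, 2, pc$gamma, "*")
    if (pc$training) {
      N <- B * T
      s1 <- colSums(dZn)
      s2 <- colSums(dZn * pc$Zn)
      dZ <- sweep(dZn - (matrix(s1, N, d_h, byrow = TRUE) +
                           pc$Zn * matrix(s2, N, d_h, byrow = TRUE)) / N,
                  2, pc$invstd, "*")
    } else {
      dZ <- sweep(dZn, 2, pc$invstd, "*")
    }
  } else {
    dZ <- dZb
  }
  grads$input$W <- crossprod(pc$Xmat, dZ)
  grads$input$b <- colSums(dZ)
  dXmat <- dZ %*% t(params$input$W)
  dX <- dX + array(dXmat, c(B, T, D))
  list(grads = grads, dX = dX)
}
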