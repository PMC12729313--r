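#' Exact Shapley values by subset enumeration
#'
#' Computes the Shapley value of every feature of a black-box function by
#' full enumeration of the 2^F feature subsets, with the missing features of
#' a coalition replaced by their reference values. Serves as the oracle that
#' the gradient approximation is validated against; refuses more than 12
#' features.
#'
#' @param model_fn function taking a numeric vector of length F, returning a
#'   scalar.
#' @param x the input to explain.
#' @param x_ref the reference input of the same length.
#' @return numeric vector `phi` with `sum(phi) = model_fn(x) - model_fn(x_ref)`.
#' @export
exact_shap_small <- function(model_fn, x, x_ref) {
  F <- length(x)
  if (F > 12) abort_validation("exact enumeration refuses more than 12 features")
  if (length(x_ref) != F) abort_validation("x and x_ref lengths differ")
  nsub <- bitwShiftL(1L, F)
  bits <- bitwShiftL(1L, seq_len(F) - 1L)
  vals <- numeric(nsub)
  sizes <- integer(nsub)
  for (s in 0:(nsub - 1L)) {
    idx <- which(bitwAnd(s, bits) != 0L)
    z <- x_ref
    z[idx] <- x[idx]
    vals[s + 1L] <- model_fn(z)
    sizes[s + 1L] <- length(idx)
  }
  fact <- factorial(0:F)
  phi <- numeric(F)
  for (j in seq_len(F)) {
    bj <- bits[j]
    for (s in 0:(nsub - 1L)) {
      if (bitwAnd(s, bj) == 0L) {
        sz <- sizes[s + 1L]
        wgt <- fact[sz + 1L] * fact[F - sz] / fact[F + 1L]
        phi[j] <- phi[j] + wgt * (vals[s + bj + 1L] - vals[s + 1L])
      }
    }
  }
  phi
}

#' Augment a background set with jittered copies
#'
#' Adds Gaussian-jittered copies of the background inputs (SD a fraction of
#' each feature column's own SD), the data-augmentation device used to widen
#' the reference distribution for the gradient explainer.
#'
#' @param X background array B x T x D.
#' @param n_jitter jittered copies per background sample.
#' @param jitter_frac jitter SD as a fraction of each column's SD.
#' @param seed integer seed.
#' @return array (B * (1 + n_jitter)) x T x D.
#' @export
augment_background <- function(X, n_jitter = 1L, jitter_frac = 0.05,
                               seed = 1L) {
  if (n_jitter < 1) return(X)
  B <- dim(X)[1]; T <- dim(X)[2]; D <- dim(X)[3]
  col_sd <- apply(X, 3, stats::sd)
  with_seed(seed, {
    copies <- lapply(seq_len(n_jitter), function(i) {
      noise <- array(stats::rnorm(B * T * D), c(B, T, D))
      X + sweep(noise, 3, jitter_frac * col_sd, "*")
    })
    out <- array(0, c(B * (1 + n_jitter), T, D))
    out[seq_len(B), , ] <- X
    for (i in seq_len(n_jitter)) {
      out[i * B + seq_len(B), , ] <- copies[[i]]
    }
    out
  })
}

#' Gradient-based Shapley attribution (expected gradients)
#'
#' Approximates Shapley values for the network by averaging
#' `(x - ref) * grad f` over draws of a background sample and an
#' interpolation point on the straight path from that reference to `x`.
#' The printed one-point form (gradient at `x` against the mean reference)
#' is available as `mode = "one_point"` but violates completeness on
#' nonlinear models; the default integrates `path_steps` midpoints per
#' background draw.
#'
#' @param model an `asir_trained_model`.
#' @param X inputs to explain: `asir_windows` or B x T x D array.
#' @param background reference inputs (typically the training inputs,
#'   possibly [augment_background()]ed).
#' @param M background draws per explained sample.
#' @param path_steps interpolation points per draw.
#' @param output `"sum"` attributes the sum of the 24 group outputs;
#'   `"group"` attributes a single group's output.
#' @param group group index when `output = "group"`.
#' @param mode `"expected"` (path-integrated) or `"one_point"`.
#' @param seed integer seed for the background draws.
#' @return an object of class `asir_shap`: per-sample `phi` (B x T x D),
#'   group-aggregated signed and absolute views, model outputs and the
#'   per-sample completeness gap.
#' @export
gradient_shap <- function(model, X, background, M = 8L, path_steps = 25L,
                          output = c("sum", "group"), group = NULL,
                          mode = c("expected", "one_point"), seed = 1L) {
  output <- match.arg(output)
  mode <- match.arg(mode)
  Xa <- if (inherits(X, "asir_windows")) X$inputs else X
  bg <- if (inherits(background, "asir_windows")) background$inputs else background
  if (!dim(bg)[1]) abort_validation("background must be non-empty")
  B <- dim(Xa)[1]; T <- dim(Xa)[2]; D <- dim(Xa)[3]
  G <- ncol(model$params$heads$W)
  sel <- if (output == "sum") rep(1, G) else {
    if (is.null(group)) abort_validation("group index required")
    as.numeric(seq_len(G) == group)
  }
  f_of <- function(A) {
    fw <- network_forward(model$params, model$hp, A, training = FALSE)
    as.vector(fw$yhat %*% sel)
  }
  grad_of <- function(A) {
    n <- dim(A)[1]
    fw <- network_forward(model$params, model$hp, A, training = FALSE,
                          keep_cache = TRUE)
    dY <- matrix(sel, n, G, byrow = TRUE)
    g <- network_backward(model$params, model$hp, fw$cache, dY)$dX
    if (any(!is.finite(g))) abort_validation("non-finite gradients")
    g
  }
  phi <- array(0, c(B, T, D))
  f_ref_each <- numeric(B)
  with_seed(seed, {
    for (i in seq_len(B)) {
      xi <- Xa[i, , , drop = FALSE]
      ref_idx <- sample.int(dim(bg)[1], M, replace = TRUE)
      if (mode == "one_point") {
        ref_mean <- apply(bg[ref_idx, , , drop = FALSE], c(2, 3), mean)
        g <- grad_of(xi)[1, , ]
        phi[i, , ] <- (xi[1, , ] - ref_mean) * g
        f_ref_each[i] <- f_of(array(ref_mean, c(1, T, D)))
      } else {
        ts <- (seq_len(path_steps) - 0.5) / path_steps
        npt <- M * path_steps
        pts <- array(0, c(npt, T, D))
        diffs <- array(0, c(npt, T, D))
        r <- 0L
        for (m in seq_len(M)) {
          refm <- bg[ref_idx[m], , ]
          dm <- xi[1, , ] - refm
          for (s in seq_len(path_steps)) {
            r <- r + 1L
            pts[r, , ] <- refm + ts[s] * dm
            diffs[r, , ] <- dm
          }
        }
        g <- grad_of(pts)
        phi[i, , ] <- apply(diffs * g, c(2, 3), mean)
        f_ref_each[i] <- mean(f_of(bg[ref_idx, , , drop = FALSE]))
      }
    }
  })
  f_x <- f_of(Xa)
  gap <- abs(apply(phi, 1, sum) - (f_x - f_ref_each))
  group_keys <- unique(series_key(model$manifest$sex, model$manifest$age_band))
  col_group <- series_key(model$manifest$sex, model$manifest$age_band)
  signed <- matrix(0, B, length(group_keys),
                   dimnames = list(NULL, group_keys))
  absval <- signed
  for (gk in group_keys) {
    cols <- which(col_group == gk)
    ps <- phi[, , cols, drop = FALSE]
    signed[, gk] <- apply(ps, 1, sum)
    absval[, gk] <- apply(abs(ps), 1, sum)
  }
  structure(list(phi = phi, phi_group = signed, phi_group_abs = absval,
                 f_x = f_x, f_ref = f_ref_each, completeness_gap = gap,
                 manifest = model$manifest, group_keys = group_keys,
                 M = M, path_steps = path_steps, mode = mode,
                 output = output),
            class = "asir_shap")
}

#' @export
print.asir_shap <- function(x, ...) {
  cat(sprintf("<asir_shap> %d samples, %d groups; mean |completeness gap| %.3g\n",
              nrow(x$phi_group), length(x$group_keys),
              mean(x$completeness_gap)))
  invisible(x)
}

group_table <- function(keys) {
  parts <- strsplit(keys, "|", fixed = TRUE)
  data.frame(group = keys,
             sex = vapply(parts, `[`, "", 1),
             age_band = vapply(parts, `[`, "", 2),
             stringsAsFactors = FALSE)
}

#' Global feature importance ranking
#'
#' Mean absolute attribution per sex-age group (all feature columns and time
#' steps owned by the group collapsed by summed `|phi|`, then averaged over
#' samples), ranked descending, with each group's share of the total.
#'
#' @param expl an `asir_shap` explanation.
#' @return data.frame with columns group, sex, age_band, importance, share,
#'   rank. Shares are `NA` when all attributions are zero.
#' @export
global_importance <- function(expl) {
  imp <- colMeans(expl$phi_group_abs)
  tab <- group_table(expl$group_keys)
  tab$importance <- imp
  total <- sum(imp)
  tab$share <- if (total > 0) imp / total else NA_real_
  tab <- tab[order(-tab$importance), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}

#' Importance stratified by age band and by sex
#'
#' @param expl an `asir_shap` explanation.
#' @return list with `by_band` (band totals, both sexes summed) and
#'   `by_cell` (one row per sex x band cell).
#' @export
stratified_importance <- function(expl) {
  g <- global_importance(expl)
  by_cell <- g[order(g$age_band, g$sex), c("sex", "age_band", "importance")]
  rownames(by_cell) <- NULL
  agg <- stats::aggregate(importance ~ age_band, data = by_cell, FUN = sum)
  list(by_band = agg[order(-agg$importance), , drop = FALSE],
       by_cell = by_cell)
}

#' Local (per-sample) attribution decomposition
#'
#' The top groups by absolute signed attribution for one explained sample,
#' together with the completeness residual, in a form suitable for a
#' waterfall rendering.
#'
#' @param expl an `asir_shap` explanation.
#' @param sample sample index.
#' @param top_k number of groups to list.
#' @return data.frame of signed contributions; attributes `f_x`, `f_ref` and
#'   `residual` carry the completeness bookkeeping.
#' @export
local_explanation <- function(expl, sample, top_k = 10L) {
  B <- nrow(expl$phi_group)
  if (sample < 1 || sample > B) abort_validation("sample index out of range")
  phi <- expl$phi_group[sample, ]
  ord <- order(-abs(phi))
  keep <- utils::head(ord, top_k)
  tab <- group_table(expl$group_keys)[keep, , drop = FALSE]
  tab$phi <- phi[keep]
  tab <- tab[abs(tab$phi) > 0, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "f_x") <- expl$f_x[sample]
  attr(tab, "f_ref") <- expl$f_ref[sample]
  attr(tab, "residual") <-
    (expl$f_x[sample] - expl$f_ref[sample]) - sum(phi)
  tab
}

#' Tidy long-format attribution export
#'
#' @param expl an `asir_shap` explanation.
#' @return data.frame (sample, group, sex, age_band, phi, abs_phi) ready for
#'   CSV export or beeswarm-style plotting.
#' @export
shap_long <- function(expl) {
  B <- nrow(expl$phi_group)
  tab <- group_table(expl$group_keys)
  data.frame(
    sample = rep(seq_len(B), times = length(expl$group_keys)),
    group = rep(tab$group, each = B),
    sex = rep(tab$sex, each = B),
    age_band = rep(tab$age_band, each = B),
    phi = as.vector(expl$phi_group),
    abs_phi = as.vector(expl$phi_group_abs),
    stringsAsFactors = FALSE
  )
}

#' Dual-pathway component contributions
#'
#' Mean absolute output of the fused-scale residual pathway
#' `(1 - alpha) X_avg W_res` and deep pathway `alpha y_deep` over a sample
#' set, with each pathway's fraction of their sum.
#'
#' @param model an `asir_trained_model`.
#' @param X an `asir_windows` dataset or B x T x D array.
#' @return object of class `asir_components`: `deep_mean_abs`,
#'   `residual_mean_abs`, `deep_fraction`, `residual_fraction`, `alpha`.
#' @export
component_contribution <- function(model, X) {
  pr <- predict(model, X, components = TRUE)
  deep <- mean(abs(pr$alpha * pr$y_deep))
  res <- mean(abs((1 - pr$alpha) * pr$y_resid))
  tot <- deep + res
  structure(list(deep_mean_abs = deep, residual_mean_abs = res,
                 deep_fraction = if (tot > 0) deep / tot else NA_real_,
                 residual_fraction = if (tot > 0) res / tot else NA_real_,
                 alpha = pr$alpha),
            class = "asir_components")
}

#' @export
print.asir_components <- function(x, ...) {
  cat(sprintf("residual %.1f%% | deep %.1f%% (alpha = %.3f)\n",
              100 * x$residual_fraction, 100 * x$deep_fraction, x$alpha))
  invisible(x)
}
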