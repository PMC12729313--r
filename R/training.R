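#' Training configuration
#'
#' Adam with cosine-annealed learning rate (from the network's learning rate
#' down to 1/100 of it over `max_epochs`, no restarts), early stopping on a
#' time-ordered validation tail, and global gradient-norm clipping.
#'
#' @param max_epochs maximum training epochs.
#' @param batch_size minibatch size.
#' @param early_stop_patience epochs without validation improvement before
#'   stopping (0 stops at the first non-improving epoch).
#' @param gradient_clip_norm global L2 norm ceiling for each step's gradient.
#' @param seed integer seed governing initialization, shuffling and dropout.
#' @param val_years the validation slice is the samples with the last
#'   `val_years` target years of the training set (leakage-free tail).
#' @return an object of class `asir_training_config`.
#' @export
training_config <- function(max_epochs = 500L, batch_size = 16L,
                            early_stop_patience = 20L,
                            gradient_clip_norm = 1.0, seed = 1L,
                            val_years = 4L) {
  if (early_stop_patience >= max_epochs) {
    abort_validation("early_stop_patience must be < max_epochs")
  }
  structure(list(max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 early_stop_patience = as.integer(early_stop_patience),
                 gradient_clip_norm = gradient_clip_norm,
                 seed = as.integer(seed), val_years = as.integer(val_years)),
            class = "asir_training_config")
}

cosine_lr <- function(epoch, max_epochs, lr0) {
  lr_min <- lr0 / 100
  lr_min + 0.5 * (lr0 - lr_min) * (1 + cos(pi * (epoch - 1) / max_epochs))
}

# Split a training dataset into a fitting part and a time-ordered validation
# tail holding the last `val_years` distinct target years.
validation_split <- function(train, val_years) {
  yrs <- sort(unique(train$target_years))
  if (length(yrs) <= val_years) {
    abort_validation("not enough target years for a ", val_years,
                     "-year validation tail")
  }
  val_set <- utils::tail(yrs, val_years)
  idx_val <- which(train$target_years %in% val_set)
  list(fit = windows_subset(train, setdiff(seq_along(train$target_years), idx_val)),
       val = windows_subset(train, idx_val))
}

mse_loss <- function(yhat, y) mean((yhat - y)^2)

#' Train the network on a windowed dataset
#'
#' Minimizes mean squared error over all groups jointly with Adam, restores
#' the parameters of the best validation epoch, and returns the per-epoch
#' training log. Deterministic for a fixed seed.
#'
#' @param train an `asir_windows` training set (standardized scale).
#' @param hp [hyperparameters()].
#' @param cfg [training_config()].
#' @return an object of class `asir_trained_model`.
#' @export
train_model <- function(train, hp, cfg = training_config()) {
  stopifnot(inherits(train, "asir_windows"))
  parts <- validation_split(train, cfg$val_years)
  fit <- parts$fit; val <- parts$val
  n_fit <- nrow(fit$targets)
  if (n_fit < 1) abort_validation("empty fitting partition")
  D <- dim(train$inputs)[3]; G <- ncol(train$targets)
  params <- init_network(hp, D, G, seed = derive_seed(cfg$seed, "init"))
  flat <- flatten_params(params)
  theta <- flat$vec
  m <- numeric(length(theta)); v <- numeric(length(theta))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  best_val <- Inf; best_params <- params; best_epoch <- 0L; wait <- 0L
  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    val_loss = numeric(), lr = numeric())
  for (epoch in seq_len(cfg$max_epochs)) {
    lr_t <- cosine_lr(epoch, cfg$max_epochs, hp$learning_rate)
    epoch_losses <- c()
    with_seed(derive_seed(cfg$seed, paste0("epoch", epoch)), {
      ord <- sample.int(n_fit)
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      for (bi in batches) {
        Xb <- fit$inputs[bi, , , drop = FALSE]
        Yb <- fit$targets[bi, , drop = FALSE]
        fw <- network_forward(params, hp, Xb, training = TRUE,
                              keep_cache = TRUE)
        params <- fw$params               # batch-norm running stats advance
        loss <- mse_loss(fw$yhat, Yb)
        if (!is.finite(loss)) {
          stop("non-finite training loss at epoch ", epoch,
               "; try a smaller learning rate")
        }
        epoch_losses <- c(epoch_losses, loss)
        dY <- 2 * (fw$yhat - Yb) / length(Yb)
        bw <- network_backward(params, hp, fw$cache, dY)
        g <- clip_gradient(flatten_params(bw$grads)$vec,
                           cfg$gradient_clip_norm)
        step <- step + 1L
        m <- beta1 * m + (1 - beta1) * g
        v <- beta2 * v + (1 - beta2) * g^2
        mhat <- m / (1 - beta1^step)
        vhat <- v / (1 - beta2^step)
        theta <- flatten_params(params)$vec
        theta <- theta - lr_t * mhat / (sqrt(vhat) + eps)
        params <- unflatten_params(params, flat, theta)
      }
    })
    vf <- network_forward(params, hp, val$inputs, training = FALSE)
    val_loss <- mse_loss(vf$yhat, val$targets)
    log <- rbind(log, data.frame(epoch = epoch,
                                 train_loss = mean(epoch_losses),
                                 val_loss = val_loss, lr = lr_t))
    if (val_loss < best_val - 1e-12) {
      best_val <- val_loss
      best_params <- params
      best_epoch <- epoch
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait > cfg$early_stop_patience) break
    }
  }
  structure(list(params = best_params, hp = hp, cfg = cfg, log = log,
                 best_epoch = best_epoch, best_val_loss = best_val,
                 manifest = train$manifest, groups = train$groups,
                 window = train$window),
            class = "asir_trained_model")
}

#' @export
print.asir_trained_model <- function(x, ...) {
  cat(sprintf("<asir_trained_model> d_h=%d layers=%d %s%s | best epoch %d, val MSE %.3g\n",
              x$hp$d_h, x$hp$n_lstm_layers,
              if (x$hp$bidirectional) "BiLSTM" else "LSTM",
              if (x$hp$attention) "+attention" else "", x$best_epoch,
              x$best_val_loss))
  invisible(x)
}

#' Predict from a trained model
#'
#' @param object an `asir_trained_model`.
#' @param newdata an `asir_windows` dataset or a B x T x D array.
#' @param components also return the two pre-fusion pathway outputs.
#' @param ... unused.
#' @return a B x G prediction matrix (standardized scale); with
#'   `components = TRUE`, a list with `yhat`, `y_deep`, `y_resid`, `alpha`.
#' @export
predict.asir_trained_model <- function(object, newdata, components = FALSE,
                                       ...) {
  X <- if (inherits(newdata, "asir_windows")) newdata$inputs else newdata
  fw <- network_forward(object$params, object$hp, X, training = FALSE)
  colnames(fw$yhat) <- object$groups$key
  if (components) {
    list(yhat = fw$yhat, y_deep = fw$y_deep, y_resid = fw$y_resid,
         alpha = fw$alpha)
  } else fw$yhat
}

#' Regression metrics report
#'
#' Computes MAE, MSE, RMSE, MAPE and R^2 pooled over all samples and groups,
#' plus a per-group breakdown. MAPE is reported as a fraction (0.15 means
#' 15%); elements with a true value of zero are excluded from MAPE and
#' counted in `mape_excluded`.
#'
#' @param y_true,y_pred matrices (or vectors) of equal shape.
#' @return an object of class `asir_metrics` with fields `mae`, `mse`,
#'   `rmse`, `mape`, `r2`, `n`, `per_group`, `mape_excluded`.
#' @export
evaluate <- function(y_true, y_pred) {
  if (is.null(dim(y_true))) y_true <- matrix(y_true, ncol = 1)
  if (is.null(dim(y_pred))) y_pred <- matrix(y_pred, ncol = 1)
  if (!all(dim(y_true) == dim(y_pred))) {
    abort_validation("y_true and y_pred must have identical shapes")
  }
  err <- y_true - y_pred
  n <- length(err)
  mae <- mean(abs(err))
  mse <- mean(err^2)
  rmse <- sqrt(mse)
  nz <- y_true != 0
  mape_excluded <- sum(!nz)
  if (mape_excluded > 0) {
    warning(mape_excluded, " element(s) with zero true value excluded from MAPE")
  }
  mape <- if (any(nz)) mean(abs(err[nz] / y_true[nz])) else NA_real_
  sst <- sum((y_true - mean(y_true))^2)
  if (sst == 0) abort_validation("R^2 undefined: constant y_true")
  r2 <- 1 - sum(err^2) / sst
  per_group <- NULL
  if (ncol(y_true) > 1) {
    keys <- colnames(y_true) %||% paste0("g", seq_len(ncol(y_true)))
    per_group <- data.frame(
      group = keys,
      mae = colMeans(abs(err)),
      rmse = sqrt(colMeans(err^2)),
      row.names = NULL, stringsAsFactors = FALSE
    )
  }
  structure(list(mae = mae, mse = mse, rmse = rmse, mape = mape, r2 = r2,
                 n = n, per_group = per_group,
                 mape_excluded = mape_excluded),
            class = "asir_metrics")
}

#' @export
print.asir_metrics <- function(x, ...) {
  cat(sprintf("MAE %.4g | MSE %.4g | RMSE %.4g | MAPE %.4g | R2 %.4g (n=%d)\n",
              x$mae, x$mse, x$rmse, x$mape, x$r2, x$n))
  invisible(x)
}

metrics_row <- function(model, rep) {
  data.frame(model = model, mae = rep$mae, mse = rep$mse, rmse = rep$rmse,
             mape = rep$mape, r2 = rep$r2, stringsAsFactors = FALSE)
}

#' Evaluate a model on a test set, optionally on the rate scale
#'
#' @param model an `asir_trained_model` or list of them (ensemble).
#' @param test an `asir_windows` test set.
#' @param scaler optional `asir_scaler`; when given, predictions and targets
#'   are mapped back to per-100,000 rates before scoring.
#' @return an `asir_metrics` report.
#' @export
evaluate_model <- function(model, test, scaler = NULL) {
  yhat <- if (inherits(model, "asir_trained_model")) {
    predict(model, test)
  } else {
    p <- ensemble_predict(model, test$inputs)
    colnames(p) <- model[[1]]$groups$key
    p
  }
  y <- test$targets
  if (!is.null(scaler)) {
    yhat <- invert_standardizer(yhat, scaler)
    y <- invert_standardizer(y, scaler)
  }
  evaluate(y, yhat)
}

ablation_variants <- list(
  "LSTM" = list(bidirectional = FALSE, attention = FALSE, pso = FALSE),
  "BiLSTM" = list(bidirectional = TRUE, attention = FALSE, pso = FALSE),
  "BiLSTM-Attention" = list(bidirectional = TRUE, attention = TRUE, pso = FALSE),
  "PSO-BiLSTM" = list(bidirectional = TRUE, attention = FALSE, pso = TRUE),
  "PSO-BiLSTM-Attention" = list(bidirectional = TRUE, attention = TRUE, pso = TRUE)
)

#' Run the component-ablation comparison
#'
#' Trains and scores one model per named configuration on the same
#' train/test split: unidirectional LSTM, BiLSTM, BiLSTM with attention, and
#' the PSO-tuned variants with and without attention. PSO variants run a
#' particle swarm search (scaled by `swarm`) before the final fit.
#'
#' @param train,test `asir_windows` partitions.
#' @param hp base [hyperparameters()] used by the non-PSO variants.
#' @param cfg [training_config()].
#' @param variants subset of the five configuration names.
#' @param scaler optional scaler for rate-scale metrics.
#' @param swarm [swarm_config()] for the PSO variants.
#' @param space [default_search_space()] or a custom space.
#' @return list with `table` (one metrics row per variant) and `reports`.
#' @export
run_ablation <- function(train, test, hp = hyperparameters(),
                         cfg = training_config(),
                         variants = names(ablation_variants),
                         scaler = NULL, swarm = NULL, space = NULL) {
  unknown <- setdiff(variants, names(ablation_variants))
  if (length(unknown)) abort_validation("unknown variant: ", unknown[1])
  reports <- list()
  rows <- NULL
  for (vn in variants) {
    vd <- ablation_variants[[vn]]
    hp_v <- hp
    hp_v$bidirectional <- vd$bidirectional
    hp_v$attention <- vd$attention
    if (vd$pso) {
      swarm <- swarm %||% swarm_config(seed = cfg$seed)
      space <- space %||% default_search_space()
      fitness <- make_fitness(train, hp_v, cfg)
      res <- pso_optimize(space, fitness, swarm)
      hp_v <- apply_search_point(hp_v, res$best_decoded)
    }
    mod <- train_model(train, hp_v, cfg)
    rep <- evaluate_model(mod, test, scaler)
    reports[[vn]] <- rep
    rows <- rbind(rows, metrics_row(vn, rep))
  }
  list(table = rows, reports = reports)
}

#' Train an ensemble of perturbed sub-models
#'
#' Members differ only by their initialization seed (`base seed + m`); the
#' ensemble prediction is their unweighted mean.
#'
#' @param train an `asir_windows` training set.
#' @param hp [hyperparameters()] (`ensemble_size` members).
#' @param cfg [training_config()].
#' @return list of `asir_trained_model`s, class `asir_ensemble`.
#' @export
train_ensemble <- function(train, hp, cfg = training_config()) {
  models <- lapply(seq_len(hp$ensemble_size), function(m) {
    cfg_m <- cfg
    cfg_m$seed <- cfg$seed + m
    train_model(train, hp, cfg_m)
  })
  structure(models, class = "asir_ensemble")
}
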