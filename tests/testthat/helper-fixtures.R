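# Shared fixtures, built in code. Expensive objects (trained models) are
# memoized for the duration of the test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Panel -> leakage-free scaler -> features -> windows -> 2016 split.
std_split <- function(seed = 7, trend = "linear", noise_sd = 0,
                      boundary = 2016L) {
  spec <- synthetic_spec(seed = seed, trend_kind = trend, noise_sd = noise_sd)
  panel <- generate_panel(spec)
  scaler <- fit_standardizer(panel, panel$years[panel$years <= boundary])
  std <- apply_standardizer(panel, scaler)
  fm <- build_feature_matrix(std)
  ds <- make_windows(fm, std)
  split <- split_sequential(ds, boundary)
  list(panel = panel, scaler = scaler, std = std, fm = fm, ds = ds,
       train = split$train, test = split$test)
}

# Small-but-capable settings used by the behavioural (analogue) tests.
small_hp <- function(...) {
  args <- utils::modifyList(
    list(d_h = 16L, n_lstm_layers = 1L, heads_per_scale = 2L, dropout = 0.1,
         learning_rate = 0.01),
    list(...))
  do.call(hyperparameters, args)
}

small_cfg <- function(seed = 1L, max_epochs = 300L, patience = 40L) {
  training_config(max_epochs = max_epochs, early_stop_patience = patience,
                  seed = seed)
}

# A tiny configuration for exactness checks (no batch norm so the scalar
# oracle stays simple).
tiny_hp <- function(...) {
  args <- utils::modifyList(
    list(d_h = 2L, n_lstm_layers = 1L, heads_per_scale = 2L, dropout = 0,
         d_a = 2L, d_shared = 3L, scales = list(c(1, 2), c(2, 3)),
         use_batchnorm = FALSE),
    list(...))
  do.call(hyperparameters, args)
}

# Moore-Penrose pseudoinverse least squares (the engineered feature matrix
# is rank-deficient by construction: residual + trend = original).
pinv_solve <- function(X, Y, tol = 1e-8) {
  s <- svd(X)
  keep <- s$d > tol * s$d[1]
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) %*% Y / s$d[keep])
}

# One trained model on the zero-noise linear panel, reused by several tests.
linear_model_fixture <- function() {
  memo("linear_model", {
    fx <- std_split(seed = 7, trend = "linear", noise_sd = 0)
    mod <- train_model(fx$train, small_hp(), small_cfg(seed = 1))
    list(model = mod, fx = fx)
  })
}

# A tiny panel (one age band, two sexes) whose windows flatten to 12 input
# features, small enough for exact Shapley enumeration of the full network.
tiny_shap_fixture <- function(alpha_logit = 0, seed = 51) {
  memo(paste0("shap_fx_", alpha_logit, "_", seed), {
    p <- generate_panel(synthetic_spec(seed = seed, n_age_bands = 1,
                                       sex_offset = 10, noise_sd = 1))
    std <- apply_standardizer(p, fit_standardizer(p))
    fm <- build_feature_matrix(std)
    ds <- make_windows(fm, std, window = 1L)
    hp <- hyperparameters(d_h = 3L, n_lstm_layers = 1L, heads_per_scale = 2L,
                          dropout = 0, d_a = 3L, d_shared = 4L,
                          scales = list(c(1, 1)), use_batchnorm = FALSE)
    params <- init_network(hp, D = 12L, G = 2L, seed = seed)
    params$alpha_logit <- alpha_logit
    model <- wrap_model(params, hp, ds$manifest, ds$groups)
    list(model = model, ds = ds, hp = hp)
  })
}

# Flattened scalar view of the network for the exact-Shapley oracle.
model_fn_flat <- function(model, T, D) {
  function(z) {
    fw <- network_forward(model$params, model$hp, array(z, c(1, T, D)))
    sum(fw$yhat)
  }
}

# Wrap raw network params in a minimal trained-model shell so prediction and
# attribution helpers can be exercised without a training run.
wrap_model <- function(params, hp, manifest, groups) {
  structure(list(params = params, hp = hp, manifest = manifest,
                 groups = groups, window = NULL),
            class = "asir_trained_model")
}
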