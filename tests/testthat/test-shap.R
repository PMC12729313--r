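test_that("exact Shapley values satisfy the axioms", {
  # linearity: f(x) = sum w x  =>  phi_j = w_j (x_j - ref_j)
  w <- c(2, -1, 0.5, 3)
  f <- function(z) sum(w * z)
  x <- c(1, 2, 3, 4); ref <- c(0, 1, 0, -1)
  expect_equal(exact_shap_small(f, x, ref), w * (x - ref), tolerance = 1e-10)
  # efficiency on a nonlinear model
  set.seed(52)
  A <- matrix(rnorm(36), 6, 6)
  g <- function(z) sum(tanh(A %*% z)) + prod(z[1:2])
  x6 <- rnorm(6); r6 <- rnorm(6)
  phi <- exact_shap_small(g, x6, r6)
  expect_equal(sum(phi), g(x6) - g(r6), tolerance = 1e-9)
  # symmetry: exchangeable features with equal values get equal credit
  h <- function(z) z[1] * z[2] + z[1] + z[2] + 3 * z[3]
  phs <- exact_shap_small(h, c(2, 2, 5), c(0, 0, 0))
  expect_equal(phs[1], phs[2], tolerance = 1e-12)
  # dummy: a never-read feature gets zero
  d <- function(z) z[1]^2 + exp(z[3])
  phd <- exact_shap_small(d, c(1, 9, 2), c(0, -9, 0))
  expect_equal(phd[2], 0, tolerance = 1e-12)
  expect_error(exact_shap_small(f, rnorm(13), rnorm(13)), "12")
})

test_that("subset enumeration equals the permutation-average formulation", {
  set.seed(53)
  A <- matrix(rnorm(25), 5, 5)
  f <- function(z) sum(sin(A %*% z)) + z[1] * z[4]
  x <- rnorm(5); ref <- rnorm(5)
  expect_equal(exact_shap_small(f, x, ref),
               oracle_shap_permutation(f, x, ref), tolerance = 1e-8)
})

test_that("gradient attribution is exact on a linear model for any M", {
  fx <- tiny_shap_fixture(alpha_logit = -100)   # pure residual path: linear
  X <- fx$ds$inputs[1, , , drop = FALSE]
  bg <- fx$ds$inputs[2, , , drop = FALSE]
  f <- model_fn_flat(fx$model, 1, 12)
  for (M in c(1L, 3L)) {
    expl <- gradient_shap(fx$model, X, bg, M = M, path_steps = 2L, seed = 9)
    phi_exact <- exact_shap_small(f, as.vector(X[1, , ]),
                                  as.vector(bg[1, , ]))
    expect_equal(as.vector(expl$phi[1, , ]), phi_exact, tolerance = 1e-6)
    expect_lt(max(expl$completeness_gap), 1e-8)
  }
  # x = reference -> all-zero attributions
  same <- gradient_shap(fx$model, bg, bg, M = 1L, path_steps = 2L, seed = 9)
  expect_equal(max(abs(same$phi)), 0)
})

test_that("gradient attribution tracks exact values on a nonlinear model", {
  fx <- tiny_shap_fixture(alpha_logit = 0)
  X <- fx$ds$inputs[3, , , drop = FALSE]
  bg <- fx$ds$inputs[7, , , drop = FALSE]
  f <- model_fn_flat(fx$model, 1, 12)
  phi_exact <- exact_shap_small(f, as.vector(X[1, , ]), as.vector(bg[1, , ]))
  expl <- gradient_shap(fx$model, X, bg, M = 1L, path_steps = 200L, seed = 3)
  phi_g <- as.vector(expl$phi[1, , ])
  expect_gte(stats::cor(phi_g, phi_exact), 0.95)
  # path integration keeps the completeness gap small
  denom <- abs(expl$f_x[1] - expl$f_ref[1])
  expect_lte(expl$completeness_gap[1], 0.05 * denom + 1e-9)
  # the literal one-point mode exists but is allowed to violate completeness
  one <- gradient_shap(fx$model, X, bg, M = 1L, mode = "one_point", seed = 3)
  expect_equal(dim(one$phi), dim(expl$phi))
})

test_that("global importance ranks the truly-read group first", {
  fx <- std_split(seed = 54)
  hp <- hyperparameters(d_h = 4L, n_lstm_layers = 1L, heads_per_scale = 2L,
                        dropout = 0, use_batchnorm = FALSE)
  params <- init_network(hp, D = 144L, G = 24L, seed = 54)
  params$alpha_logit <- -100            # only the residual path is active
  target_group <- "Male|60-64"
  own <- which(paste(fx$ds$manifest$sex, fx$ds$manifest$age_band,
                     sep = "|") == target_group)
  params$residual$W[] <- 0
  params$residual$W[own, ] <- 1
  model <- wrap_model(params, hp, fx$ds$manifest, fx$ds$groups)
  expl <- gradient_shap(model, fx$test, fx$train, M = 2L, path_steps = 5L,
                        seed = 4)
  tab <- global_importance(expl)
  expect_equal(tab$group[1], target_group)
  expect_equal(sum(tab$share), 1, tolerance = 1e-9)
  expect_true(all(tab$share >= 0))
  # stratified tables decompose the global totals additively
  strat <- stratified_importance(expl)
  for (b in unique(strat$by_cell$age_band)) {
    cells <- strat$by_cell$importance[strat$by_cell$age_band == b]
    expect_equal(strat$by_band$importance[strat$by_band$age_band == b],
                 sum(cells), tolerance = 1e-12)
  }
  expect_equal(sum(strat$by_cell$importance), sum(tab$importance),
               tolerance = 1e-12)
})

test_that("all-zero attributions yield undefined shares, not NaN noise", {
  fx <- tiny_shap_fixture(alpha_logit = -100, seed = 55)
  model <- fx$model
  model$params$residual$W[] <- 0        # constant model: silence both paths
  model$params$heads$W[] <- 0
  model$params$heads$b[] <- 0
  expl <- gradient_shap(model, fx$ds$inputs[1, , , drop = FALSE],
                        fx$ds$inputs[2, , , drop = FALSE], M = 1L,
                        path_steps = 2L, seed = 1)
  tab <- global_importance(expl)
  expect_true(all(is.na(tab$share)))
  expect_false(any(is.nan(tab$importance)))
})

test_that("local explanations keep the completeness bookkeeping", {
  fx <- tiny_shap_fixture(alpha_logit = 0)
  X <- fx$ds$inputs[1:2, , , drop = FALSE]
  bg <- fx$ds$inputs[5, , , drop = FALSE]
  expl <- gradient_shap(fx$model, X, bg, M = 1L, path_steps = 50L, seed = 2)
  full <- local_explanation(expl, 1, top_k = length(expl$group_keys))
  expect_equal(sum(full$phi) + attr(full, "residual"),
               attr(full, "f_x") - attr(full, "f_ref"), tolerance = 1e-9)
  expect_error(local_explanation(expl, 99), "out of range")
  # explaining the reference itself: nothing to report
  self <- gradient_shap(fx$model, bg, bg, M = 1L, path_steps = 2L, seed = 2)
  empty <- local_explanation(self, 1, top_k = 3)
  expect_equal(nrow(empty), 0L)
})

test_that("a local value can flip sign against its global direction", {
  f <- function(z) z[1] * z[2]
  ref <- c(0, 0)
  phi_a <- exact_shap_small(f, c(1, 1), ref)
  phi_b <- exact_shap_small(f, c(1, -1), ref)
  expect_gt(phi_a[1], 0)
  expect_lt(phi_b[1], 0)
})

test_that("component contributions respond to alpha and sum to one", {
  fx <- tiny_shap_fixture(alpha_logit = 0)
  X <- fx$ds$inputs
  model <- fx$model
  model$params$alpha_logit <- 100       # alpha -> 1: all deep
  cc1 <- component_contribution(model, X)
  expect_equal(cc1$deep_fraction, 1, tolerance = 1e-9)
  expect_equal(cc1$residual_fraction, 0, tolerance = 1e-9)
  fracs <- vapply(c(-2, 0, 2), function(a) {
    model$params$alpha_logit <- a
    component_contribution(model, X)$residual_fraction
  }, numeric(1))
  expect_true(all(diff(fracs) < 0))
  expect_equal(fracs + vapply(c(-2, 0, 2), function(a) {
    model$params$alpha_logit <- a
    component_contribution(model, X)$deep_fraction
  }, numeric(1)), rep(1, 3), tolerance = 1e-12)
})

test_that("background augmentation jitters copies at the stated scale", {
  set.seed(57)
  X <- array(rnorm(5 * 3 * 4), c(5, 3, 4))
  aug <- augment_background(X, n_jitter = 2L, jitter_frac = 0.05, seed = 1)
  expect_equal(dim(aug), c(15L, 3L, 4L))
  expect_equal(aug[1:5, , ], X)
  expect_false(identical(aug[6:10, , ], X))
  expect_lt(max(abs(aug[6:10, , ] - X)), 1)
})
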