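#' Particle swarm configuration
#'
#' Defaults follow the stated regime: 8 particles, 20 iterations, inertia
#' decaying linearly from 0.9 to 0.4, learning factors c1 = c2 = 2, velocity
#' clamped to 20% of each dimension's range.
#'
#' @param n_particles swarm size (>= 2).
#' @param max_iterations K_max, maximum iterations.
#' @param w_max,w_min inertia weight at iteration 0 and K_max.
#' @param c1,c2 cognitive and social learning factors.
#' @param clamp_frac velocity ceiling as a fraction of each dimension's range.
#' @param seed integer seed.
#' @param stagnation optional early-exit window: stop after this many
#'   iterations without global-best improvement (default `Inf`, off).
#' @param r_mode draw the random factors r1, r2 per dimension (the common
#'   convention) or once per particle.
#' @return an object of class `asir_swarm_config`.
#' @export
swarm_config <- function(n_particles = 8L, max_iterations = 20L,
                         w_max = 0.9, w_min = 0.4, c1 = 2.0, c2 = 2.0,
                         clamp_frac = 0.2, seed = 1L, stagnation = Inf,
                         r_mode = c("per_dim", "per_particle")) {
  if (w_min > w_max) abort_validation("w_min must be <= w_max")
  if (n_particles < 2) abort_validation("n_particles must be >= 2")
  if (max_iterations < 1) abort_validation("max_iterations must be >= 1")
  structure(list(n_particles = as.integer(n_particles),
                 max_iterations = as.integer(max_iterations),
                 w_max = w_max, w_min = w_min, c1 = c1, c2 = c2,
                 clamp_frac = clamp_frac, seed = as.integer(seed),
                 stagnation = stagnation, r_mode = match.arg(r_mode)),
            class = "asir_swarm_config")
}

#' Linearly decaying inertia weight
#'
#' `w(k) = w_max - (w_max - w_min) * k / K_max`: 0.9 at k = 0 and 0.4 at
#' k = K_max under the defaults.
#'
#' @param k iteration counter in `[0, K_max]`.
#' @param cfg a [swarm_config()].
#' @return the inertia weight at iteration `k`.
#' @export
inertia_weight <- function(k, cfg = swarm_config()) {
  if (k < 0 || k > cfg$max_iterations) {
    abort_validation("iteration k must lie in [0, K_max]")
  }
  cfg$w_max - (cfg$w_max - cfg$w_min) * k / cfg$max_iterations
}

#' Hyperparameter search space
#'
#' Each dimension is continuous, integer or categorical-ordinal. The internal
#' particle coordinate is always continuous: ordinal dimensions move on the
#' index scale 1..K and are decoded by nearest-value rounding (half up);
#' a dimension may declare `transform = "log10"` so the particle moves on a
#' log-scaled coordinate.
#'
#' @param dims list of dimension specs, each a list with `name`, `kind`
#'   ("continuous" | "integer" | "ordinal"), and either `lower`/`upper`
#'   (continuous/integer) or `values` (ordinal), plus optional `transform`.
#' @return an object of class `asir_search_space`.
#' @export
search_space <- function(dims) {
  for (d in dims) {
    if (d$kind == "ordinal") {
      if (length(d$values) < 2) abort_validation("ordinal dim '", d$name,
                                                 "' needs >= 2 values")
    } else if (!all(is.finite(c(d$lower, d$upper))) || d$lower >= d$upper) {
      abort_validation("dimension '", d$name, "' needs finite lower < upper")
    }
  }
  structure(list(dims = dims), class = "asir_search_space")
}

#' Default network search space
#'
#' Bounds chosen to contain the reported optimum (hidden width 64, 2 layers,
#' dropout 0.15, learning rate 0.002, 4 heads): hidden width in
#' \{16, 32, 64, 128\}, layers in \{1, 2, 3\}, dropout in `[0.05, 0.5]`,
#' learning rate log-scaled in `[1e-4, 1e-2]`, heads in \{2, 4, 8\}.
#'
#' @return an `asir_search_space`.
#' @export
default_search_space <- function() {
  search_space(list(
    list(name = "d_h", kind = "ordinal", values = c(16, 32, 64, 128)),
    list(name = "n_lstm_layers", kind = "ordinal", values = c(1, 2, 3)),
    list(name = "dropout", kind = "continuous", lower = 0.05, upper = 0.5),
    list(name = "learning_rate", kind = "continuous", lower = -4, upper = -2,
         transform = "log10"),
    list(name = "heads_per_scale", kind = "ordinal", values = c(2, 4, 8))
  ))
}

space_bounds <- function(space) {
  lower <- vapply(space$dims, function(d)
    if (d$kind == "ordinal") 1 else d$lower, numeric(1))
  upper <- vapply(space$dims, function(d)
    if (d$kind == "ordinal") length(d$values) else d$upper, numeric(1))
  list(lower = lower, upper = upper)
}

round_half_up <- function(x) floor(x + 0.5)

#' Decode a particle position into hyperparameter values
#'
#' Continuous dimensions pass through (after any declared transform);
#' integer and ordinal dimensions round to the nearest admissible value, ties
#' rounding half up. Decoding is idempotent on admissible points.
#'
#' @param position numeric vector, one coordinate per dimension.
#' @param space an `asir_search_space`.
#' @return named list of decoded values.
#' @export
decode_position <- function(position, space) {
  out <- list()
  for (i in seq_along(space$dims)) {
    d <- space$dims[[i]]
    x <- position[i]
    val <- switch(d$kind,
      continuous = x,
      integer = round_half_up(x),
      ordinal = d$values[min(max(round_half_up(x), 1), length(d$values))]
    )
    if (!is.null(d$transform) && d$transform == "log10" &&
        d$kind == "continuous") {
      val <- 10^val
    }
    out[[d$name]] <- val
  }
  out
}

# Overwrite hyperparameter fields with a decoded search point.
apply_search_point <- function(hp, decoded) {
  for (nm in names(decoded)) hp[[nm]] <- decoded[[nm]]
  hp$d_a <- as.integer(hp$d_h)
  hp$d_shared <- as.integer(hp$d_h)
  hp$d_h <- as.integer(hp$d_h)
  hp$n_lstm_layers <- as.integer(hp$n_lstm_layers)
  hp$heads_per_scale <- as.integer(hp$heads_per_scale)
  hp
}

#' One particle velocity/position update
#'
#' Applies the velocity rule
#' `v <- w v + c1 r1 (p_best - x) + c2 r2 (g_best - x)` followed by
#' `x <- x + v`, with the random factors drawn per dimension (or per
#' particle, by configuration), velocity clamped to `clamp_frac` of each
#' dimension's range and position clamped to the bounds.
#'
#' @param p particle state: list with `x`, `v`, `p_best`, `p_best_fit`.
#' @param g_best current global best position.
#' @param w inertia weight for this iteration.
#' @param cfg [swarm_config()].
#' @param space an `asir_search_space`.
#' @param r1,r2 optional fixed random factors (testing); drawn from the
#'   current RNG when `NULL`.
#' @return the updated particle state.
#' @export
update_particle <- function(p, g_best, w, cfg, space, r1 = NULL, r2 = NULL) {
  nd <- length(p$x)
  if (is.null(r1)) {
    r1 <- if (cfg$r_mode == "per_dim") stats::runif(nd) else
      rep(stats::runif(1), nd)
  }
  if (is.null(r2)) {
    r2 <- if (cfg$r_mode == "per_dim") stats::runif(nd) else
      rep(stats::runif(1), nd)
  }
  b <- space_bounds(space)
  vmax <- cfg$clamp_frac * (b$upper - b$lower)
  v <- w * p$v + cfg$c1 * r1 * (p$p_best - p$x) + cfg$c2 * r2 * (g_best - p$x)
  v <- pmin(pmax(v, -vmax), vmax)
  x <- pmin(pmax(p$x + v, b$lower), b$upper)
  p$v <- v
  p$x <- x
  p
}

#' Particle swarm search
#'
#' Minimizes `fitness` (called with the decoded position) over the search
#' space. Non-finite fitness marks the evaluation failed (+Inf) and the
#' search continues. The returned history of per-iteration global-best
#' fitness is monotone non-increasing.
#'
#' @param space an `asir_search_space`.
#' @param fitness function(decoded list) -> scalar to minimize.
#' @param cfg [swarm_config()].
#' @return list with `best_position`, `best_decoded`, `best_fitness`,
#'   `history` (length `max_iterations`), `trace` (iteration x particle
#'   fitness log) and `n_evaluations`.
#' @export
pso_optimize <- function(space, fitness, cfg = swarm_config()) {
  nd <- length(space$dims)
  b <- space_bounds(space)
  eval_fit <- function(x) {
    f <- tryCatch(fitness(decode_position(x, space)), error = function(e) Inf)
    if (!is.finite(f)) Inf else f
  }
  with_seed(cfg$seed, {
    particles <- lapply(seq_len(cfg$n_particles), function(i) {
      x <- b$lower + stats::runif(nd) * (b$upper - b$lower)
      v <- stats::runif(nd, -1, 1) * cfg$clamp_frac * (b$upper - b$lower)
      list(x = x, v = v, p_best = x, p_best_fit = Inf)
    })
    n_eval <- 0L
    trace <- NULL
    for (i in seq_along(particles)) {
      f <- eval_fit(particles[[i]]$x)
      n_eval <- n_eval + 1L
      particles[[i]]$p_best_fit <- f
      trace <- rbind(trace, data.frame(iteration = 0L, particle = i,
                                       fitness = f))
    }
    fits <- vapply(particles, `[[`, numeric(1), "p_best_fit")
    g_idx <- which.min(fits)
    g_best <- particles[[g_idx]]$p_best
    g_fit <- fits[g_idx]
    history <- numeric(cfg$max_iterations)
    since_improve <- 0L
    for (k in seq_len(cfg$max_iterations)) {
      w <- inertia_weight(k, cfg)
      improved <- FALSE
      for (i in seq_along(particles)) {
        particles[[i]] <- update_particle(particles[[i]], g_best, w, cfg,
                                          space)
        f <- eval_fit(particles[[i]]$x)
        n_eval <- n_eval + 1L
        trace <- rbind(trace, data.frame(iteration = k, particle = i,
                                         fitness = f))
        if (f < particles[[i]]$p_best_fit) {
          particles[[i]]$p_best_fit <- f
          particles[[i]]$p_best <- particles[[i]]$x
        }
        if (f < g_fit) {
          g_fit <- f
          g_best <- particles[[i]]$x
          improved <- TRUE
        }
      }
      history[k] <- g_fit
      since_improve <- if (improved) 0L else since_improve + 1L
      if (since_improve >= cfg$stagnation) {
        history <- history[seq_len(k)]
        break
      }
    }
    list(best_position = g_best, best_decoded = decode_position(g_best, space),
         best_fitness = g_fit, history = history, trace = trace,
         n_evaluations = n_eval)
  })
}

#' Fitness function: validation RMSE of a trained network
#'
#' Returns a closure that decodes a search point into hyperparameters,
#' trains on the fitting slice and returns the RMSE on the time-ordered
#' validation tail (standardized scale). Each evaluation trains at a fixed
#' seed derived from the point, so the search is reproducible.
#'
#' @param train an `asir_windows` training set.
#' @param hp base [hyperparameters()] supplying the non-searched fields.
#' @param cfg [training_config()] for the inner trainings.
#' @return function(decoded list) -> validation RMSE.
#' @export
make_fitness <- function(train, hp, cfg) {
  function(decoded) {
    hp_i <- apply_search_point(hp, decoded)
    cfg_i <- cfg
    cfg_i$seed <- derive_seed(cfg$seed,
                              paste0("pso_eval_",
                                     paste(signif(unlist(decoded), 6),
                                           collapse = "_")))
    mod <- train_model(train, hp_i, cfg_i)
    sqrt(mod$best_val_loss)
  }
}
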