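# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) pmax(x, 0)

#' Derive a reproducible sub-seed from a global seed and a stage name
#'
#' Every stochastic stage of the pipeline draws its seed deterministically
#' from one global seed plus the stage's name, so inserting a new stage never
#' silently reshuffles the randomness of later stages. The derived seed is
#' always a positive integer below 2^31.
#'
#' @param seed integer global seed.
#' @param name character stage name (e.g. "train", "pso").
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(name))
  codes <- utf8ToInt(name)
  h <- (seed %% 2147483647)
  for (c in codes) h <- (h * 31 + c) %% 2147483647
  as.integer(h %% 2147483562L + 1L)
}

# Evaluate code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    get(".Random.seed", envir = .GlobalEnv)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
        rm(".Random.seed", envir = .GlobalEnv)
      }
    } else {
      assign(".Random.seed", old, envir = .GlobalEnv)
    }
  })
  set.seed(seed)
  force(code)
}

# Series key used everywhere a (sex, age_band) pair must index a column.
series_key <- function(sex, age_band) paste(sex, age_band, sep = "|")

# Scale a flattened gradient so its global L2 norm is at most max_norm.
clip_gradient <- function(g, max_norm) {
  gn <- sqrt(sum(g^2))
  if (is.finite(max_norm) && gn > max_norm) g * (max_norm / gn) else g
}

abort_validation <- function(...) {
  stop(structure(class = c("asircast_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# Flatten all numeric leaves of a nested list into one vector, remembering
# the structure so the vector can be written back. Leaves whose name starts
# with "running_" (batch-norm buffers) and the "mask_" entries are excluded
# from training.
flatten_params <- function(params) {
  paths <- list()
  values <- list()
  walk <- function(x, path) {
    if (is.numeric(x)) {
      paths[[length(paths) + 1L]] <<- path
      values[[length(values) + 1L]] <<- x
    } else if (is.list(x)) {
      nms <- names(x)
      for (i in seq_along(x)) {
        nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
        if (startsWith(nm, "running_") || startsWith(nm, "frozen_")) next
        walk(x[[i]], c(path, i))
      }
    }
  }
  walk(params, integer(0))
  lens <- vapply(values, length, integer(1))
  list(vec = unlist(values, use.names = FALSE), paths = paths, lens = lens)
}

unflatten_params <- function(params, flat, vec) {
  offset <- 0L
  for (i in seq_along(flat$paths)) {
    n <- flat$lens[i]
    leaf <- vec[(offset + 1L):(offset + n)]
    path <- flat$paths[[i]]
    params <- assign_path(params, path, leaf)
    offset <- offset + n
  }
  params
}

assign_path <- function(x, path, leaf) {
  if (length(path) == 1L) {
    old <- x[[path]]
    attributes(leaf) <- attributes(old)
    x[[path]] <- leaf
  } else {
    x[[path[1L]]] <- assign_path(x[[path[1L]]], path[-1L], leaf)
  }
  x
}
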