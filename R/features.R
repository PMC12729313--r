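#' Trailing moving average with expanding warm-up
#'
#' Right-aligned: the value at year t is the mean of the last `k`
#' observations up to and including t. During the first `k - 1` years the
#' mean of all observations so far is used (expanding window), so the output
#' has the same length as the input and uses no future information.
#'
#' @param x numeric series.
#' @param k window length in years.
#' @return numeric series of `length(x)`.
#' @export
moving_average <- function(x, k) {
  if (!is.numeric(k) || length(k) != 1 || k < 1) {
    abort_validation("window length k must be >= 1")
  }
  n <- length(x)
  out <- numeric(n)
  for (t in seq_len(n)) {
    j <- max(1L, t - as.integer(k) + 1L)
    out[t] <- mean(x[j:t])
  }
  out
}

#' Residual (short-term fluctuation) feature
#'
#' The original value minus its three-year trailing moving average, so that
#' residual + trend reconstructs the series exactly.
#'
#' @param x numeric series.
#' @return numeric series.
#' @export
residual_feature <- function(x) x - moving_average(x, 3)

#' Trailing rolling standard deviation (volatility)
#'
#' Population-formula SD over the trailing `k`-year window, with the same
#' expanding warm-up as [moving_average()]. A single observation has SD 0.
#'
#' @param x numeric series.
#' @param k window length (default 3).
#' @return non-negative numeric series.
#' @export
volatility <- function(x, k = 3) {
  if (k < 1) abort_validation("window length k must be >= 1")
  n <- length(x)
  out <- numeric(n)
  for (t in seq_len(n)) {
    j <- max(1L, t - as.integer(k) + 1L)
    w <- x[j:t]
    out[t] <- sqrt(mean((w - mean(w))^2))
  }
  out
}

#' Exponentially weighted moving average
#'
#' `s_1 = x_1`; `s_t = decay * x_t + (1 - decay) * s_{t-1}`.
#'
#' @param x numeric series.
#' @param decay smoothing weight on the current observation, in (0, 1).
#' @return numeric series.
#' @export
ewma <- function(x, decay = 0.3) {
  if (!is.numeric(decay) || decay <= 0 || decay >= 1) {
    abort_validation("decay must lie strictly in (0, 1)")
  }
  n <- length(x)
  out <- numeric(n)
  out[1] <- x[1]
  for (t in seq_len(n)[-1]) out[t] <- decay * x[t] + (1 - decay) * out[t - 1]
  out
}

#' Male minus female difference columns
#'
#' For each age band i the column Male_i - Female_i is computed (on whatever
#' scale the panel is on, normally standardized) and the identical column is
#' assigned to both the male-slot and the female-slot for that band, yielding
#' one column per series but only one distinct series per band.
#'
#' @param panel an `asir_panel` containing both sexes for every band.
#' @return numeric matrix, years x series, series-key column names.
#' @export
sex_difference <- function(panel) {
  stopifnot(inherits(panel, "asir_panel"))
  bands <- unique(panel$info$age_band)
  out <- matrix(NA_real_, nrow(panel$values), ncol(panel$values),
                dimnames = dimnames(panel$values))
  for (b in bands) {
    mk <- series_key("Male", b)
    fk <- series_key("Female", b)
    if (!(mk %in% colnames(panel$values)) || !(fk %in% colnames(panel$values))) {
      abort_validation("band ", b, " is missing one sex")
    }
    d <- panel$values[, mk] - panel$values[, fk]
    for (key in panel$info$key[panel$info$age_band == b]) out[, key] <- d
  }
  out
}

feature_blocks <- c("original", "trend", "residual", "volatility",
                    "sex_difference", "ewma")

#' Expand a standardized panel into the engineered feature matrix
#'
#' Each of the panel's series contributes six columns, in fixed block order:
#' the original standardized value, its 3-year trailing moving average
#' (trend), the residual from that trend, the 3-year rolling SD (volatility),
#' the male-minus-female gap for its age band, and an EWMA smoother
#' (decay 0.3). A 24-series panel therefore yields D = 144 columns. The
#' 5- and 7-year moving averages are computed as diagnostics but are not part
#' of the model input, which keeps the dimension accounting at exactly
#' 6 columns per series.
#'
#' @param panel a standardized `asir_panel` with both sexes complete.
#' @param ewma_decay EWMA decay (default 0.3).
#' @return an object of class `asir_features`: list with the `X` matrix
#'   (years x D), `years`, a column `manifest` (column, name, block, sex,
#'   age_band) and `diagnostics` (5- and 7-year moving averages).
#' @export
build_feature_matrix <- function(panel, ewma_decay = 0.3) {
  stopifnot(inherits(panel, "asir_panel"))
  ns <- n_series(panel)
  ny <- length(panel$years)
  sd_block <- sex_difference(panel)
  blocks <- list(
    original = panel$values,
    trend = apply(panel$values, 2, moving_average, k = 3),
    residual = apply(panel$values, 2, residual_feature),
    volatility = apply(panel$values, 2, volatility),
    sex_difference = sd_block,
    ewma = apply(panel$values, 2, ewma, decay = ewma_decay)
  )
  X <- do.call(cbind, blocks)
  manifest <- data.frame(
    column = seq_len(6L * ns),
    name = paste(rep(feature_blocks, each = ns), rep(panel$info$key, 6),
                 sep = "|"),
    block = rep(feature_blocks, each = ns),
    sex = rep(panel$info$sex, 6),
    age_band = rep(panel$info$age_band, 6),
    stringsAsFactors = FALSE
  )
  colnames(X) <- manifest$name
  if (anyNA(X) || any(!is.finite(X))) {
    abort_validation("non-finite feature values after warm-up handling")
  }
  structure(list(
    X = X, years = panel$years, manifest = manifest,
    diagnostics = list(ma5 = apply(panel$values, 2, moving_average, k = 5),
                       ma7 = apply(panel$values, 2, moving_average, k = 7))
  ), class = "asir_features")
}

#' @export
print.asir_features <- function(x, ...) {
  cat(sprintf("<asir_features> %d years x %d columns (%d series x %d blocks)\n",
              nrow(x$X), ncol(x$X), ncol(x$X) / length(feature_blocks),
              length(feature_blocks)))
  invisible(x)
}

#' Frame supervised samples with a sliding window
#'
#' One sample per feasible target year: the input is the `window`-year block
#' of feature rows ending exactly `horizon` years before the target year, the
#' target is the standardized ASIR of all series at the target year. For a
#' 32-year panel with a 10-year window and 1-year horizon this yields 22
#' samples with target years 2000-2021.
#'
#' @param fm an `asir_features` matrix.
#' @param target_panel the standardized `asir_panel` supplying targets (must
#'   share the year index with `fm`).
#' @param window input window length T in years (default 10).
#' @param horizon forecast step in years (default 1).
#' @return an object of class `asir_windows`: `inputs` (B x T x D array),
#'   `targets` (B x G), `target_years`, plus the manifest and group table.
#' @export
make_windows <- function(fm, target_panel, window = 10L, horizon = 1L) {
  stopifnot(inherits(fm, "asir_features"), inherits(target_panel, "asir_panel"))
  if (!identical(fm$years, target_panel$years)) {
    abort_validation("feature matrix and target panel must share the year index")
  }
  ny <- nrow(fm$X)
  B <- ny - window - horizon + 1L
  if (B < 1) abort_validation("series too short: need > window + horizon years")
  D <- ncol(fm$X)
  G <- n_series(target_panel)
  inputs <- array(NA_real_, c(B, window, D))
  targets <- matrix(NA_real_, B, G, dimnames = list(NULL, target_panel$info$key))
  target_years <- integer(B)
  for (i in seq_len(B)) {
    inputs[i, , ] <- fm$X[i:(i + window - 1L), , drop = FALSE]
    t_row <- i + window + horizon - 1L
    targets[i, ] <- target_panel$values[t_row, ]
    target_years[i] <- fm$years[t_row]
  }
  structure(list(inputs = inputs, targets = targets,
                 target_years = target_years, manifest = fm$manifest,
                 groups = target_panel$info, window = as.integer(window),
                 horizon = as.integer(horizon)),
            class = "asir_windows")
}

#' @export
print.asir_windows <- function(x, ...) {
  cat(sprintf("<asir_windows> %d samples x (T=%d x D=%d) -> %d groups; targets %d-%d\n",
              nrow(x$targets), x$window, dim(x$inputs)[3], ncol(x$targets),
              min(x$target_years), max(x$target_years)))
  invisible(x)
}

# Subset a windowed dataset by sample index, keeping metadata.
windows_subset <- function(ds, idx) {
  structure(list(inputs = ds$inputs[idx, , , drop = FALSE],
                 targets = ds$targets[idx, , drop = FALSE],
                 target_years = ds$target_years[idx], manifest = ds$manifest,
                 groups = ds$groups, window = ds$window, horizon = ds$horizon),
            class = "asir_windows")
}

#' Sequential train/test split by target year
#'
#' Training samples are those with target year `<= boundary_year`; test
#' samples follow. All test targets postdate all training targets
#' (walk-forward split), so no training target or training input row is
#' affected by post-boundary values.
#'
#' @param ds an `asir_windows` dataset.
#' @param boundary_year last training target year (default 2016).
#' @return list with elements `train` and `test`, both `asir_windows`.
#' @export
split_sequential <- function(ds, boundary_year = 2016L) {
  stopifnot(inherits(ds, "asir_windows"))
  tr <- which(ds$target_years <= boundary_year)
  te <- which(ds$target_years > boundary_year)
  if (!length(tr) || !length(te)) {
    abort_validation("boundary_year ", boundary_year,
                     " leaves an empty train or test partition")
  }
  list(train = windows_subset(ds, tr), test = windows_subset(ds, te))
}
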