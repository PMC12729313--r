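#' Incidence panel container
#'
#' An `asir_panel` holds a sex x age-band x year grid of age-standardized
#' incidence rates: a numeric matrix with one row per calendar year and one
#' column per (sex, age band) series, plus a series-information table. All
#' series share an identical, gap-free year range. Raw panels must be
#' non-negative everywhere; standardized panels (produced by
#' [apply_standardizer()]) carry `standardized = TRUE` and may be negative.
#'
#' @param values numeric matrix, years x series.
#' @param years contiguous integer year vector (one per row).
#' @param info data.frame with columns `sex` and `age_band`, one row per
#'   series, in column order.
#' @param standardized logical; skip the non-negativity check when TRUE.
#' @return an object of class `asir_panel`.
#' @export
new_panel <- function(values, years, info, standardized = FALSE) {
  values <- as.matrix(values)
  years <- as.integer(years)
  if (nrow(values) != length(years)) {
    abort_validation("values must have one row per year")
  }
  if (length(years) > 1 && any(diff(years) != 1L)) {
    abort_validation("year range must be contiguous with no gaps")
  }
  if (nrow(info) != ncol(values)) {
    abort_validation("info must have one row per series column")
  }
  if (!standardized && any(values < 0, na.rm = TRUE)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    abort_validation("negative ASIR at year ", years[bad[1]], ", series ",
                     series_key(info$sex[bad[2]], info$age_band[bad[2]]))
  }
  if (anyNA(values)) abort_validation("panel contains missing values")
  keys <- series_key(info$sex, info$age_band)
  if (anyDuplicated(keys)) {
    abort_validation("duplicate series: ", keys[duplicated(keys)][1])
  }
  colnames(values) <- keys
  structure(list(values = values, years = years,
                 info = data.frame(sex = info$sex, age_band = info$age_band,
                                   key = keys, stringsAsFactors = FALSE)),
            class = "asir_panel", standardized = standardized)
}

#' @export
print.asir_panel <- function(x, ...) {
  cat(sprintf("<asir_panel> %d series (%s) x %d years (%d-%d)%s\n",
              ncol(x$values),
              paste(unique(x$info$sex), collapse = "/"),
              length(x$years), min(x$years), max(x$years),
              if (isTRUE(attr(x, "standardized"))) " [standardized]" else ""))
  invisible(x)
}

#' @export
as.data.frame.asir_panel <- function(x, ...) {
  data.frame(
    year = rep(x$years, times = ncol(x$values)),
    sex = rep(x$info$sex, each = length(x$years)),
    age_group = rep(x$info$age_band, each = length(x$years)),
    value = as.vector(x$values),
    stringsAsFactors = FALSE
  )
}

#' Number of series in a panel
#' @param panel an `asir_panel`.
#' @return integer count of (sex, age band) series.
#' @export
n_series <- function(panel) ncol(panel$values)

#' Read a long-format GBD-style incidence CSV
#'
#' Expects (in any column order, header-driven) the columns `year`, `sex`,
#' `age_group`, `value`; optional `lower`/`upper` columns are ignored. Rows
#' are sorted by year within each series. Duplicate (year, sex, age_group)
#' rows, year gaps, negative rates and missing columns are all rejected with
#' an error naming the offender.
#'
#' @param path CSV file path.
#' @return an [new_panel()] object.
#' @export
read_gbd_csv <- function(path) {
  if (!file.exists(path)) abort_validation("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("year", "sex", "age_group", "value")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort_validation("missing required column(s): ", paste(missing, collapse = ", "))
  }
  # normalize sex labels case-insensitively to Title case
  df$sex <- paste0(toupper(substr(df$sex, 1, 1)),
                   tolower(substr(df$sex, 2, nchar(df$sex))))
  key <- series_key(df$sex, df$age_group)
  dup <- duplicated(paste(df$year, key))
  if (any(dup)) {
    abort_validation("duplicate row for year ", df$year[dup][1], ", series ",
                     key[dup][1])
  }
  if (any(df$value < 0, na.rm = TRUE)) {
    i <- which(df$value < 0)[1]
    abort_validation("negative ASIR at year ", df$year[i], ", series ", key[i])
  }
  years <- sort(unique(df$year))
  if (length(years) > 1 && any(diff(years) != 1L)) {
    abort_validation("global year range has gaps: ",
                     paste(years[c(which(diff(years) != 1L))], collapse = ", "))
  }
  # order series by sex (appearance order) then age band lower bound
  ukey <- unique(key)
  uinfo <- data.frame(sex = df$sex[match(ukey, key)],
                      age_band = df$age_group[match(ukey, key)],
                      stringsAsFactors = FALSE)
  lower_bound <- suppressWarnings(as.numeric(sub("[^0-9].*$", "", uinfo$age_band)))
  ord <- order(match(uinfo$sex, unique(uinfo$sex)),
               ifelse(is.na(lower_bound), Inf, lower_bound), uinfo$age_band)
  uinfo <- uinfo[ord, , drop = FALSE]
  ukey <- ukey[ord]
  values <- matrix(NA_real_, length(years), length(ukey))
  for (j in seq_along(ukey)) {
    rows <- df[key == ukey[j], , drop = FALSE]
    if (nrow(rows) != length(years) ||
        !setequal(rows$year, years)) {
      miss <- setdiff(years, rows$year)
      abort_validation("series ", ukey[j], " is missing year(s): ",
                       paste(miss, collapse = ", "))
    }
    values[, j] <- rows$value[match(years, rows$year)]
  }
  new_panel(values, years, uinfo)
}

#' Fit a per-series Z-score standardizer
#'
#' Computes each series' mean and standard deviation (population formula,
#' divide by n, so the standardized fit window has mean exactly 0 and SD
#' exactly 1) on the stated `fit_years` only. Fitting on the training years
#' only is the leakage-free choice; pass the full year range for the
#' fit-on-everything reading.
#'
#' @param panel an `asir_panel`.
#' @param fit_years integer years to fit on (subset of `panel$years`);
#'   default all years.
#' @return an object of class `asir_scaler` with per-series `mean` and `sd`.
#' @export
fit_standardizer <- function(panel, fit_years = NULL) {
  stopifnot(inherits(panel, "asir_panel"))
  fit_years <- fit_years %||% panel$years
  if (!all(fit_years %in% panel$years)) {
    abort_validation("fit_years must be a subset of the panel's years")
  }
  rows <- match(fit_years, panel$years)
  sub <- panel$values[rows, , drop = FALSE]
  mu <- colMeans(sub)
  n <- nrow(sub)
  sdv <- sqrt(colMeans(sweep(sub, 2, mu)^2))
  if (any(sdv <= 1e-12)) {
    abort_validation("constant series on the fit window: ",
                     colnames(sub)[which(sdv <= 1e-12)][1])
  }
  structure(list(mean = mu, sd = sdv,
                 fit_years = range(fit_years), keys = colnames(panel$values)),
            class = "asir_scaler")
}

#' Standardize a panel with a fitted scaler
#' @param panel an `asir_panel`.
#' @param scaler an `asir_scaler` covering every series in `panel`.
#' @return a standardized `asir_panel` (values may be negative).
#' @export
apply_standardizer <- function(panel, scaler) {
  stopifnot(inherits(panel, "asir_panel"), inherits(scaler, "asir_scaler"))
  keys <- colnames(panel$values)
  unknown <- setdiff(keys, names(scaler$mean))
  if (length(unknown)) abort_validation("scaler has no series ", unknown[1])
  z <- sweep(sweep(panel$values, 2, scaler$mean[keys]), 2, scaler$sd[keys], "/")
  new_panel(z, panel$years, panel$info, standardized = TRUE)
}

#' Map standardized values back to the rate scale
#'
#' The inverse of [apply_standardizer()]: `invert(apply(x))` is the identity
#' to 1e-9 relative tolerance. Accepts a matrix (or vector) whose columns are
#' named with series keys `"sex|age_band"`.
#'
#' @param values numeric matrix/vector with series-key column names.
#' @param scaler an `asir_scaler`.
#' @return values on the per-100,000 rate scale.
#' @export
invert_standardizer <- function(values, scaler) {
  stopifnot(inherits(scaler, "asir_scaler"))
  if (is.null(dim(values))) values <- matrix(values, 1,
                                             dimnames = list(NULL, names(values)))
  keys <- colnames(values)
  if (is.null(keys)) abort_validation("values must carry series-key column names")
  unknown <- setdiff(keys, names(scaler$mean))
  if (length(unknown)) abort_validation("scaler has no series ", unknown[1])
  sweep(sweep(values, 2, scaler$sd[keys], "*"), 2, scaler$mean[keys], "+")
}

#' Serialize / restore a scaler as JSON
#' @param scaler an `asir_scaler`.
#' @param path JSON file path.
#' @return `path` (write) or an `asir_scaler` (read).
#' @export
write_scaler_json <- function(scaler, path) {
  jsonlite::write_json(list(
    fit_years = scaler$fit_years,
    series = lapply(seq_along(scaler$mean), function(i) {
      list(key = names(scaler$mean)[i], mean = scaler$mean[[i]],
           sd = scaler$sd[[i]])
    })
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scaler_json
#' @export
read_scaler_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    mean = stats::setNames(raw$series$mean, raw$series$key),
    sd = stats::setNames(raw$series$sd, raw$series$key),
    fit_years = as.integer(raw$fit_years), keys = raw$series$key
  ), class = "asir_scaler")
}
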