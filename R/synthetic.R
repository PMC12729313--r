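#' Specification of a synthetic sex-age incidence panel
#'
#' Describes a Global Burden of Disease style panel of age-standardized
#' incidence rates (ASIR, cases per 100,000): two sexes crossed with a set of
#' five-year age bands, one observation per calendar year. With the defaults
#' (12 bands from 40-44 to 95+, years 1990-2021) the panel contains 24 series
#' of 32 annual observations each.
#'
#' The generator draws, per age band, a female baseline level rising with age
#' and a smooth trend of the requested kind; the male series is the female
#' series plus a systematic per-band offset. Observation noise is independent
#' Gaussian per (series, year), heteroscedastic across bands (its standard
#' deviation scales with the band's baseline level relative to the average
#' band), and generated values are clipped at zero because a rate cannot be
#' negative.
#'
#' @param n_age_bands number of five-year age bands (default 12, starting at
#'   40-44 per the GBD convention).
#' @param sexes labels for the two sexes.
#' @param year_start,year_end first and last calendar year (inclusive).
#' @param trend_kind one of "linear", "logistic", "piecewise". Piecewise uses
#'   one change-point with independent slopes before and after it — the
#'   simplest structure that defeats a purely linear forecaster.
#' @param changepoint_year calendar year of the change-point (piecewise and
#'   logistic midpoint); `NULL` means the middle of the year range.
#' @param noise_sd base noise standard deviation in per-100,000 rate units
#'   (the band with average baseline level gets exactly this SD).
#' @param sex_offset additive male minus female gap per age band, in
#'   per-100,000 units; recycled to `n_age_bands`.
#' @param age_band_labels optional character labels, ordered by lower bound.
#' @param seed integer seed; panels are bit-identical for a fixed seed.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_age_bands = 12L,
                           sexes = c("Male", "Female"),
                           year_start = 1990L, year_end = 2021L,
                           trend_kind = c("piecewise", "linear", "logistic"),
                           changepoint_year = NULL,
                           noise_sd = 2,
                           sex_offset = 25,
                           age_band_labels = NULL,
                           seed = 42L) {
  trend_kind <- match.arg(trend_kind)
  n_years <- year_end - year_start + 1
  if (n_years < 12) {
    abort_validation("year range must span at least 12 years (window + horizon), got ",
                     n_years)
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    abort_validation("noise_sd must be >= 0, got ", noise_sd)
  }
  if (length(sexes) != 2L) abort_validation("exactly two sex labels required")
  if (is.null(age_band_labels)) {
    age_band_labels <- gbd_age_bands(n_age_bands)
  }
  if (length(age_band_labels) != n_age_bands) {
    abort_validation("need ", n_age_bands, " age band labels, got ",
                     length(age_band_labels))
  }
  if (is.null(changepoint_year)) {
    changepoint_year <- floor((year_start + year_end) / 2)
  }
  if (changepoint_year <= year_start || changepoint_year >= year_end) {
    abort_validation("changepoint_year must lie strictly inside the year range")
  }
  structure(list(
    n_age_bands = as.integer(n_age_bands), sexes = sexes,
    year_start = as.integer(year_start), year_end = as.integer(year_end),
    trend_kind = trend_kind, changepoint_year = as.integer(changepoint_year),
    noise_sd = noise_sd,
    sex_offset = rep_len(sex_offset, n_age_bands),
    age_band_labels = age_band_labels, seed = as.integer(seed)
  ), class = "synthetic_spec")
}

# GBD five-year band labels starting at 40-44; the last band is open-ended.
gbd_age_bands <- function(n) {
  lows <- 40 + 5 * (seq_len(n) - 1)
  labs <- paste0(lows, "-", lows + 4)
  labs[n] <- paste0(lows[n], "+")
  labs
}

#' Generate a synthetic incidence panel
#'
#' Produces a complete [asir_panel]: one series per (sex, age band), one value
#' per year. The ground-truth trend parameters are attached as the `truth`
#' attribute so parameter-recovery tests can compare against them.
#'
#' @param spec a [synthetic_spec()].
#' @return an `asir_panel` with attribute `truth`.
#' @export
generate_panel <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  years <- spec$year_start:spec$year_end
  nb <- spec$n_age_bands
  with_seed(spec$seed, {
    base <- 80 + 40 * seq_len(nb) + stats::runif(nb, -10, 10)
    truth <- list(trend_kind = spec$trend_kind,
                  changepoint_year = spec$changepoint_year,
                  base = base, sex_offset = spec$sex_offset,
                  noise_sd = spec$noise_sd)
    trend <- switch(spec$trend_kind,
      linear = {
        truth$slope <- stats::runif(nb, -1, 5)
        outer(years - spec$year_start, truth$slope) +
          matrix(base, length(years), nb, byrow = TRUE)
      },
      logistic = {
        truth$amplitude <- stats::runif(nb, 40, 150)
        truth$scale <- stats::runif(nb, 2, 5)
        vapply(seq_len(nb), function(b) {
          base[b] + truth$amplitude[b] /
            (1 + exp(-(years - spec$changepoint_year) / truth$scale[b]))
        }, numeric(length(years)))
      },
      piecewise = {
        truth$slope_before <- stats::runif(nb, 0.5, 4)
        truth$slope_after <- stats::runif(nb, -5, 1)
        cp <- spec$changepoint_year
        m <- matrix(0, length(years), nb)
        for (b in seq_len(nb)) {
          pre <- pmin(years, cp) - spec$year_start
          post <- pmax(years - cp, 0)
          m[, b] <- base[b] + truth$slope_before[b] * pre +
            truth$slope_after[b] * post
        }
        m
      })
    # female gets the baseline trend, male = female + offset
    female_idx <- match("Female", spec$sexes)
    values <- matrix(NA_real_, length(years), 2L * nb)
    info <- expand.grid(age_band = spec$age_band_labels, sex = spec$sexes,
                        stringsAsFactors = FALSE)[, c("sex", "age_band")]
    # order series sex-major in the order given by spec$sexes
    rel_sd <- spec$noise_sd * base / mean(base)
    for (s in seq_along(spec$sexes)) {
      off <- if (s == female_idx) rep(0, nb) else spec$sex_offset
      for (b in seq_len(nb)) {
        col <- (s - 1L) * nb + b
        noise <- stats::rnorm(length(years), 0, rel_sd[b])
        values[, col] <- pmax(trend[, b] + off[b] + noise, 0)
      }
    }
    panel <- new_panel(values, years, info)
    attr(panel, "truth") <- truth
    panel
  })
}

#' Write a panel to a long-format GBD-style CSV
#'
#' Columns are `year,sex,age_group,value`, one row per (year, sex, age band).
#' The inverse of [read_gbd_csv()].
#'
#' @param panel an `asir_panel`.
#' @param path file path to write.
#' @return the path, invisibly.
#' @export
write_gbd_csv <- function(panel, path) {
  df <- as.data.frame(panel)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
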