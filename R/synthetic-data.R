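# Synthetic CBF3 expression time series emulating the statistical structure
# of diurnal microarray data: a sharp unimodal daily waveform peaking 8 h
# after dawn, identical phase in every photoperiod (including constant
# light), plus zero-truncated Gaussian measurement noise.

#' Deterministic CBF3 expression template
#'
#' A 24-h periodic raised-cosine bump centred `peak_zt` hours after dawn on
#' a low constant baseline. The same waveform is used for every light
#' regime: the peak phase of CBF3 expression is robust against photoperiod
#' and persists in constant light.
#'
#' @param regime A [light_regime()] (kept for interface symmetry; the
#'   template does not depend on it).
#' @param t Time(s) in hours after dawn, >= 0.
#' @param peak_zt Peak phase, hours after dawn (default 8).
#' @param fwhm Full width at half maximum of the peak, hours (default 4;
#'   the raised cosine has support `2 * fwhm` around the peak).
#' @param baseline Baseline expression as a fraction of peak (default 0.05).
#' @param peak Peak expression in arbitrary units (default 1).
#' @return Expression value(s), a.u.
#' @examples
#' cbf3_template(light_regime(12), c(0, 4, 8, 12))
#' @export
cbf3_template <- function(regime, t, peak_zt = 8, fwhm = 4,
                          baseline = 0.05, peak = 1) {
  if (any(t < 0)) abort("`t` must be non-negative.")
  delta <- (t - peak_zt) %% 24
  delta <- ifelse(delta > 12, delta - 24, delta)
  bump <- ifelse(abs(delta) <= fwhm,
                 0.5 * (1 + cos(pi * delta / fwhm)), 0)
  peak * (baseline + (1 - baseline) * bump)
}

#' Generate a synthetic multi-regime CBF3 expression dataset
#'
#' Samples the [cbf3_template()] on a time grid in each regime and adds
#' independent Gaussian noise truncated at zero. Identical seed and
#' settings always give the identical dataset.
#'
#' @param regimes List of [light_regime()]s (default [standard_regimes()]).
#' @param times Sampling times in hours after dawn (default
#'   `seq(0, 48, by = 4)`, the standard diurnal microarray design).
#' @param noise_sd Noise standard deviation in a.u. (default 0.1, i.e. 10%
#'   of the template peak); must be >= 0.
#' @param seed Integer seed.
#' @param ... Template settings passed to [cbf3_template()].
#' @return A `cbf_dataset` tibble with columns `regime`, `time_h`,
#'   `expression`, carrying `noise_sd` and `seed` as attributes.
#' @examples
#' d <- generate_dataset(seed = 1)
#' nrow(d)  # 13 time points x 4 regimes = 52
#' @export
generate_dataset <- function(regimes = standard_regimes(),
                             times = seq(0, 48, by = 4),
                             noise_sd = 0.1, seed = 1, ...) {
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  if (any(diff(times) <= 0)) abort("`times` must be strictly increasing.")
  regimes <- lapply(regimes, as_regime)
  labels <- vapply(regimes, `[[`, "", "label")
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  out <- purrr::map2_dfr(regimes, labels, function(rg, lb) {
    mu <- cbf3_template(rg, times, ...)
    tibble(regime = lb, time_h = times,
           expression = pmax(0, mu + rnorm(length(times), 0, noise_sd)))
  })
  structure(out, class = c("cbf_dataset", class(tibble())),
            regimes = regimes, noise_sd = noise_sd, seed = seed,
            template_args = list(...))
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Write a dataset as one CSV per regime
#'
#' Files are named `expression_<label>.csv` (with `/` replaced by `-`) and
#' contain columns `time_h`, `expression`.
#'
#' @param dataset A `cbf_dataset` from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Character vector of file paths, invisibly.
#' @export
write_dataset_csv <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(unique(dataset$regime), function(lb) {
    path <- file.path(dir, paste0("expression_", gsub("/", "-", lb), ".csv"))
    readr::write_csv(dplyr::select(dplyr::filter(dataset, regime == lb),
                                   time_h, expression), path)
    path
  }, "")
  invisible(paths)
}

#' Read a multi-regime dataset from per-regime CSV files
#'
#' @param paths Named character vector of CSV paths; names are regime
#'   labels (e.g. `"12L/12D"`).
#' @return A `cbf_dataset` tibble.
#' @export
read_dataset_csv <- function(paths) {
  if (is.null(names(paths))) abort("`paths` must be named by regime label.")
  out <- purrr::imap_dfr(paths, function(p, lb) {
    d <- readr::read_csv(p, show_col_types = FALSE)
    tibble(regime = lb, time_h = d$time_h, expression = d$expression)
  })
  structure(out, class = c("cbf_dataset", class(tibble())),
            regimes = lapply(names(paths), as_regime))
}
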