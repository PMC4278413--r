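# CBF3 transcription submodel: Hill-function production driven by clock
# regulators, exponential mRNA decay.
#
#   dC/dt = v_max * prod_A A^n/(A^n + K_A^n) * prod_R K_R^n/(K_R^n + R^n) - d*C
#
# The production term is a known function of time once the clock trajectory
# is fixed, so the ODE is linear in C and is integrated exactly for a
# piecewise-linear production signal on a fine internal grid.

#' CBF3 submodel parameters
#'
#' @param v_max Maximal transcription rate (a.u. per hour), > 0.
#' @param K Named numeric vector of half-saturation constants (a.u.), one
#'   per regulator, all > 0.
#' @param d mRNA degradation rate (per hour), > 0.
#' @param hill_n Hill exponent (dimensionless, >= 1). Fixed by convention at
#'   2 and never counted as a free parameter.
#' @return A `cbf_params` object.
#' @examples
#' cbf_params(1, c(LHY_CCA1 = 0.3, EC = 0.1, TOC1 = 0.5), d = 1)
#' @export
cbf_params <- function(v_max, K, d, hill_n = 2) {
  if (!is.numeric(v_max) || length(v_max) != 1 || v_max <= 0)
    abort("`v_max` must be a single positive number.")
  if (!is.numeric(d) || length(d) != 1 || d <= 0)
    abort("`d` must be a single positive number.")
  if (hill_n < 1) abort("`hill_n` must be >= 1.")
  if (length(K)) {
    if (is.null(names(K)) || any(names(K) == ""))
      abort("`K` must be a named numeric vector (one entry per regulator).")
    if (any(!is.finite(K)) || any(K <= 0))
      abort("All half-saturation constants must be positive and finite.")
    bad <- setdiff(names(K), clock_species())
    if (length(bad)) abort(paste0("Unknown species in `K`: ", toString(bad)))
  }
  structure(list(v_max = v_max, K = K, d = d, hill_n = hill_n),
            class = "cbf_params")
}

#' @export
print.cbf_params <- function(x, ...) {
  cat("<CBF3 parameters> v_max =", signif(x$v_max, 4),
      " d =", signif(x$d, 4), " n =", x$hill_n, "\n K:",
      paste0(names(x$K), " = ", signif(x$K, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Serialise parameters to JSON
#' @param params A [cbf_params()].
#' @return A JSON string.
#' @export
params_to_json <- function(params) {
  jsonlite::toJSON(list(v_max = params$v_max, K = as.list(params$K),
                        d = params$d, hill_n = params$hill_n),
                   auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Deserialise parameters from JSON
#' @param json JSON string or path produced by [params_to_json()].
#' @return A [cbf_params()].
#' @export
params_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  cbf_params(x$v_max, unlist(x$K), x$d, x$hill_n)
}

# vectorised Hill production over a times x species abundance matrix
production_from_matrix <- function(mat, arch, params) {
  n <- params$hill_n
  p <- rep(params$v_max, nrow(mat))
  for (sp in arch$activators) {
    a <- mat[, sp]^n
    p <- p * a / (a + params$K[[sp]]^n)
  }
  for (sp in arch$repressors) {
    kn <- params$K[[sp]]^n
    p <- p * kn / (kn + mat[, sp]^n)
  }
  unname(p)
}

#' Instantaneous CBF3 transcription rate
#'
#' Multiplicative combination of independent Hill terms, one per regulator,
#' sharing a single fixed exponent: activators contribute
#' `A^n/(A^n + K_A^n)` and repressors `K_R^n/(K_R^n + R^n)`, scaled by
#' `v_max`. The rate lies in `[0, v_max]`, increases in every activator and
#' decreases in every repressor.
#'
#' @param arch A [cbf_architecture()].
#' @param params A [cbf_params()] with a `K` entry for every regulator.
#' @param state Named numeric vector (or a data frame / matrix with one
#'   column per species) of non-negative clock abundances.
#' @return Numeric production rate(s), a.u. per hour.
#' @examples
#' arch <- cbf_architecture("LHY_CCA1", c("EC", "TOC1"))
#' pars <- cbf_params(1, c(LHY_CCA1 = 1, EC = 1, TOC1 = 1), d = 1)
#' production_rate(arch, pars, c(LHY_CCA1 = 1, EC = 1, TOC1 = 1))  # 0.125
#' @export
production_rate <- function(arch, params, state) {
  stopifnot(inherits(arch, "cbf_architecture"), inherits(params, "cbf_params"))
  miss <- setdiff(regulators(arch), names(params$K))
  if (length(miss)) abort(paste0("Missing K for: ", toString(miss)))
  if (is.null(dim(state))) state <- matrix(state, nrow = 1,
                                           dimnames = list(NULL, names(state)))
  state <- as.matrix(state)
  if (any(state[, regulators(arch), drop = FALSE] < 0))
    abort("Clock abundances must be non-negative.")
  production_from_matrix(state, arch, params)
}

# exact update of dC/dt = p(t) - d*C over uniform steps h, with p piecewise
# linear between grid points; vectorised with stats::filter (recursive form)
integrate_linear_decay <- function(p, d, h, c0) {
  n <- length(p)
  a  <- exp(-d * h)
  e1 <- (1 - a) / d
  e2 <- (h - e1) / d
  x <- p[-n] * (e1 - e2 / h) + p[-1] * (e2 / h)
  c(c0, as.numeric(stats::filter(x, a, method = "recursive", init = c0)))
}

#' Simulate CBF3 mRNA dynamics
#'
#' Integrates `dC/dt = production_rate(t) - d * C` over the clock
#' trajectory's grid. The clock waveforms are evaluated on a fine internal
#' grid (exactly, when the trajectory carries its generating waveforms;
#' otherwise by linear interpolation), and the linear mRNA equation is then
#' solved with an exact exponential-integrator step for piecewise-linear
#' production, so the result is non-negative by construction.
#'
#' @param clock A `cbf_clock` trajectory from [simulate_clock()] on a
#'   uniform grid.
#' @param arch A [cbf_architecture()].
#' @param params A [cbf_params()].
#' @param initial_mrna Initial mRNA level (a.u., >= 0). Default
#'   `production_rate(0)/d`, the instantaneous balance point, which damps
#'   the entrainment transient.
#' @param internal_step Target internal integration step in hours
#'   (default 0.05; rounded so it divides the clock grid step).
#' @return A `cbf_trajectory` tibble with columns `time_h`, `cbf3_mrna`,
#'   carrying the fine-grid solution and provenance as attributes.
#' @examples
#' clk <- simulate_clock(light_regime(12))
#' arch <- cbf_architecture("LHY_CCA1", c("EC", "TOC1"))
#' pars <- cbf_params(1, c(LHY_CCA1 = 0.5, EC = 0.1, TOC1 = 0.5), d = 1)
#' cbf <- simulate_cbf3(clk, arch, pars)
#' @export
simulate_cbf3 <- function(clock, arch, params, initial_mrna = NULL,
                          internal_step = 0.05) {
  stopifnot(inherits(clock, "cbf_clock"))
  times <- clock$time_h
  step <- unique(round(diff(times), 9))
  if (length(step) != 1) abort("Clock trajectory grid must be uniform.")
  nsub <- max(1L, as.integer(ceiling(step / internal_step)))
  h <- step / nsub
  tt <- seq(times[1], times[length(times)], by = h)
  mat <- clock_evaluator(clock)(tt)
  p <- production_from_matrix(mat, arch, params)
  if (any(!is.finite(p))) abort("Non-finite production rate; check parameters.")
  if (is.null(initial_mrna)) initial_mrna <- p[1] / params$d
  if (initial_mrna < 0) abort("`initial_mrna` must be non-negative.")
  cc <- integrate_linear_decay(p, params$d, h, initial_mrna)
  out <- tibble(time_h = times,
                cbf3_mrna = cc[seq(1, length(cc), by = nsub)])
  structure(out, class = c("cbf_trajectory", class(tibble())),
            fine = tibble(time_h = tt, cbf3_mrna = cc),
            arch = arch, params = params,
            regime = attr(clock, "regime"),
            genotype = attr(clock, "genotype"))
}

#' Export a clock + CBF3 trajectory pair to CSV
#'
#' Writes one row per time point with columns `time_h`, the clock species,
#' and `cbf3_mrna`.
#'
#' @param clock A `cbf_clock` trajectory.
#' @param cbf The matching `cbf_trajectory` from [simulate_cbf3()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_trajectory_csv <- function(clock, cbf, path) {
  stopifnot(identical(clock$time_h, cbf$time_h))
  readr::write_csv(dplyr::bind_cols(as_tibble(clock),
                                    cbf3_mrna = cbf$cbf3_mrna), path)
  invisible(path)
}
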