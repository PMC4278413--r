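# Figure-style ggplot2 output for each result type.

#' Plot clock regulator waveforms
#'
#' @param object A `cbf_clock` trajectory.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cbf_clock <- function(object, ...) {
  ggplot2::ggplot(clock_long(object),
                  ggplot2::aes(time_h, abundance, colour = species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (h after dawn)", y = "Abundance (a.u.)",
                  title = attr(object, "regime")$label) +
    ggplot2::theme_minimal()
}

#' Plot a CBF3 mRNA trajectory
#'
#' @param object A `cbf_trajectory`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cbf_trajectory <- function(object, ...) {
  fine <- attr(object, "fine") %||% object
  ggplot2::ggplot(fine, ggplot2::aes(time_h, cbf3_mrna)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (h after dawn)", y = "CBF3 mRNA (a.u.)") +
    ggplot2::theme_minimal()
}

#' Plot Akaike weights of a ranked ensemble
#'
#' @param object A `cbf_selection`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cbf_selection <- function(object, ...) {
  d <- tidy(object)
  d$label <- factor(d$label, levels = rev(d$label))
  ggplot2::ggplot(d, ggplot2::aes(weight, label)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Akaike weight", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a cold-gating profile
#'
#' @param object A `cbf_gating` profile (or a bound tibble with both
#'   modes).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cbf_gating <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(pulse_time, induction, colour = mode)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "Pulse time (h after subjective dawn)",
                  y = "Induction (max pulsed CBF3 mRNA)") +
    ggplot2::theme_minimal()
}

#' Plot a fitted model against the data in every regime
#'
#' Shows the unit-max-normalised simulated CBF3 mRNA (line) over the
#' normalised expression data (points), one facet per light regime.
#'
#' @param fit A `cbf_fit`.
#' @param dataset The `cbf_dataset` it was fitted to.
#' @param clocks Named list of `cbf_clock` trajectories per regime.
#' @param transient Discarded entrainment transient, hours (default 24).
#' @return A ggplot.
#' @export
plot_fit <- function(fit, dataset, clocks, transient = 24) {
  sims <- purrr::map_dfr(unique(dataset$regime), function(lb) {
    dat <- dataset[dataset$regime == lb, ]
    tr <- attr(simulate_cbf3(clocks[[lb]], fit$arch, fit$params), "fine")
    tr <- tr[tr$time_h >= transient, ]
    at_data <- approxfun(tr$time_h - transient, tr$cbf3_mrna)(dat$time_h)
    tibble(regime = lb, time_h = tr$time_h - transient,
           value = tr$cbf3_mrna / max(at_data))
  })
  dat <- dplyr::mutate(dplyr::group_by(as_tibble(dataset), regime),
                       value = expression / max(expression))
  ggplot2::ggplot(sims, ggplot2::aes(time_h, value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(data = dat) +
    ggplot2::facet_wrap(~regime) +
    ggplot2::labs(x = "Time (h after dawn)",
                  y = "Normalised CBF3 expression",
                  title = fit$arch$label) +
    ggplot2::theme_minimal()
}

#' Plot a mutant fold-change panel
#'
#' @param mutants Tibble from [mutant_panel()] or [run_experiments()].
#' @return A ggplot (log-scaled fold-change bars with class labels).
#' @export
plot_mutants <- function(mutants) {
  d <- dplyr::mutate(mutants,
                     fold_plot = pmax(fold_change, 1e-3))
  ggplot2::ggplot(d, ggplot2::aes(genotype, fold_plot, fill = class)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "Peak CBF3 mRNA (mutant / wild type)") +
    ggplot2::theme_minimal()
}
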