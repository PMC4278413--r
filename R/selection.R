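# Corrected-AIC model selection over the fitted ensemble.

#' Corrected Akaike Information Criterion from a residual sum of squares
#'
#' Assumes Gaussian i.i.d. residuals with profiled variance, which counts
#' as one extra parameter: `k_total = k_free + 1`. The score is
#' `n*log(rss/n) + 2*k + 2*k*(k+1)/(n - k - 1)` with `k = k_total`; lower
#' is better.
#'
#' @param rss Residual sum of squares, > 0.
#' @param n_points Number of fitted data points (pooled across regimes).
#' @param k_free Number of free model parameters (excluding the residual
#'   variance).
#' @return The AICc score.
#' @examples
#' aicc(rss = 1, n_points = 52, k_free = 5)
#' @export
aicc <- function(rss, n_points, k_free) {
  if (rss <= 0) abort("`rss` must be positive.")
  k <- k_free + 1
  if (n_points <= k + 1) {
    abort("Small-sample correction undefined: need n_points > k_free + 2.")
  }
  n_points * log(rss / n_points) + 2 * k + 2 * k * (k + 1) / (n_points - k - 1)
}

#' Akaike weights from a set of AICc scores
#'
#' `w_i = exp(-delta_i/2) / sum_j exp(-delta_j/2)` with
#' `delta_i = score_i - min(score)`, computed stably by subtracting the
#' minimum before exponentiating. Weights are non-negative and sum to 1.
#'
#' @param scores Numeric vector of AICc scores (at least one finite).
#' @return Numeric vector of weights.
#' @examples
#' aicc_weights(c(0, 2))
#' @export
aicc_weights <- function(scores) {
  if (!length(scores)) abort("`scores` must be non-empty.")
  if (!any(is.finite(scores))) abort("At least one score must be finite.")
  delta <- scores - min(scores, na.rm = TRUE)
  w <- exp(-delta / 2)
  w[!is.finite(scores)] <- 0
  w / sum(w)
}

#' Rank a fitted ensemble by AICc
#'
#' Computes each fit's AICc and Akaike weight and returns the ensemble
#' sorted by ascending score (ties broken deterministically by architecture
#' label). All fits must share the same number of data points.
#'
#' @param fits List of `cbf_fit` objects (from [fit_ensemble()] or repeated
#'   [fit_architecture()] calls on the same dataset).
#' @param features Optional named character vector of qualitative feature
#'   annotations, named by architecture label.
#' @return A `cbf_selection` tibble with columns `rank`, `label`, `aicc`,
#'   `weight`, `k_free`, `rss`, `n_points`, `features` and a list-column
#'   `fit`.
#' @export
rank_ensemble <- function(fits, features = NULL) {
  if (!length(fits)) abort("`fits` must be non-empty.")
  stopifnot(all(vapply(fits, inherits, TRUE, "cbf_fit")))
  n <- unname(vapply(fits, function(f) as.integer(f$n_points), 0L))
  if (length(unique(n)) != 1) {
    abort("All fits must be scored on the same number of data points.")
  }
  tab <- tibble(
    label = unname(vapply(fits, function(f) f$arch$label, "")),
    aicc = unname(vapply(fits,
                         function(f) aicc(f$rss, f$n_points, f$k_free), 0)),
    k_free = unname(vapply(fits, function(f) as.integer(f$k_free), 0L)),
    rss = unname(vapply(fits, function(f) as.numeric(f$rss), 0)),
    n_points = n,
    fit = unname(fits)
  )
  tab <- dplyr::arrange(tab, aicc, label)
  tab$weight <- aicc_weights(tab$aicc)
  tab$rank <- seq_len(nrow(tab))
  tab$features <- if (is.null(features)) NA_character_ else
    unname(features[tab$label])
  tab <- dplyr::select(tab, rank, label, aicc, weight, k_free, rss,
                       n_points, features, fit)
  structure(tab, class = c("cbf_selection", class(tibble())))
}

#' Tidy a selection table
#' @param x A `cbf_selection`.
#' @param ... Unused.
#' @return The table without the `fit` list-column.
#' @export
tidy.cbf_selection <- function(x, ...) {
  d <- as_tibble(x)
  d <- d[setdiff(names(d), "fit")]
  # drop run-provenance attributes attached by the pipeline
  keep <- c("names", "row.names", "class")
  for (a in setdiff(names(attributes(d)), keep)) attr(d, a) <- NULL
  d
}

#' One-row summary of a selection run
#' @param x A `cbf_selection`.
#' @param ... Unused.
#' @return A tibble with the number of models, the top label and weight.
#' @export
glance.cbf_selection <- function(x, ...) {
  tibble(n_models = nrow(x), top_label = x$label[1],
         top_weight = x$weight[1],
         delta_next = if (nrow(x) > 1) x$aicc[2] - x$aicc[1] else NA_real_)
}

#' Render a selection table as human-readable text
#'
#' Mirrors the canonical table layout (Rank, Model, AICc score, AICc
#' weight, Features), with scores and weights to two decimals.
#'
#' @param selection A `cbf_selection`.
#' @return Character vector of lines.
#' @export
format_selection_table <- function(selection) {
  hdr <- sprintf("%-4s %-28s %10s %7s  %s",
                 "Rank", "Model", "AICc", "Weight", "Features")
  rows <- sprintf("%-4d %-28s %10.2f %7.2f  %s",
                  selection$rank, selection$label, selection$aicc,
                  selection$weight,
                  ifelse(is.na(selection$features), "", selection$features))
  c(hdr, rows)
}

#' @export
print.cbf_selection <- function(x, ...) {
  writeLines(format_selection_table(x))
  invisible(x)
}

#' Write a selection table to CSV (and optionally a text rendering)
#'
#' @param selection A `cbf_selection`.
#' @param path CSV output path.
#' @param text_path Optional path for the text table.
#' @return `path`, invisibly.
#' @export
write_selection <- function(selection, path, text_path = NULL) {
  readr::write_csv(tidy(selection), path)
  if (!is.null(text_path)) writeLines(format_selection_table(selection),
                                      text_path)
  invisible(path)
}
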