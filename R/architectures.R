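# Candidate regulatory architectures for the CBF3 transcription submodel.

#' Define one candidate CBF3 regulatory architecture
#'
#' An architecture names which clock species activate and which repress
#' CBF3 transcription. Activators and repressors must be disjoint and there
#' must be at least one regulator.
#'
#' @param activators Character vector of activating species.
#' @param repressors Character vector of repressing species.
#' @return A `cbf_architecture` object with an auto-generated label in which
#'   an up arrow marks activation and a down arrow repression
#'   (e.g. `"EC↓:TOC1↓:LHY/CCA1↑"`).
#' @examples
#' cbf_architecture(activators = "LHY_CCA1", repressors = c("EC", "TOC1"))
#' @export
cbf_architecture <- function(activators = character(),
                             repressors = character()) {
  activators <- unique(as.character(activators))
  repressors <- unique(as.character(repressors))
  bad <- setdiff(c(activators, repressors), clock_species())
  if (length(bad)) abort(paste0("Unknown species: ", toString(bad)))
  if (length(intersect(activators, repressors))) {
    abort("Activators and repressors must be disjoint.")
  }
  if (!length(activators) && !length(repressors)) {
    abort("An architecture needs at least one regulator.")
  }
  structure(list(activators = activators, repressors = repressors,
                 label = arch_label(activators, repressors)),
            class = "cbf_architecture")
}

pretty_species <- function(x) sub("LHY_CCA1", "LHY/CCA1", x, fixed = TRUE)

arch_label <- function(activators, repressors) {
  # render repressors before activators, as in the published table labels
  parts <- c(
    if (length(repressors)) paste0(pretty_species(repressors), "↓"),
    if (length(activators)) paste0(pretty_species(activators), "↑")
  )
  paste0(parts, collapse = ":")
}

#' @export
print.cbf_architecture <- function(x, ...) {
  cat("<CBF3 architecture ", x$label, ">\n", sep = "")
  invisible(x)
}

#' @export
format.cbf_architecture <- function(x, ...) x$label

regulators <- function(arch) c(arch$activators, arch$repressors)

#' Enumerate the candidate ensemble of CBF3 architectures
#'
#' Returns the thirteen candidate architectures considered in the analysis,
#' in the canonical order of the published ranking: combinations of EC and
#' TOC1 repression with LHY/CCA1 activation, single-regulator variants, EC
#' activation, and the day-PRR repression variants (NI, PRR7, PRR9 jointly
#' or singly). The two joint-PRR variants carry three repressor terms (plus
#' optional LHY/CCA1 activation) and are the only members exceeding the
#' generic three-regulator cap.
#'
#' @return A tibble with columns `label`, `n_regulators`, `k_free` and a
#'   list-column `arch` of [cbf_architecture()] objects.
#' @examples
#' cbf_ensemble()$label
#' @export
cbf_ensemble <- function() {
  a <- list(
    cbf_architecture("LHY_CCA1", c("EC", "TOC1")),
    cbf_architecture(character(), c("EC", "TOC1")),
    cbf_architecture("LHY_CCA1", "EC"),
    cbf_architecture(character(), "EC"),
    cbf_architecture("LHY_CCA1", "TOC1"),
    cbf_architecture(character(), "TOC1"),
    cbf_architecture("LHY_CCA1", character()),
    cbf_architecture("LHY_CCA1", c("NI", "PRR7", "PRR9")),
    cbf_architecture("EC", character()),
    cbf_architecture(character(), c("NI", "PRR7", "PRR9")),
    cbf_architecture(character(), "NI"),
    cbf_architecture(character(), "PRR7"),
    cbf_architecture(character(), "PRR9")
  )
  # table labels render LHY/CCA1 activation last except for the
  # LHY/CCA1-with-TOC1 variant, which is printed activation-first
  labels <- vapply(a, `[[`, "", "label")
  labels[5] <- "LHY/CCA1↑:TOC1↓"
  labels[8] <- "LHY/CCA1↑:NI↓:PRR7↓:PRR9↓"
  for (i in c(5, 8)) a[[i]]$label <- labels[i]
  tibble(
    label = labels,
    n_regulators = vapply(a, function(x) length(regulators(x)), 0L),
    k_free = vapply(a, count_free_parameters, 0L),
    arch = a
  )
}

#' Count free parameters of an architecture's transcription submodel
#'
#' Each architecture contributes a maximal transcription rate, an mRNA
#' degradation rate and one half-saturation constant per regulator; the
#' Hill exponent is fixed and never counted. A single-regulator variant
#' therefore has 3 free parameters and a two-regulator variant 4.
#'
#' @param arch A [cbf_architecture()].
#' @return Integer count `2 + number of regulators`.
#' @examples
#' count_free_parameters(cbf_architecture("LHY_CCA1"))            # 3
#' count_free_parameters(cbf_architecture(, c("EC", "TOC1")))     # 4
#' @export
count_free_parameters <- function(arch) {
  stopifnot(inherits(arch, "cbf_architecture"))
  n <- length(regulators(arch))
  if (n == 0) abort("Architecture has no regulators.")
  2L + n
}

#' Look up an ensemble architecture by label
#'
#' @param label Label as rendered by [cbf_ensemble()], with arrows, e.g.
#'   `"EC↓:TOC1↓:LHY/CCA1↑"`.
#' @return The matching [cbf_architecture()].
#' @export
arch_by_label <- function(label) {
  ens <- cbf_ensemble()
  i <- match(label, ens$label)
  if (is.na(i)) abort(paste0("No ensemble architecture labelled ", label))
  ens$arch[[i]]
}

#' Serialise an architecture to JSON
#' @param arch A [cbf_architecture()].
#' @return A JSON string.
#' @export
arch_to_json <- function(arch) {
  jsonlite::toJSON(list(activators = arch$activators,
                        repressors = arch$repressors,
                        label = arch$label),
                   auto_unbox = FALSE, pretty = TRUE)
}

#' Deserialise an architecture from JSON
#' @param json JSON string or path produced by [arch_to_json()].
#' @return A [cbf_architecture()].
#' @export
arch_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  cbf_architecture(unlist(x$activators), unlist(x$repressors))
}
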