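#' Light regimes
#'
#' A light regime is a 24-h cycle with `hours_light` hours of light starting
#' at dawn (time 0 of each cycle). `hours_light = 24` denotes constant light
#' ("24L/0D"), in which times are interpreted relative to subjective dawn.
#'
#' @param hours_light Hours of light per 24-h cycle, in `[0, 24]`.
#' @return A `cbf_regime` object (a small list with `hours_light` and
#'   `label`).
#' @examples
#' light_regime(12)
#' light_regime(24)$label
#' @export
light_regime <- function(hours_light) {
  if (!is.numeric(hours_light) || length(hours_light) != 1 ||
      is.na(hours_light) || hours_light < 0 || hours_light > 24) {
    abort("`hours_light` must be a single number in [0, 24].")
  }
  label <- sprintf("%gL/%gD", hours_light, 24 - hours_light)
  structure(list(hours_light = hours_light, label = label),
            class = "cbf_regime")
}

#' @export
print.cbf_regime <- function(x, ...) {
  cat("<light regime ", x$label, ">\n", sep = "")
  invisible(x)
}

#' The four photoperiodic regimes used throughout the analysis
#'
#' Short days (8L/16D), equinox (12L/12D), long days (16L/8D) and constant
#' light (24L/0D).
#'
#' @return A named list of [light_regime()] objects.
#' @export
standard_regimes <- function() {
  r <- list(light_regime(8), light_regime(12), light_regime(16),
            light_regime(24))
  setNames(r, vapply(r, `[[`, "", "label"))
}

is_regime <- function(x) inherits(x, "cbf_regime")

as_regime <- function(x) {
  if (is_regime(x)) return(x)
  if (is.numeric(x)) return(light_regime(x))
  if (is.character(x) && length(x) == 1) {
    hl <- suppressWarnings(as.numeric(sub("L/.*$", "", x)))
    if (!is.na(hl)) return(light_regime(hl))
  }
  abort("Cannot interpret `regime`; use light_regime() or a label like '12L/12D'.")
}
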