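# Phenomenological clock driver: smooth 24-h periodic waveforms for the six
# clock regulator species that serve as inputs to the CBF3 submodel.

#' Clock regulator species
#'
#' The six clock species used as candidate CBF3 regulators: the merged
#' morning factors LHY/CCA1 (one variable, `LHY_CCA1`), the day-phased
#' pseudo-response regulators `PRR9`, `PRR7` and `NI` (the proxy for PRR5),
#' the evening regulator `TOC1`, and the Evening Complex activity `EC`.
#'
#' @return Character vector of species identifiers.
#' @export
clock_species <- function() {
  c("LHY_CCA1", "PRR9", "PRR7", "NI", "TOC1", "EC")
}

#' Default clock waveform configuration
#'
#' Each species is a smooth 24-h periodic von-Mises-shaped bump
#' `a * exp(kappa * (cos(2*pi*(t - peak_zt)/24) - 1))`, peaking `peak_zt`
#' hours after dawn with sharpness `kappa` (larger is narrower) and
#' amplitude `amplitude`. The defaults encode the canonical phase ordering:
#' LHY/CCA1 in the early morning, PRR9, PRR7 then NI in sequence through the
#' day, TOC1 near dusk, and EC activity spanning late night across dawn and
#' low through the afternoon.
#'
#' @param ... Per-species overrides, e.g. `LHY_CCA1 = list(kappa = 2)`;
#'   each value is a list with any of `peak_zt`, `kappa`, `amplitude`.
#' @return A tibble with columns `species`, `peak_zt`, `kappa`, `amplitude`.
#' @examples
#' clock_config()
#' clock_config(EC = list(kappa = 2))
#' @export
clock_config <- function(...) {
  cfg <- tibble(
    species   = clock_species(),
    peak_zt   = c(1, 3, 6, 9, 13, 23),
    kappa     = c(1, 2, 2, 2, 1.5, 1.5),
    amplitude = rep(1, 6)
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), cfg$species)
    if (length(bad)) abort(paste0("Unknown species: ", toString(bad)))
    for (sp in names(overrides)) {
      ov <- overrides[[sp]]
      for (field in intersect(names(ov), c("peak_zt", "kappa", "amplitude"))) {
        cfg[cfg$species == sp, field] <- ov[[field]]
      }
    }
  }
  cfg
}

#' Specify a clock genotype
#'
#' A genotype is a set of knocked-out species (abundance identically zero)
#' plus multiplicative amplitude modifiers for the remaining species
#' (default 1). Modifiers must be non-negative.
#'
#' @param knocked_out Character vector of species identifiers to knock out.
#' @param modifiers Named numeric vector of amplitude multipliers.
#' @param label Optional genotype label (e.g. `"toc1"`).
#' @return A `cbf_genotype` object.
#' @examples
#' genotype()                          # wild type
#' genotype("TOC1", label = "toc1")
#' genotype(c("NI", "PRR7", "PRR9"), c(LHY_CCA1 = 2))
#' @export
genotype <- function(knocked_out = character(), modifiers = numeric(),
                     label = NULL) {
  knocked_out <- unique(as.character(knocked_out))
  bad <- setdiff(knocked_out, clock_species())
  if (length(bad)) abort(paste0("Unknown species in `knocked_out`: ", toString(bad)))
  if (length(modifiers)) {
    if (is.null(names(modifiers)) || any(names(modifiers) == "")) {
      abort("`modifiers` must be a named numeric vector.")
    }
    bad <- setdiff(names(modifiers), clock_species())
    if (length(bad)) abort(paste0("Unknown species in `modifiers`: ", toString(bad)))
    if (any(!is.finite(modifiers)) || any(modifiers < 0)) {
      abort("Amplitude modifiers must be finite and non-negative.")
    }
  }
  if (is.null(label)) {
    label <- if (!length(knocked_out) && !length(modifiers)) "wild type" else
      paste0(c(knocked_out, paste0(names(modifiers), "x", modifiers)),
             collapse = " ")
  }
  structure(list(knocked_out = knocked_out,
                 modifiers = modifiers, label = label),
            class = "cbf_genotype")
}

#' @export
print.cbf_genotype <- function(x, ...) {
  cat("<genotype ", x$label, ">\n", sep = "")
  invisible(x)
}

is_wild_type <- function(g) {
  !length(g$knocked_out) &&
    (!length(g$modifiers) || all(g$modifiers == 1))
}

genotypes_equal <- function(a, b) {
  ma <- a$modifiers[a$modifiers != 1]
  mb <- b$modifiers[b$modifiers != 1]
  setequal(a$knocked_out, b$knocked_out) &&
    length(ma) == length(mb) &&
    setequal(names(ma), names(mb)) &&
    all(ma[names(mb)] == mb)
}

#' Standard clock-mutant genotypes
#'
#' Default configuration of the simulated mutant backgrounds. Knock-on
#' effects are configuration rather than mechanism: in the *ni prr7 prr9*
#' triple mutant LHY/CCA1 amplitude is doubled (the day PRRs repress
#' LHY/CCA1 transcription), and in *lux* (Evening Complex loss) LHY/CCA1
#' amplitude is reduced to 0.3 because EC mutants have low LHY levels.
#'
#' @return Named list of [genotype()] objects
#'   (`lhy cca1`, `ni prr7 prr9`, `toc1`, `lux`).
#' @export
standard_genotypes <- function() {
  list(
    "lhy cca1"     = genotype("LHY_CCA1", label = "lhy cca1"),
    "ni prr7 prr9" = genotype(c("NI", "PRR7", "PRR9"), c(LHY_CCA1 = 2),
                              label = "ni prr7 prr9"),
    "toc1"         = genotype("TOC1", label = "toc1"),
    "lux"          = genotype("EC", c(LHY_CCA1 = 0.3), label = "lux")
  )
}

# apply a genotype to a waveform configuration (idempotent by construction:
# KO sets amplitude to zero; modifiers are recorded so re-application of the
# same genotype is a no-op)
apply_genotype_config <- function(cfg, geno) {
  applied <- attr(cfg, "genotype")
  if (!is.null(applied)) {
    if (genotypes_equal(applied, geno)) return(cfg)
    abort("Configuration already carries a different genotype.")
  }
  amp <- setNames(cfg$amplitude, cfg$species)
  if (length(geno$modifiers)) {
    amp[names(geno$modifiers)] <- amp[names(geno$modifiers)] * geno$modifiers
  }
  amp[geno$knocked_out] <- 0
  cfg$amplitude <- unname(amp[cfg$species])
  attr(cfg, "genotype") <- geno
  cfg
}

# vectorised waveform evaluation: times x species matrix
clock_waveform_matrix <- function(times, cfg) {
  m <- vapply(seq_len(nrow(cfg)), function(i) {
    cfg$amplitude[i] *
      exp(cfg$kappa[i] * (cos(2 * pi * (times - cfg$peak_zt[i]) / 24) - 1))
  }, numeric(length(times)))
  m <- matrix(m, nrow = length(times), ncol = nrow(cfg))
  colnames(m) <- cfg$species
  m
}

#' Simulate clock-regulator time courses
#'
#' Produces deterministic abundances of the six clock regulator species on a
#' uniform time grid under a light regime and genotype. In the default
#' (surrogate) mode each wild-type species is a prescribed smooth 24-h
#' periodic waveform (see [clock_config()]); waveform phases are identical
#' across photoperiods, including constant light. Knocked-out species are
#' identically zero; amplitude modifiers scale waveforms multiplicatively.
#'
#' @param regime A [light_regime()] (or its label / hours of light).
#' @param genotype A [genotype()]; default wild type.
#' @param duration Simulation length in hours (>= 48; the first 24 h are
#'   treated as an entrainment transient by downstream analyses).
#' @param step Grid step in hours; must divide 24 evenly.
#' @param config Waveform configuration from [clock_config()].
#' @return A `cbf_clock` tibble with columns `time_h` and one column per
#'   species, carrying the regime, genotype and an exact waveform evaluator
#'   as attributes.
#' @examples
#' clk <- simulate_clock(light_regime(12))
#' head(clk)
#' @export
simulate_clock <- function(regime, genotype = cbfclock::genotype(),
                           duration = 72, step = 0.5,
                           config = clock_config()) {
  regime <- as_regime(regime)
  if (!inherits(genotype, "cbf_genotype")) abort("`genotype` must be a cbf_genotype.")
  if (duration < 48) abort("`duration` must be at least 48 h.")
  if (step <= 0 || abs(24 / step - round(24 / step)) > 1e-9) {
    abort("`step` must be positive and divide 24 h evenly.")
  }
  cfg <- apply_genotype_config(config, genotype)
  times <- seq(0, duration, by = step)
  m <- clock_waveform_matrix(times, cfg)
  out <- as_tibble(cbind(tibble(time_h = times), as.data.frame(m)))
  fun <- function(t) clock_waveform_matrix(t, cfg)
  new_clock_trajectory(out, regime, genotype, fun)
}

new_clock_trajectory <- function(tbl, regime, genotype, clock_fun) {
  structure(tbl,
            class = c("cbf_clock", class(tibble())),
            regime = regime, genotype = genotype, clock_fun = clock_fun)
}

#' Apply a genotype to an existing clock trajectory
#'
#' Sets knocked-out species to zero and scales the others by the genotype's
#' amplitude modifiers. Applying the genotype the trajectory already carries
#' is a no-op, so the operation is idempotent.
#'
#' @param clock A `cbf_clock` trajectory from [simulate_clock()].
#' @param genotype A [genotype()].
#' @return The modified `cbf_clock` trajectory.
#' @export
apply_genotype <- function(clock, genotype) {
  stopifnot(inherits(clock, "cbf_clock"))
  applied <- attr(clock, "genotype")
  if (!is.null(applied) && genotypes_equal(applied, genotype)) return(clock)
  if (!is.null(applied) && !is_wild_type(applied)) {
    abort("Trajectory already carries a different genotype.")
  }
  for (sp in names(genotype$modifiers)) {
    clock[[sp]] <- clock[[sp]] * genotype$modifiers[[sp]]
  }
  for (sp in genotype$knocked_out) clock[[sp]] <- 0 * clock[[sp]]
  base_fun <- attr(clock, "clock_fun")
  geno <- genotype
  if (!is.null(base_fun)) {
    attr(clock, "clock_fun") <- function(t) {
      m <- base_fun(t)
      for (sp in names(geno$modifiers)) m[, sp] <- m[, sp] * geno$modifiers[[sp]]
      m[, geno$knocked_out] <- 0
      m
    }
  }
  attr(clock, "genotype") <- genotype
  clock
}

# exact or interpolated species evaluator for a trajectory
clock_evaluator <- function(clock) {
  fun <- attr(clock, "clock_fun")
  if (!is.null(fun)) return(fun)
  sp <- intersect(clock_species(), names(clock))
  fns <- lapply(sp, function(s) approxfun(clock$time_h, clock[[s]], rule = 2))
  names(fns) <- sp
  function(t) {
    m <- vapply(fns, function(f) f(t), numeric(length(t)))
    m <- matrix(m, nrow = length(t), ncol = length(fns),
                dimnames = list(NULL, sp))
    m
  }
}

#' Convert a clock trajectory to long (tidy) format
#'
#' @param clock A `cbf_clock` trajectory.
#' @return A tibble with columns `time_h`, `species`, `abundance`.
#' @export
clock_long <- function(clock) {
  tidyr::pivot_longer(as_tibble(clock), -time_h,
                      names_to = "species", values_to = "abundance")
}
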