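# In-silico experiments on fitted models: peak-phase analysis, clock-mutant
# fold-change predictions, and circadian gating of simulated cold pulses.

#' Peak phase of a rhythmic trajectory
#'
#' Argmax time of the final full 24-h cycle, reported modulo 24 as hours
#' after (subjective) dawn on `[0, 24)`. The trajectory must span at least
#' two cycles beyond the 24-h entrainment transient. A flat trajectory
#' (range below `1e-9` of its maximum) raises a classed error
#' (`cbfclock_arrhythmic`) rather than returning a number.
#'
#' @param traj A `cbf_trajectory` (or any tibble with `time_h` and a value
#'   column named `cbf3_mrna` or `expression`).
#' @param regime Optional [light_regime()] (metadata only; dawn is time 0
#'   modulo 24 in either case).
#' @return Peak phase in hours after dawn.
#' @examples
#' clk <- simulate_clock(light_regime(12), duration = 96)
#' arch <- cbf_architecture("LHY_CCA1", c("EC", "TOC1"))
#' pars <- cbf_params(1, c(LHY_CCA1 = 2, EC = 0.1, TOC1 = 0.5), d = 2)
#' peak_phase(simulate_cbf3(clk, arch, pars))
#' @export
peak_phase <- function(traj, regime = NULL) {
  fine <- attr(traj, "fine") %||% traj
  value_col <- intersect(c("cbf3_mrna", "expression", "value"), names(fine))[1]
  if (is.na(value_col)) abort("No mRNA/expression column found.")
  t <- fine$time_h
  x <- fine[[value_col]]
  if (max(t) - min(t) < 72 - 1e-9) {
    abort("Trajectory must span at least two cycles beyond the 24-h transient.")
  }
  keep <- t > max(t) - 24 + 1e-9
  t <- t[keep]; x <- x[keep]
  if (max(x) - min(x) < 1e-9 * max(abs(x), 1e-300)) {
    abort("Trajectory is arrhythmic (flat over the final cycle).",
          class = "cbfclock_arrhythmic")
  }
  t[which.max(x)] %% 24
}

#' Classify a mutant/wild-type fold change
#'
#' Default thresholds: below 0.05 abolished, below 0.5 reduced, 0.5-2
#' wild-type-like, above 2 elevated.
#'
#' @param fold_change Positive ratio (mutant / wild type).
#' @param thresholds Named numeric vector with `abolished`, `reduced`,
#'   `elevated` cut points.
#' @return One of `"abolished"`, `"reduced"`, `"wild-type-like"`,
#'   `"elevated"`.
#' @export
classify_fold_change <- function(fold_change,
                                 thresholds = c(abolished = 0.05,
                                                reduced = 0.5,
                                                elevated = 2)) {
  dplyr::case_when(
    fold_change < thresholds[["abolished"]] ~ "abolished",
    fold_change < thresholds[["reduced"]] ~ "reduced",
    fold_change <= thresholds[["elevated"]] ~ "wild-type-like",
    TRUE ~ "elevated"
  )
}

#' Predicted CBF3 fold change in a clock-mutant background
#'
#' Simulates wild-type and mutant CBF3 trajectories with identical fitted
#' parameters (mutant genotypes alter only the clock inputs) and reports
#' the ratio of cycle-peak mRNA levels over the final simulated cycle.
#' Comparisons are run in constant light by default, matching the
#' convention of the published mutant simulations. An arrhythmic wild type
#' is an error; an arrhythmic mutant is allowed (its final-cycle mean is
#' used and flagged).
#'
#' @param arch A [cbf_architecture()].
#' @param params Fitted [cbf_params()] (wild-type fit).
#' @param genotype A [genotype()] describing the mutant.
#' @param regime Light regime (default constant light).
#' @param clock_config Waveform configuration.
#' @param duration Simulation length in hours (default 96).
#' @param thresholds Passed to [classify_fold_change()].
#' @return A one-row tibble: `genotype`, `fold_change`, `class`,
#'   `mutant_arrhythmic`.
#' @export
mutant_fold_change <- function(arch, params, genotype,
                               regime = light_regime(24),
                               clock_config = cbfclock::clock_config(),
                               duration = 96,
                               thresholds = c(abolished = 0.05,
                                              reduced = 0.5, elevated = 2)) {
  regime <- as_regime(regime)
  wt_clk <- simulate_clock(regime, duration = duration, config = clock_config)
  mu_clk <- simulate_clock(regime, genotype = genotype, duration = duration,
                           config = clock_config)
  wt <- attr(simulate_cbf3(wt_clk, arch, params), "fine")
  mu <- attr(simulate_cbf3(mu_clk, arch, params), "fine")
  final <- function(tr) tr[tr$time_h > max(tr$time_h) - 24 + 1e-9, ]
  wt_f <- final(wt); mu_f <- final(mu)
  if (max(wt_f$cbf3_mrna) - min(wt_f$cbf3_mrna) <
        1e-9 * max(wt_f$cbf3_mrna, 1e-300)) {
    abort("Wild-type trajectory is arrhythmic; cannot form a peak ratio.",
          class = "cbfclock_arrhythmic")
  }
  mu_flat <- max(mu_f$cbf3_mrna) - min(mu_f$cbf3_mrna) <
    1e-9 * max(mu_f$cbf3_mrna, 1e-300)
  mu_level <- if (mu_flat) mean(mu_f$cbf3_mrna) else max(mu_f$cbf3_mrna)
  fold <- mu_level / max(wt_f$cbf3_mrna)
  tibble(genotype = genotype$label, fold_change = fold,
         class = classify_fold_change(fold, thresholds),
         mutant_arrhythmic = mu_flat)
}

#' Mutant predictions for a panel of genotypes
#'
#' @inheritParams mutant_fold_change
#' @param genotypes Named list of [genotype()]s (default
#'   [standard_genotypes()]).
#' @return A tibble with one row per genotype.
#' @export
mutant_panel <- function(arch, params, genotypes = standard_genotypes(),
                         regime = light_regime(24), ...) {
  purrr::map_dfr(genotypes, function(g)
    mutant_fold_change(arch, params, g, regime = regime, ...))
}

#' Circadian gating profile of simulated cold pulses
#'
#' Simulates a five-fold (by default) cold induction applied at each pulse
#' time across the subjective day in constant light, with the fitted model
#' otherwise unperturbed. In `via_LHY` mode the pulse multiplies the
#' LHY/CCA1 abundance by `fold` for `pulse_duration` hours from the pulse
#' onset (a cold signal routed through the clock); in `direct` mode the
#' CBF3 mRNA state itself is multiplied by `fold` at the pulse instant (a
#' clock-independent cold signal arriving at the locus). The induction read
#' out for each pulse time is the maximum pulsed mRNA level within
#' `observation_window` hours of pulse onset.
#'
#' @param arch A [cbf_architecture()].
#' @param params Fitted [cbf_params()].
#' @param mode `"via_LHY"` or `"direct"`.
#' @param fold Pulse magnitude, >= 1 (default 5).
#' @param pulse_times Hours after subjective dawn (default
#'   `c(0, 4, 8, 12, 16, 20)`).
#' @param pulse_duration via-LHY pulse length in hours (default 4; must not
#'   exceed 24).
#' @param observation_window Hours after pulse onset over which induction
#'   is read (default 4).
#' @param normalise Scale the profile to unit maximum (default TRUE).
#' @param clock_config Waveform configuration.
#' @param internal_step Integration step (default 0.05 h).
#' @return A `cbf_gating` tibble with columns `pulse_time`, `induction`,
#'   `mode`, carrying the unperturbed reference levels as attribute
#'   `reference`.
#' @export
cold_gating_profile <- function(arch, params, mode = c("via_LHY", "direct"),
                                fold = 5,
                                pulse_times = seq(0, 20, by = 4),
                                pulse_duration = 4, observation_window = 4,
                                normalise = TRUE,
                                clock_config = cbfclock::clock_config(),
                                internal_step = 0.05) {
  mode <- match.arg(mode)
  if (fold < 1) abort("`fold` must be >= 1.")
  if (pulse_duration > 24) abort("`pulse_duration` must not exceed 24 h.")
  if (any(pulse_times < 0 | pulse_times >= 24)) {
    abort("`pulse_times` must lie in [0, 24).")
  }
  entrain <- 48  # two discarded cycles before pulsing
  horizon <- entrain + 24 + max(pulse_times) + observation_window
  regime <- light_regime(24)
  base_clk <- simulate_clock(regime, duration = horizon,
                             step = internal_step, config = clock_config)
  base_fun <- clock_evaluator(base_clk)
  base <- simulate_cbf3(base_clk, arch, params,
                        internal_step = internal_step)
  fine <- attr(base, "fine")
  h <- internal_step

  window_max <- function(tr, t0) {
    max(tr$cbf3_mrna[tr$time_h >= t0 - 1e-9 &
                       tr$time_h <= t0 + observation_window + 1e-9])
  }

  induction <- vapply(pulse_times, function(zt) {
    t0 <- entrain + zt
    if (mode == "via_LHY") {
      pulsed_fun <- function(t) {
        m <- base_fun(t)
        in_pulse <- t >= t0 & t < t0 + pulse_duration
        m[in_pulse, "LHY_CCA1"] <- m[in_pulse, "LHY_CCA1"] * fold
        m
      }
      clk <- base_clk
      attr(clk, "clock_fun") <- pulsed_fun
      tr <- attr(simulate_cbf3(clk, arch, params,
                               internal_step = internal_step), "fine")
      window_max(tr, t0)
    } else {
      # integrate onwards from the pulsed state on the fine grid
      i0 <- which.min(abs(fine$time_h - t0))
      tt <- fine$time_h[fine$time_h >= fine$time_h[i0] - 1e-9 &
                          fine$time_h <= t0 + observation_window + 1e-9]
      p <- production_from_matrix(base_fun(tt), arch, params)
      cc <- integrate_linear_decay(p, params$d, h,
                                   fold * fine$cbf3_mrna[i0])
      max(cc)
    }
  }, 0)

  reference <- vapply(pulse_times, function(zt)
    window_max(fine, entrain + zt), 0)
  if (normalise && max(induction) > 0) induction <- induction / max(induction)
  structure(tibble(pulse_time = pulse_times, induction = induction,
                   mode = mode),
            class = c("cbf_gating", class(tibble())),
            fold = fold, normalised = normalise, reference = reference,
            baseline = fine)
}
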