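top_arch <- cbf_architecture("LHY_CCA1", c("EC", "TOC1"))
demo_params <- cbf_params(1, c(LHY_CCA1 = 0.25, EC = 0.05, TOC1 = 0.33),
                          d = 3)

test_that("peak phase is read from the final cycle on [0, 24)", {
  tt <- seq(0, 96, by = 0.25)
  traj <- tibble::tibble(time_h = tt,
                         expression = cbf3_template(light_regime(12), tt))
  expect_equal(peak_phase(traj), 8)
  # translation equivariance: shifting the waveform shifts the phase
  shifted <- tibble::tibble(
    time_h = tt, expression = cbf3_template(light_regime(12), tt,
                                            peak_zt = 12))
  expect_equal(peak_phase(shifted), 12)
  flat <- tibble::tibble(time_h = tt, expression = rep(2, length(tt)))
  expect_error(peak_phase(flat), class = "cbfclock_arrhythmic")
  expect_error(peak_phase(traj[traj$time_h <= 48, ]), "two cycles")
})

test_that("mutant fold changes obey the knockout structure", {
  # wild-type 'mutant' is exactly 1
  wt <- mutant_fold_change(top_arch, demo_params, genotype())
  expect_identical(wt$fold_change, 1)
  expect_identical(wt$class, "wild-type-like")
  # knocking out a species the architecture ignores changes nothing
  arch_ec <- cbf_architecture(character(), "EC")
  p_ec <- cbf_params(1, c(EC = 0.1), d = 2)
  f <- mutant_fold_change(arch_ec, p_ec, genotype("TOC1"))
  expect_identical(f$fold_change, 1)
  # losing the sole activator abolishes expression
  lhy <- mutant_fold_change(top_arch, demo_params,
                            genotype("LHY_CCA1", label = "lhy cca1"))
  expect_identical(lhy$class, "abolished")
  expect_true(lhy$mutant_arrhythmic)
  # removing a repressor can only raise expression
  toc1 <- mutant_fold_change(top_arch, demo_params, genotype("TOC1"))
  expect_gte(toc1$fold_change, 1)
})

test_that("fold-change classes follow the configured thresholds", {
  expect_identical(classify_fold_change(0.01), "abolished")
  expect_identical(classify_fold_change(0.3), "reduced")
  expect_identical(classify_fold_change(1), "wild-type-like")
  expect_identical(classify_fold_change(2.5), "elevated")
})

test_that("a unit pulse reproduces the unperturbed trajectory exactly", {
  for (md in c("via_LHY", "direct")) {
    g <- cold_gating_profile(top_arch, demo_params, mode = md, fold = 1,
                             normalise = FALSE)
    expect_identical(g$induction, attr(g, "reference"))
  }
  expect_error(cold_gating_profile(top_arch, demo_params, fold = 0.5),
               ">= 1")
  expect_error(cold_gating_profile(top_arch, demo_params,
                                   pulse_duration = 30), "24")
})

test_that("induction is monotone in the pulse magnitude", {
  for (md in c("via_LHY", "direct")) {
    profiles <- lapply(c(1, 2, 5), function(f)
      cold_gating_profile(top_arch, demo_params, mode = md, fold = f,
                          normalise = FALSE)$induction)
    expect_true(all(profiles[[2]] >= profiles[[1]] - 1e-12))
    expect_true(all(profiles[[3]] >= profiles[[2]] - 1e-12))
  }
})

test_that("direct pulses track the ambient waveform", {
  g <- cold_gating_profile(top_arch, demo_params, mode = "direct", fold = 5,
                           normalise = FALSE)
  base <- attr(g, "baseline")
  at_pulse <- approxfun(base$time_h, base$cbf3_mrna)(48 + g$pulse_time)
  # the observation-window max is at least the instantaneous pulsed level,
  # and the profile is strongly correlated with the ambient waveform
  expect_true(all(g$induction >= 5 * at_pulse - 1e-9))
  expect_gt(cor(g$induction, at_pulse), 0.9)
})
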