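test_that("Hill production rate reproduces analytic values", {
  arch1 <- cbf_architecture("LHY_CCA1")
  p1 <- cbf_params(1, c(LHY_CCA1 = 0.7), d = 1)
  # half-saturation: A = K gives v_max/2
  expect_equal(production_rate(arch1, p1, c(LHY_CCA1 = 0.7)), 0.5)
  # an absent activator silences transcription
  expect_equal(production_rate(arch1, p1, c(LHY_CCA1 = 0)), 0)
  # three-regulator product form, all at half-saturation
  arch3 <- cbf_architecture("LHY_CCA1", c("EC", "TOC1"))
  p3 <- cbf_params(1, c(LHY_CCA1 = 1, EC = 1, TOC1 = 1), d = 1)
  expect_equal(production_rate(arch3, p3,
                               c(LHY_CCA1 = 1, EC = 1, TOC1 = 1)), 0.125)
})

test_that("production rate is bounded and monotone in each regulator", {
  arch <- cbf_architecture("LHY_CCA1", c("EC", "TOC1"))
  pars <- ref_params(arch)
  set.seed(42)
  for (i in 1:25) {
    s <- setNames(runif(3, 0, 3), c("LHY_CCA1", "EC", "TOC1"))
    r0 <- production_rate(arch, pars, s)
    expect_gte(r0, 0)
    expect_lte(r0, pars$v_max)
    up <- s; up["LHY_CCA1"] <- up["LHY_CCA1"] * 1.3
    expect_gte(production_rate(arch, pars, up), r0)
    rep_up <- s; rep_up["EC"] <- rep_up["EC"] * 1.3
    expect_lte(production_rate(arch, pars, rep_up), r0)
  }
  expect_error(production_rate(arch, pars, c(LHY_CCA1 = -1, EC = 1, TOC1 = 1)),
               "non-negative")
})

test_that("with frozen clock inputs the mRNA converges to production/d", {
  # kappa = 0 makes every waveform constant at its amplitude
  flat_cfg <- do.call(clock_config, setNames(
    lapply(clock_species(), function(s) list(kappa = 0)), clock_species()))
  clk <- simulate_clock(light_regime(24), duration = 96, config = flat_cfg)
  arch <- cbf_architecture("LHY_CCA1")
  pars <- cbf_params(2, c(LHY_CCA1 = 1), d = 0.5)
  p_const <- production_rate(arch, pars, c(LHY_CCA1 = 1))  # = 1
  tr <- simulate_cbf3(clk, arch, pars, initial_mrna = 0)
  expect_equal(tail(tr$cbf3_mrna, 1), p_const / pars$d, tolerance = 1e-8)
})

test_that("knocking out the sole activator leaves pure exponential decay", {
  clk <- simulate_clock(light_regime(12), genotype = genotype("LHY_CCA1"),
                        duration = 72)
  arch <- cbf_architecture("LHY_CCA1")
  pars <- cbf_params(1, c(LHY_CCA1 = 0.5), d = 0.8)
  tr <- simulate_cbf3(clk, arch, pars, initial_mrna = 3)
  expect_equal(tr$cbf3_mrna, 3 * exp(-0.8 * tr$time_h), tolerance = 1e-9)
})

test_that("the integrator matches a fine-step RK4 oracle for all 13 architectures", {
  clk <- simulate_clock(light_regime(12), duration = 48, step = 0.5)
  for (arch in cbf_ensemble()$arch) {
    pars <- ref_params(arch)
    got <- simulate_cbf3(clk, arch, pars)
    oracle <- rk4_cbf3(clk, arch, pars, t_end = 48, h = 0.001)
    at_grid <- oracle$cbf3_mrna[seq(1, length(oracle$cbf3_mrna), by = 500)]
    rel_err <- max(abs(got$cbf3_mrna - at_grid)) / max(at_grid)
    expect_lt(rel_err, 1e-4)
  }
})

test_that("post-transient mRNA is bounded by v_max/d and 24-h periodic", {
  clk <- simulate_clock(light_regime(12), duration = 168, step = 0.5)
  arch <- cbf_architecture("LHY_CCA1", "EC")
  pars <- cbf_params(1.3, c(LHY_CCA1 = 0.4, EC = 0.2), d = 0.5)
  tr <- simulate_cbf3(clk, arch, pars)
  post <- tr$cbf3_mrna[tr$time_h >= 24]
  expect_true(all(post >= 0))
  expect_true(all(post <= pars$v_max / pars$d + 1e-12))
  x <- tr$cbf3_mrna
  tl <- tr$time_h
  late <- x[tl >= 120 & tl <= 144]
  later <- x[tl >= 144 & tl <= 168]
  expect_lt(max(abs(late - later)), 1e-8 * max(x))
})

test_that("raising an activator waveform never lowers the mRNA anywhere", {
  arch <- cbf_architecture("LHY_CCA1", "TOC1")
  pars <- ref_params(arch)
  base <- simulate_cbf3(simulate_clock(light_regime(12)), arch, pars)
  up_act <- simulate_cbf3(
    simulate_clock(light_regime(12),
                   genotype = genotype(modifiers = c(LHY_CCA1 = 1.5))),
    arch, pars)
  expect_true(all(up_act$cbf3_mrna >= base$cbf3_mrna - 1e-12))
  up_rep <- simulate_cbf3(
    simulate_clock(light_regime(12),
                   genotype = genotype(modifiers = c(TOC1 = 1.5))),
    arch, pars)
  expect_true(all(up_rep$cbf3_mrna <= base$cbf3_mrna + 1e-12))
})

test_that("parameter validation and JSON round trip work", {
  expect_error(cbf_params(-1, c(EC = 1), d = 1), "positive")
  expect_error(cbf_params(1, c(EC = -1), d = 1), "positive")
  expect_error(cbf_params(1, c(EC = 1), d = 0), "positive")
  p <- cbf_params(1.5, c(LHY_CCA1 = 0.25, EC = 0.05), d = 2.5)
  q <- params_from_json(params_to_json(p))
  expect_equal(q$v_max, p$v_max)
  expect_equal(q$K, p$K)
  expect_equal(q$d, p$d)
})
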