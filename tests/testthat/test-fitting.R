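flat_clock <- function(duration = 48) {
  flat_cfg <- do.call(clock_config, setNames(
    lapply(clock_species(), function(s) list(kappa = 0)), clock_species()))
  simulate_clock(light_regime(12), duration = duration, config = flat_cfg)
}

# a dataset generated noiselessly from a known architecture/parameter pair
model_dataset <- function(arch, pars, clocks, times = seq(0, 48, by = 4)) {
  purrr::map_dfr(names(clocks), function(lb) {
    fine <- attr(simulate_cbf3(clocks[[lb]], arch, pars), "fine")
    at <- approxfun(fine$time_h, fine$cbf3_mrna)(times + 24)
    tibble::tibble(regime = lb, time_h = times, expression = at)
  })
}

test_that("the normalised cost matches hand arithmetic", {
  # constant production => normalised model is identically 1; with data
  # normalised to (0.5, 0.5, 0.5, 1) the cost is 3 * 0.25
  clk <- flat_clock()
  arch <- cbf_architecture("LHY_CCA1")
  pars <- cbf_params(1, c(LHY_CCA1 = 1), d = 1)
  dat <- tibble::tibble(regime = "12L/12D", time_h = c(4, 8, 12, 16),
                        expression = c(1, 1, 1, 2))
  cost <- rss_cost(arch, pars, dat, list("12L/12D" = clk))
  expect_equal(cost, 3 * 0.25, tolerance = 1e-12)
})

test_that("the cost vanishes at the generating parameters and is scale-free", {
  clocks <- std_clocks()
  arch <- cbf_architecture("LHY_CCA1", "EC")
  pars <- cbf_params(1, c(LHY_CCA1 = 0.4, EC = 0.15), d = 1.2)
  dat <- model_dataset(arch, pars, clocks)
  expect_lt(rss_cost(arch, pars, dat, clocks), 1e-10)
  # multiplying one regime's raw data by a positive constant changes nothing
  noisy <- generate_dataset(seed = 4)
  pars2 <- ref_params(arch)
  c1 <- rss_cost(arch, pars2, noisy, clocks)
  scaled <- noisy
  scaled$expression[scaled$regime == "8L/16D"] <-
    scaled$expression[scaled$regime == "8L/16D"] * 3.7
  expect_identical(rss_cost(arch, pars2, scaled, clocks), c1)
  expect_gte(c1, 0)
})

test_that("a degenerate simulation yields an infinite-cost sentinel", {
  ko_clock <- simulate_clock(light_regime(12),
                             genotype = genotype("LHY_CCA1"))
  arch <- cbf_architecture("LHY_CCA1")
  pars <- cbf_params(1, c(LHY_CCA1 = 1), d = 1)
  dat <- generate_dataset(regimes = list(light_regime(12)), seed = 2)
  expect_warning(
    cost <- rss_cost(arch, pars, dat, list("12L/12D" = ko_clock)),
    "infinite cost")
  expect_identical(cost, Inf)
})

test_that("fitting is deterministic and improves with nested restarts", {
  clocks <- std_clocks()
  dat <- generate_dataset(seed = 6)
  arch <- cbf_architecture(character(), "EC")
  f1 <- fit_architecture(arch, dat, clocks, n_restarts = 2, seed = 7,
                         maxit = 80)
  f2 <- fit_architecture(arch, dat, clocks, n_restarts = 2, seed = 7,
                         maxit = 80)
  expect_identical(f1$rss, f2$rss)
  expect_identical(f1$params$K, f2$params$K)
  expect_identical(f1$trace, f2$trace)
  f6 <- fit_architecture(arch, dat, clocks, n_restarts = 6, seed = 7,
                         maxit = 80)
  expect_lte(f6$rss, f1$rss)
  # the nested restart sequence shares its first rows
  expect_identical(f6$trace$best_cost[1:2], f1$trace$best_cost)
  expect_equal(nrow(f6$trace), 6)
  expect_equal(f1$n_points, 52)
  expect_equal(f1$k_free, 3)
})

test_that("fitting recovers known parameters from noiseless data", {
  clocks <- std_clocks()
  arch <- cbf_architecture("LHY_CCA1")
  truth <- cbf_params(1, c(LHY_CCA1 = 0.5), d = 1)
  dat <- model_dataset(arch, truth, clocks)
  fit <- fit_architecture(arch, dat, clocks, n_restarts = 8, seed = 3)
  # v_max is only identified up to the normalisation scale; K and d are
  # identified by the waveform shape
  expect_lt(abs(fit$params$K[["LHY_CCA1"]] - 0.5) / 0.5, 0.1)
  expect_lt(abs(fit$params$d - 1) / 1, 0.1)
  expect_lt(fit$rss, 1e-6)
})

test_that("every architecture is recoverable from its own noiseless data", {
  clocks <- std_clocks()
  for (i in seq_len(13)) {
    arch <- cbf_ensemble()$arch[[i]]
    truth <- ref_params(arch)
    dat <- model_dataset(arch, truth, clocks)
    # search effort scales with the architecture's parameter count
    k <- count_free_parameters(arch)
    fit <- fit_architecture(arch, dat, clocks,
                            n_restarts = c(8, 16, 24)[findInterval(k, c(0, 5, 6))],
                            seed = 20 + i,
                            maxit = c(500, 800, 1200)[findInterval(k, c(0, 5, 6))])
    expect_lt(fit$rss, 1e-6)
    # recovered normalised waveform deviates < 1% of peak from the truth
    clk <- clocks[["12L/12D"]]
    f_true <- attr(simulate_cbf3(clk, arch, truth), "fine")
    f_fit <- attr(simulate_cbf3(clk, arch, fit$params), "fine")
    keep <- f_true$time_h >= 24
    dev <- max(abs(f_true$cbf3_mrna[keep] / max(f_true$cbf3_mrna[keep]) -
                     f_fit$cbf3_mrna[keep] / max(f_fit$cbf3_mrna[keep])))
    expect_lt(dev, 0.01)
  }
})

test_that("fit accessors and serialisation behave", {
  clocks <- std_clocks()
  dat <- generate_dataset(seed = 8)
  arch <- cbf_architecture(character(), "TOC1")
  fit <- fit_architecture(arch, dat, clocks, n_restarts = 2, seed = 1,
                          maxit = 60)
  td <- tidy(fit)
  expect_identical(td$term, c("v_max", "K_TOC1", "d"))
  gl <- glance(fit)
  expect_equal(gl$aicc, aicc(fit$rss, 52, 3))
  path <- withr::local_tempfile(fileext = ".json")
  fit_to_json(fit, path)
  back <- jsonlite::fromJSON(path)
  expect_equal(back$rss, fit$rss)
  expect_equal(back$params$d, fit$params$d)
  expect_error(fit_architecture(arch, dat, clocks, n_restarts = 0), "at least 1")
})
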