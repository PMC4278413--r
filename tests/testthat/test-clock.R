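test_that("wild-type surrogate waveforms respect the canonical phase ordering", {
  clk <- simulate_clock(light_regime(12), duration = 48, step = 0.25)
  day1 <- dplyr::filter(tibble::as_tibble(clk), time_h < 24)
  peak_of <- function(sp) day1$time_h[which.max(day1[[sp]])]
  expect_gte(peak_of("LHY_CCA1"), 0)
  expect_lte(peak_of("LHY_CCA1"), 4)   # LHY/CCA1 maximal in the early morning
  expect_true(peak_of("PRR9") < peak_of("PRR7"))
  expect_true(peak_of("PRR7") < peak_of("NI"))
  expect_true(peak_of("NI") < peak_of("TOC1"))
  expect_gte(peak_of("TOC1"), 11)      # near dusk
  expect_lte(peak_of("TOC1"), 15)
  # EC activity low through the afternoon, high across late night / dawn
  afternoon <- day1$EC[day1$time_h >= 6 & day1$time_h <= 12]
  expect_lt(max(afternoon) / max(day1$EC), 0.25)
  expect_gt(day1$EC[day1$time_h == 0] / max(day1$EC), 0.5)
})

test_that("surrogate waveforms are non-negative and exactly 24-h periodic", {
  for (hl in c(8, 24)) {
    clk <- simulate_clock(light_regime(hl), duration = 96, step = 0.5)
    m <- as.matrix(tibble::as_tibble(clk)[-1])
    expect_true(all(m >= 0))
    first <- clk$time_h <= 72 + 1e-9
    shifted <- clk$time_h >= 24 - 1e-9
    expect_lt(max(abs(m[first, ] - m[shifted, ])), 1e-9)
  }
})

test_that("knockouts zero a species and leave the others untouched", {
  wt <- simulate_clock(light_regime(12))
  ko <- simulate_clock(light_regime(12), genotype = genotype("TOC1"))
  expect_true(all(ko$TOC1 == 0))
  for (sp in setdiff(clock_species(), "TOC1")) {
    expect_identical(ko[[sp]], wt[[sp]])
  }
})

test_that("amplitude modifiers scale waveforms multiplicatively", {
  wt <- simulate_clock(light_regime(12))
  mod <- simulate_clock(light_regime(12),
                        genotype = genotype(modifiers = c(LHY_CCA1 = 2)))
  expect_equal(mod$LHY_CCA1, 2 * wt$LHY_CCA1)
  expect_identical(mod$EC, wt$EC)
})

test_that("genotype application is idempotent", {
  g <- genotype(c("NI", "PRR7", "PRR9"), c(LHY_CCA1 = 2))
  clk <- simulate_clock(light_regime(24), genotype = g)
  again <- apply_genotype(clk, g)
  expect_identical(tibble::as_tibble(again), tibble::as_tibble(clk))
})

test_that("invalid clock inputs are rejected", {
  expect_error(genotype("NOT_A_GENE"), "Unknown species")
  expect_error(genotype(modifiers = c(TOC1 = -1)), "non-negative")
  expect_error(simulate_clock(light_regime(12), step = 5), "divide 24")
  expect_error(simulate_clock(light_regime(12), duration = 24), "48")
  expect_error(light_regime(30), "0, 24")
})

test_that("mutant genotype panel is non-negative under arbitrary modifiers", {
  set.seed(11)
  for (i in 1:10) {
    sp <- sample(clock_species(), sample(1:3, 1))
    mods <- setNames(runif(2, 0, 3),
                     sample(setdiff(clock_species(), sp), 2))
    clk <- simulate_clock(light_regime(sample(c(8, 12, 16, 24), 1)),
                          genotype = genotype(sp, mods))
    expect_true(all(as.matrix(tibble::as_tibble(clk)[-1]) >= 0))
  }
})
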