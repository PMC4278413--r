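# AICc scores as printed in the published ranking, used as input data for
# the weight computation
published_scores <- c(-807.29, -746.64, -732.40, -700.14, -316.76, -316.47,
                      -257.29, -220.30, -105.04, -76.48, 2.80, 4.16, 10.27)

fake_fit <- function(label, rss, n = 52, k = 3) {
  arch <- if (grepl("↑", label) || grepl("↓", label)) {
    arch_by_label(label)
  } else cbf_architecture(character(), "EC")
  f <- list(arch = arch, params = NULL, rss = rss, n_points = n, k_free = k)
  f$arch$label <- label
  structure(f, class = "cbf_fit")
}

test_that("the AICc score matches the closed form", {
  # hand evaluation: n=52, k_free=5 => k=6:
  # 52*log(1/52) + 12 + 2*6*7/45
  expect_equal(aicc(1, 52, 5), -191.5980067, tolerance = 1e-7)
  # penalty strictly increases with model complexity at fixed rss and n
  scores <- vapply(1:6, function(k) aicc(2, 52, k), 0)
  expect_true(all(diff(scores) > 0))
  # symmetry: equal rss, k, n give equal scores
  expect_identical(aicc(0.7, 40, 4), aicc(0.7, 40, 4))
  expect_error(aicc(0, 52, 5), "positive")
  expect_error(aicc(1, 7, 5), "Small-sample")
})

test_that("Akaike weights are normalised, stable and shift-invariant", {
  w <- aicc_weights(published_scores)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_equal(round(w, 2), c(1, rep(0, 12)))
  expect_equal(aicc_weights(c(5, 5)), c(0.5, 0.5))
  expect_equal(aicc_weights(c(0, 2)),
               c(1, exp(-1)) / (1 + exp(-1)))
  # adding a constant to every score changes nothing
  expect_equal(aicc_weights(published_scores + 1e4),
               w, tolerance = 1e-12)
  # extreme scores do not overflow
  expect_equal(sum(aicc_weights(c(-1e8, -1e8 + 10))), 1)
  expect_error(aicc_weights(numeric()), "non-empty")
})

test_that("rank_ensemble sorts, weights and annotates deterministically", {
  fits <- list(fake_fit("B", rss = 2), fake_fit("A", rss = 1),
               fake_fit("C", rss = 4))
  tab <- rank_ensemble(fits)
  expect_identical(tab$label, c("A", "B", "C"))
  expect_identical(tab$rank, 1:3)
  expect_equal(sum(tab$weight), 1, tolerance = 1e-12)
  # permutation of the input leaves the table unchanged
  tab2 <- rank_ensemble(fits[c(3, 1, 2)])
  expect_equal(tidy(tab2), tidy(tab))
  # exact ties break by label
  tie <- rank_ensemble(list(fake_fit("Z", 1), fake_fit("M", 1)))
  expect_identical(tie$label, c("M", "Z"))
  # singleton gets weight 1
  single <- rank_ensemble(list(fake_fit("A", 3)))
  expect_equal(single$weight, 1)
  expect_error(rank_ensemble(list(fake_fit("A", 1, n = 52),
                                  fake_fit("B", 1, n = 40))),
               "same number of data points")
})

test_that("selection tables render like the published layout", {
  fits <- list(fake_fit("EC↓:TOC1↓:LHY/CCA1↑", 0.5, k = 5),
               fake_fit("EC↓", 5, k = 3))
  tab <- rank_ensemble(fits, features = c(
    "EC↓:TOC1↓:LHY/CCA1↑" = "Good fit to waveform and phase"))
  lines <- format_selection_table(tab)
  expect_length(lines, 3)
  expect_match(lines[1], "Rank")
  expect_match(lines[2], "EC↓:TOC1↓:LHY/CCA1↑")
  expect_match(lines[2], "Good fit")
  gl <- glance(tab)
  expect_identical(gl$top_label, "EC↓:TOC1↓:LHY/CCA1↑")
})
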