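# independent Welch oracle, straight from the formula
welch_oracle <- function(x, y) {
  se2 <- stats::var(x) / length(x) + stats::var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((stats::var(x) / length(x))^2 / (length(x) - 1) +
                   (stats::var(y) / length(y))^2 / (length(y) - 1))
  list(t = t, p = 2 * stats::pt(-abs(t), df))
}

panel_of <- function(values, prefix = "A") {
  tibble::tibble(allele = paste0(prefix, seq_along(values)), mfi = values)
}

calls_for <- function(panel, types) {
  tibble::tibble(allele = panel$allele, type = types)
}

test_that("type summary matches the Welch oracle on a 3-vs-3 panel", {
  panel <- panel_of(c(8000, 8400, 8800, 600, 680, 760))
  calls <- calls_for(panel, rep(c("type_I", "type_II"), each = 3))
  gs <- summarize_by_type(panel, calls)
  expect_equal(gs$mean_I, 8400)
  expect_equal(gs$mean_II, 680)
  expect_equal(gs$sd_I, 400)
  expect_equal(gs$sd_II, 80)
  oracle <- welch_oracle(c(8000, 8400, 8800), c(600, 680, 760))
  expect_equal(gs$statistic, oracle$t, tolerance = 1e-12)
  expect_equal(gs$p_value, oracle$p, tolerance = 1e-12)
  # Mann-Whitney alternative is exposed
  gw <- summarize_by_type(panel, calls, test = "wilcoxon")
  expect_true(gw$p_value < 0.1)
})

test_that("identical constant groups give t = 0, p = 1", {
  panel <- panel_of(rep(10, 6))
  calls <- calls_for(panel, rep(c("type_I", "type_II"), each = 3))
  gs <- summarize_by_type(panel, calls)
  expect_equal(gs$statistic, 0)
  expect_equal(gs$p_value, 1)
})

test_that("summary is order-invariant and label-swap negates t", {
  panel <- panel_of(c(9, 7, 8, 1, 2, 3))
  calls <- calls_for(panel, rep(c("type_I", "type_II"), each = 3))
  base <- summarize_by_type(panel, calls)
  shuffled <- panel[withr::with_seed(1, sample(nrow(panel))), ]
  expect_equal(summarize_by_type(shuffled, calls), base)
  swapped_calls <- calls
  swapped_calls$type <- c(type_I = "type_II", type_II = "type_I")[calls$type]
  swapped <- summarize_by_type(panel, swapped_calls)
  expect_equal(swapped$statistic, -base$statistic)
  expect_equal(swapped$mean_I, base$mean_II)
})

test_that("replicate wells are averaged per allele before grouping", {
  panel <- tibble::tibble(
    allele = rep(c("A1", "A2", "A3", "A4"), each = 2),
    replicate = rep(1:2, 4),
    mfi = c(100, 120, 200, 220, 10, 30, 40, 60)
  )
  calls <- tibble::tibble(allele = paste0("A", 1:4),
                          type = rep(c("type_I", "type_II"), each = 2))
  gs <- summarize_by_type(panel, calls)
  expect_equal(gs$mean_I, mean(c(110, 210)))
  expect_equal(gs$n_I, 2)
})

test_that("undersized groups return the summary with the test unavailable", {
  panel <- panel_of(c(5, 6, 7))
  calls <- calls_for(panel, c("type_I", "type_II", "type_II"))
  gs <- summarize_by_type(panel, calls)
  expect_false(gs$test_available)
  expect_true(is.na(gs$p_value))
  expect_equal(gs$mean_I, 5)
  expect_error(summarize_by_type(panel_of(c(1, 2)), calls_for(panel_of(c(1, 2)), "type_I")[1, ]),
               "without a type call")
})

test_that("pattern concordance is a Pearson r over shared alleles", {
  panel <- panel_of(c(10, 40, 90, 20))
  expect_equal(pattern_concordance(panel, panel), 1.0)
  negated <- panel
  negated$mfi <- 100 - panel$mfi
  expect_equal(pattern_concordance(panel, negated), -1.0)
  expect_error(pattern_concordance(panel[1:2, ], panel[1:2, ]), "3 shared")
  flat <- panel
  flat$mfi <- rep(5, 4)
  expect_error(pattern_concordance(panel, flat), "zero variance")
})

test_that("opposite-reactivity panels anticorrelate by construction", {
  calls <- classify_alleles(mica_alignment())
  s001 <- simulate_mfi_panel(calls, reagent = "S001", seed = 11)
  s002 <- simulate_mfi_panel(calls, reagent = "S002", seed = 12)
  expect_true(pattern_concordance(s001, s002) < 0)
})

test_that("bimodal split finds the obvious gap and rejects flat panels", {
  panel <- panel_of(c(1, 2, 100, 101))
  sp <- bimodal_split(panel)
  expect_setequal(sp$high, c("A3", "A4"))
  expect_setequal(sp$low, c("A1", "A2"))
  expect_true(sp$threshold > 2 && sp$threshold < 100)
  expect_error(bimodal_split(panel_of(rep(5, 5))), "no split")
  expect_error(bimodal_split(panel_of(c(1, 2, 3))), "at least 4")
})

test_that("split threshold agrees with a brute-force Otsu re-implementation", {
  # oracle: minimise total within-group variance over every cut of the
  # sorted values (equivalent formulation of the Otsu criterion)
  otsu_oracle <- function(v) {
    v <- sort(v)
    cuts <- seq_len(length(v) - 1)
    within <- vapply(cuts, function(k) {
      lo <- v[1:k]; hi <- v[(k + 1):length(v)]
      sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    }, numeric(1))
    k <- cuts[which.min(within)]
    (v[k] + v[k + 1]) / 2
  }
  for (seed in 1:10) {
    values <- withr::with_seed(seed, c(stats::rnorm(7, 100, 20),
                                       stats::rnorm(5, 400, 30)))
    sp <- bimodal_split(panel_of(values))
    expect_equal(sp$threshold, otsu_oracle(values))
  }
})

test_that("well-separated generated panels are split on the true partition", {
  calls <- classify_alleles(mica_alignment())
  truth_high <- calls$allele[calls$type == "type_I"]
  for (seed in 1:20) {
    # separation 8000 - 700 = 7300 >> 6 generating SDs (6 * 350)
    panel <- simulate_mfi_panel(calls, mean_I = 8000, sd_I = 350,
                                mean_II = 700, sd_II = 90, seed = seed)
    sp <- bimodal_split(panel)
    expect_setequal(sp$high, truth_high)
  }
})
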