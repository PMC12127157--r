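test_that("generators are pure functions of their seed", {
  a <- simulate_alleles(20, seed = 9)
  b <- simulate_alleles(20, seed = 9)
  expect_equal(a$table, b$table)
  expect_equal(a$truth, b$truth)
  expect_false(identical(simulate_alleles(20, seed = 10)$table, a$table))

  calls <- tibble::tibble(allele = c("x", "y"), type = c("type_I", "type_II"))
  expect_equal(simulate_mfi_panel(calls, seed = 4),
               simulate_mfi_panel(calls, seed = 4))
  params <- tibble::tibble(allele = "a", bottom = 0, top = 90, hill = 2,
                           midpoint = 25)
  expect_equal(simulate_dose_response(params, seed = 4),
               simulate_dose_response(params, seed = 4))
  rates <- tibble::tibble(target = "t", ratio = 1, rate = 0.3)
  expect_equal(simulate_killing(rates, seed = 4),
               simulate_killing(rates, seed = 4))
})

test_that("generated site tables live on the packaged positions", {
  sim <- simulate_alleles(10, seed = 2)
  expect_s3_class(sim$table, "mica_site_table")
  expect_equal(st_positions(sim$table), st_positions(mica_alignment()))
  expect_equal(nrow(sim$truth), 10)
  expect_error(simulate_alleles(0), ">= 1")
})

test_that("zero discordance means the classifier recovers every label", {
  for (p1 in c(0, 0.5, 1)) {
    sim <- simulate_alleles(100, p_type_I = p1, discordance_rate = 0,
                            seed = 31)
    calls <- classify_alleles(sim$table)
    expect_equal(signature_concordance(calls, sim$truth), 1.0)
  }
})

test_that("classifier accuracy under discordance matches a per-allele oracle", {
  sim <- simulate_alleles(500, discordance_rate = 0.15, seed = 77)
  calls <- classify_alleles(sim$table)
  # oracle: recount signature matches directly from the generated residues
  sig <- mica_signature()
  tbl <- as.data.frame(sim$table)
  oracle <- vapply(sim$truth$allele, function(nm) {
    res <- tbl$residue[tbl$allele == nm][match(sig$position,
                                               tbl$position[tbl$allele == nm])]
    sI <- sum(res == sig$type_I); sII <- sum(res == sig$type_II)
    if (sI > sII) "type_I" else if (sII > sI) "type_II" else {
      r129 <- res[sig$position == 129]
      if (r129 == "M") "type_I" else if (r129 == "V") "type_II" else "unclassified"
    }
  }, character(1))
  expect_equal(calls$type, unname(oracle))
  # reproducible accuracy against the generating truth
  acc <- signature_concordance(calls, sim$truth)
  acc2 <- signature_concordance(
    classify_alleles(simulate_alleles(500, discordance_rate = 0.15,
                                      seed = 77)$table),
    sim$truth
  )
  expect_equal(acc, acc2)
})

test_that("MFI panels honour their generating parameters", {
  calls <- tibble::tibble(allele = paste0("a", 1:6),
                          type = rep(c("type_I", "type_II"), 3))
  exact <- simulate_mfi_panel(calls, mean_I = 8000, sd_I = 0, mean_II = 700,
                              sd_II = 0, seed = 1)
  expect_true(all(exact$mfi[exact$allele %in% calls$allele[calls$type == "type_I"]] == 8000))
  expect_true(all(exact$mfi[exact$allele %in% calls$allele[calls$type == "type_II"]] == 700))

  mixed <- tibble::tibble(allele = c("a", "b", "c"),
                          type = c("type_I", "unclassified", "type_II"))
  expect_warning(panel <- simulate_mfi_panel(mixed, seed = 1),
                 "unclassified")
  expect_false("b" %in% panel$allele)
})

test_that("panel moments converge to the generating parameters", {
  calls <- tibble::tibble(allele = sprintf("a%04d", 1:2000),
                          type = rep(c("type_I", "type_II"), 1000))
  panel <- simulate_mfi_panel(calls, replicates = 1, seed = 13)
  pars <- mica_mfi_params()[mica_mfi_params()$reagent == "S001", ]
  m_I <- mean(panel$mfi[panel$allele %in% calls$allele[calls$type == "type_I"]])
  m_II <- mean(panel$mfi[panel$allele %in% calls$allele[calls$type == "type_II"]])
  expect_lt(abs(m_I - pars$mean_I), 3 * pars$sd_I / sqrt(1000))
  expect_lt(abs(m_II - pars$mean_II), 3 * pars$sd_II / sqrt(1000))
})

test_that("dose-response draws are clipped to [0, 100]", {
  params <- tibble::tibble(allele = "a", bottom = 0, top = 99, hill = 2,
                           midpoint = 10)
  d <- simulate_dose_response(params, noise_sd = 5, replicates = 20, seed = 8)
  expect_true(all(d$response <= 100 & d$response >= 0))
})

test_that("killing draws respect degenerate rates and binomial spread", {
  zero <- simulate_killing(tibble::tibble(target = "t", ratio = c(1, 3),
                                          rate = 0), seed = 1)
  expect_true(all(zero$n_dead == 0))
  one <- simulate_killing(tibble::tibble(target = "t", ratio = c(1, 3),
                                         rate = 1), seed = 1)
  expect_true(all(one$n_dead == one$n_total))
  # rate 0.5 at n = 10000: within 48-52% for the vast majority of seeds
  eff <- vapply(1:100, function(seed) {
    k <- simulate_killing(tibble::tibble(target = "t", ratio = 1, rate = 0.5),
                          n_total = 10000, replicates = 1, seed = seed)
    killing_efficiency(k$n_dead, k$n_total)
  }, numeric(1))
  expect_gte(mean(eff >= 48 & eff <= 52), 0.99)
})
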