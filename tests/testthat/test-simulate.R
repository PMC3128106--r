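test_that("degenerate allele frequencies give constant genotypes", {
  expect_true(all(simulate_genotypes(0, 100, seed = 1) == 0))
  expect_true(all(simulate_genotypes(1, 100, seed = 1) == 2))
  expect_error(simulate_genotypes(1.2, 10), "freq")
})

test_that("genotypes follow Hardy-Weinberg proportions at large n", {
  n <- 50000
  g <- simulate_genotypes(0.3, n, seed = 11)
  # mean dose within 3 Monte-Carlo SE of 2f
  se_mc <- sqrt(2 * 0.3 * 0.7 / n)
  expect_lt(abs(mean(g) - 0.6), 3 * se_mc)
  f_hat <- mean(g) / 2
  expected <- n * c((1 - f_hat)^2, 2 * f_hat * (1 - f_hat), f_hat^2)
  observed <- tabulate(g + 1, 3)
  chi2 <- sum((observed - expected)^2 / expected)
  expect_gt(stats::pchisq(chi2, df = 1, lower.tail = FALSE), 0.001)
})

test_that("linked-pair simulation hits feasible LD targets", {
  # perfect LD with equal frequencies: the two loci are copies
  lp <- simulate_linked_pair(0.3, 0.3, 1, 500, seed = 3)
  expect_identical(lp$causal, lp$tag)
  # independence
  lp0 <- simulate_linked_pair(0.3, 0.5, 0, 100000, seed = 4)
  expect_lt(ld_r2(lp0$counts)$r2, 3 * 1 / sqrt(100000))
  # feasible grid: empirical haplotype r2 within 3 MC SE of the realized target
  grid <- expand.grid(pA = c(0.2, 0.5), pB = c(0.2, 0.4), r2 = c(0.1, 0.3))
  for (i in seq_len(nrow(grid))) {
    n <- 50000
    lp <- suppressWarnings(
      simulate_linked_pair(grid$pA[i], grid$pB[i], grid$r2[i], n,
                           seed = 100 + i))
    emp <- ld_r2(lp$counts)$r2
    # delta-method MC SE of r2-hat, approximated as 2 r sqrt((1-r2)/2n)
    se_mc <- 2 * sqrt(lp$realized_r2) * sqrt((1 - lp$realized_r2) / (2 * n)) +
      1e-3
    expect_lt(abs(emp - lp$realized_r2), 3 * se_mc)
  }
  # infeasible request is clipped with a warning and reported
  expect_warning(lp <- simulate_linked_pair(0.2, 0.4, 0.9, 100, seed = 5),
                 "infeasible")
  expect_equal(lp$realized_r2, hap_r2_oracle(0.2, 0.4, min(0.2 * 0.6,
                                                           0.8 * 0.4)))
})

test_that("cohort tables are reproducible and respect the scenario", {
  sc <- basic_scenario(n = 500, freq = 0.25, beta = 2, missing_rate = 0.05)
  d1 <- simulate_cohort(sc, seed = 9)
  d2 <- simulate_cohort(sc, seed = 9)
  expect_identical(d1, d2)
  expect_false(identical(d1, simulate_cohort(sc, seed = 10)))
  expect_true(all(d1$rs1 %in% c(0:2, NA)))
  expect_gt(sum(is.na(d1$rs1)), 0)
  expect_true(all(is.na(d1$menopause[d1$sex == "M"])))
  expect_true(all(d1$tg > 0))
  # total cholesterol is built so Friedewald recovers LDL exactly
  ldl <- friedewald_ldl(d1$tc, d1$hdl, d1$tg)
  ok <- d1$tg <= 400
  expect_equal(ldl[ok], (d1$tc - d1$hdl - d1$tg / 5)[ok])
})

test_that("adding a covariate effect does not perturb the genotype stream", {
  sc1 <- basic_scenario(n = 300, freq = 0.4)
  sc2 <- basic_scenario(n = 300, freq = 0.4,
                        covariate_effects = data.frame(covariate = "age",
                                                       trait = "HDL",
                                                       beta = 0.1))
  d1 <- simulate_cohort(sc1, seed = 21)
  d2 <- simulate_cohort(sc2, seed = 21)
  expect_identical(d1$rs1, d2$rs1)
  expect_identical(d1$age, d2$age)
  expect_false(identical(d1$hdl, d2$hdl))
})

test_that("medication acts as the configured constant offset", {
  # keep LDL far from the positivity floor so the shift stays exact
  means <- c(HDL = 52, LDL = 160, lnTG = 4.7)
  sds <- c(HDL = 15, LDL = 20, lnTG = 0.5)
  sc <- basic_scenario(n = 20000, medication_rate = 1,
                       trait_means = means, trait_sds = sds,
                       medication_offset = c(HDL = 0, LDL = -40, lnTG = 0))
  sc0 <- basic_scenario(n = 20000, medication_rate = 0,
                        trait_means = means, trait_sds = sds,
                        medication_offset = c(HDL = 0, LDL = -40, lnTG = 0))
  d <- simulate_cohort(sc, seed = 2)
  d0 <- simulate_cohort(sc0, seed = 2)
  # TG draws above 400 mg/dl make Friedewald LDL missing at identical
  # positions in both cohorts (same seed), so the offset is exact
  ldl <- friedewald_ldl(d$tc, d$hdl, d$tg)
  ldl0 <- friedewald_ldl(d0$tc, d0$hdl, d0$tg)
  expect_equal(mean(ldl, na.rm = TRUE) - mean(ldl0, na.rm = TRUE), -40,
               tolerance = 1e-8)
})

test_that("overlarge genetic variance is rejected", {
  sc <- basic_scenario(n = 50, freq = 0.5, beta = 40)  # 2pq b^2 = 800 > 225
  expect_error(simulate_cohort(sc, seed = 1), "variance")
})

test_that("simulated effect sizes are recovered by the regression", {
  sc <- basic_scenario(n = 25000, freq = 0.32, beta = 3.64)
  d <- simulate_cohort(sc, seed = 33)
  fit <- fit_additive_model(d, "rs1", "HDL", model = 1)
  expect_lt(abs(fit$beta - 3.64), 3 * fit$se)
})
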