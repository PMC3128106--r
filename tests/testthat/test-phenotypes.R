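test_that("Friedewald LDL follows the formula with the TG cut-off", {
  expect_equal(friedewald_ldl(200, 50, 100), 130)
  expect_true(is.na(friedewald_ldl(200, 50, 450)))   # TG > 400 -> missing
  expect_equal(friedewald_ldl(200, 50, 400), 70)     # boundary retained
  expect_equal(friedewald_ldl(180, 60, 1e-4), 120, tolerance = 1e-4)
  expect_true(is.na(friedewald_ldl(NA, 50, 100)))
  expect_error(friedewald_ldl(200, -5, 100), "positive")
})

test_that("trait transform is ln for TG and identity otherwise", {
  expect_equal(transform_trait(100, "lnTG"), log(100))
  expect_equal(transform_trait(c(50, 500), "lnTG"), c(3.912023, 6.214608),
               tolerance = 1e-6)
  expect_identical(transform_trait(55, "HDL"), 55)
  expect_error(transform_trait(c(10, 0), "lnTG"), "positive")
})

make_participants <- function(age = 30, fasting = 10, tg = 100, med = FALSE) {
  k <- max(lengths(list(age, fasting, tg, med)))
  data.frame(id = sprintf("p%d", seq_len(k)), age = age,
             fasting_hours = fasting, tg = tg, on_lipid_med = med)
}

test_that("exclusion rules use the stated boundaries", {
  d <- make_participants(age = c(17.9, 18, 45), fasting = c(10, 10, 10))
  f <- apply_exclusions(d, "HDL")
  expect_equal(nrow(f$data), 2)
  expect_equal(f$exclusions$reason, "age_lt_18")

  d <- make_participants(age = 30, fasting = c(7.99, 8, 12))
  f <- apply_exclusions(d, "LDL")
  expect_equal(nrow(f$data), 2)
  expect_equal(f$exclusions$reason, "nonfasting")

  d <- make_participants(tg = c(999, 1000, 1000.5))
  expect_equal(nrow(apply_exclusions(d, "lnTG")$data), 2)    # 1000 retained
  expect_equal(nrow(apply_exclusions(d, "HDL")$data), 3)     # rule lnTG-only

  d <- make_participants(med = c(TRUE, FALSE))
  expect_equal(nrow(apply_exclusions(d, "HDL")$data), 2)
  f <- apply_exclusions(d, "HDL", include_medicated = FALSE)
  expect_equal(f$exclusions$reason, "lipid_medication")
})

test_that("exclusions are idempotent and partition the input", {
  set.seed(5)
  d <- make_participants(age = runif(200, 10, 80),
                         fasting = runif(200, 0, 16),
                         tg = runif(200, 50, 1500),
                         med = runif(200) < 0.3)
  f1 <- apply_exclusions(d, "lnTG", include_medicated = FALSE)
  f2 <- apply_exclusions(f1$data, "lnTG", include_medicated = FALSE)
  expect_identical(f1$data, f2$data)
  expect_equal(nrow(f2$exclusions), 0)
  expect_equal(nrow(f1$data) + nrow(f1$exclusions), nrow(d))
  # first-triggered-reason accounting, fixed order age -> fasting -> TG -> med
  young_nonfasting <- d$age < 18 & d$fasting_hours < 8
  expect_equal(sum(f1$exclusions$reason == "age_lt_18"), sum(d$age < 18))
  expect_true(all(f1$exclusions$reason[match(
    d$id[young_nonfasting], f1$exclusions$id)] == "age_lt_18"))
})

test_that("missing columns raise a schema error", {
  expect_error(apply_exclusions(data.frame(age = 30), "HDL"), "lacks column")
})

test_that("medication adjustment restores the pre-treatment scale", {
  off <- c(HDL = 0, LDL = -40, lnTG = -0.2)
  expect_equal(adjust_for_medication(100, TRUE, "LDL", off), 140)
  expect_equal(adjust_for_medication(100, FALSE, "LDL", off), 100)
  expect_error(adjust_for_medication(1, TRUE, "HDL", c(LDL = -40)), "offset")

  # round trip against the simulator's subtractive treatment effect
  sc_med <- basic_scenario(n = 20000, medication_rate = 0.5,
                           medication_offset = c(HDL = 0, LDL = -40,
                                                 lnTG = 0))
  sc_unmed <- basic_scenario(n = 20000, medication_rate = 0,
                             medication_offset = c(HDL = 0, LDL = -40,
                                                   lnTG = 0))
  d <- simulate_cohort(sc_med, seed = 8)
  d0 <- simulate_cohort(sc_unmed, seed = 8)
  ldl <- friedewald_ldl(d$tc, d$hdl, d$tg)
  adj <- adjust_for_medication(ldl, d$on_lipid_med, "LDL",
                               c(LDL = -40))
  ldl0 <- friedewald_ldl(d0$tc, d0$hdl, d0$tg)
  se_mc <- sd(ldl, na.rm = TRUE) / sqrt(sum(!is.na(ldl)))
  expect_lt(abs(mean(adj, na.rm = TRUE) - mean(ldl0, na.rm = TRUE)),
            3 * se_mc)
})
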