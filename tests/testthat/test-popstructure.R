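test_that("Weir-Cockerham theta behaves at the anchors", {
  # no differentiation
  f <- weir_cockerham_fst(0.3, 1000, 0.3, 1000)
  expect_lt(abs(f$theta), 1e-3)
  expect_lte(f$theta, 1e-12)  # equal frequencies, equal n: theta <= 0
  # fixed difference
  expect_gt(weir_cockerham_fst(0, 5000, 1, 5000)$theta, 0.999)
  # the published FADS1 anchor: EA vs AA with per-trait n_max
  expect_equal(round(weir_cockerham_fst(0.66, 25167, 0.91, 10436)$theta, 2),
               0.15)
  # both monomorphic at the same allele -> undefined
  expect_true(weir_cockerham_fst(0, 100, 0, 100)$undefined)
  # symmetry in the two populations
  f1 <- weir_cockerham_fst(0.2, 400, 0.7, 900)
  f2 <- weir_cockerham_fst(0.7, 900, 0.2, 400)
  expect_equal(f1$theta, f2$theta, tolerance = 1e-12)
  expect_equal(f1$a, f2$a, tolerance = 1e-12)
})

test_that("theta approaches the large-n closed form on a frequency grid", {
  # equal n -> infinity: theta -> s2 / (s2 + p(1-p) terms), i.e. a/(a+b+c)
  # with the finite-sample corrections vanishing
  grid <- expand.grid(p1 = c(0.1, 0.3, 0.5, 0.8), p2 = c(0.2, 0.5, 0.9))
  for (i in seq_len(nrow(grid))) {
    p1 <- grid$p1[i]; p2 <- grid$p2[i]
    n <- 5e6
    th <- weir_cockerham_fst(p1, n, p2, n)$theta
    pbar <- (p1 + p2) / 2
    s2 <- (p1 - pbar)^2 + (p2 - pbar)^2
    hbar <- p1 * (1 - p1) + p2 * (1 - p2)
    limit <- s2 / (s2 + (pbar * (1 - pbar) - s2 / 2 - hbar / 2) + hbar / 2)
    expect_equal(th, limit, tolerance = 1e-3)
  }
})

test_that("allele-frequency correlations and panel counts are computed over
           pairwise-complete SNPs", {
  caf <- cbind(EA = c(0.1, 0.5, 0.9, NA), XX = c(0.2, 0.5, 0.8, 0.3))
  rownames(caf) <- paste0("s", 1:4)
  cc <- caf_correlation(caf, "EA", "XX")
  expect_equal(cc$n_snps, 3)
  expect_equal(cc$r, stats::cor(c(0.1, 0.5, 0.9), c(0.2, 0.5, 0.8)))
  expect_equal(caf_correlation(cbind(EA = caf[, 1], EA2 = caf[, 1]),
                               "EA", "EA2")$r, 1)
  expect_error(caf_correlation(caf[1:2, ], "EA", "XX"), "fewer than 3")

  tab <- list(caf = cbind(EA = c(0.2, 0.4, 0.6), XX = c(0.2, 0.4, 0.6)),
              n = matrix(1000, 3, 2, dimnames = list(NULL, c("EA", "XX"))))
  rownames(tab$caf) <- paste0("s", 1:3)
  ps <- fst_panel_summary(tab, "EA", threshold = 0.15)
  expect_equal(ps$n_above, 0)
  expect_equal(fst_panel_summary(tab, "EA", threshold = 1.0)$n_above, 0)
})

test_that("CAF panels merge duplicate SNPs and police discrepancies", {
  t1 <- data.frame(snp = c("a", "b"), population = "EA", caf = c(0.80, 0.3))
  t2 <- data.frame(snp = "a", population = "EA", caf = 0.79)
  sizes <- data.frame(trait = c("HDL", "LDL"), population = "EA",
                      n_max = c(100, 200))
  tab <- build_caf_table(list(HDL = t1, LDL = t2), sizes)
  expect_equal(tab$caf["a", "EA"], 0.795)
  expect_equal(tab$n["a", "EA"], 100)  # first reporting trait's n_max
  t2$caf <- 0.60
  expect_error(build_caf_table(list(HDL = t1, LDL = t2), sizes),
               "discrepancy")
})

test_that("LD statistics recover textbook cases and the simulator target", {
  # independence
  ind <- ld_r2(c(25, 25, 25, 25))
  expect_equal(ind$D, 0)
  expect_equal(ind$r2, 0)
  # perfect coupling at 0.5/0.5
  pc <- ld_r2(c(50, 0, 0, 50))
  expect_equal(pc$r2, 1)
  expect_equal(pc$Dprime, 1)
  # label swap at one locus: D flips sign, r2 invariant
  cts <- c(40, 20, 10, 30)
  sw <- ld_r2(cts[c(2, 1, 4, 3)])
  expect_equal(sw$D, -ld_r2(cts)$D, tolerance = 1e-12)
  expect_equal(sw$r2, ld_r2(cts)$r2, tolerance = 1e-12)
  # monomorphic flag
  expect_true(ld_r2(c(10, 0, 10, 0))$undefined)
  # simulator round trip at a feasible target
  lp <- simulate_linked_pair(0.3, 0.3, 0.5, 100000, seed = 12)
  expect_equal(lp$realized_r2, 0.5, tolerance = 1e-12)
  expect_lt(abs(ld_r2(lp$counts)$r2 - 0.5), 3 * 0.005)
})
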