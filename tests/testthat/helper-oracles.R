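# Independent oracles and shared scenario builders for the suite.

# Brute-force OLS via the normal equations; independent of stats::lm.
ols_oracle <- function(y, X) {
  X <- cbind(Intercept = 1, X)
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  resid <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  s2 <- sum(resid^2) / df
  se <- sqrt(diag(s2 * solve(XtX)))
  list(beta = drop(beta), se = se, df = df)
}

# Closed-form IVW pooling for a handful of strata, written straight from the
# defining formulas.
ivw_oracle <- function(beta, se) {
  w <- 1 / se^2
  bm <- sum(w * beta) / sum(w)
  sem <- 1 / sqrt(sum(w))
  Q <- sum(w * (beta - bm)^2)
  k <- length(beta)
  I2 <- if (k > 1 && Q > 0) max(0, (Q - (k - 1)) / Q) * 100 else 0
  list(beta = bm, se = sem, Q = Q, I2 = I2)
}

# Expected two-locus r^2 by direct enumeration of the haplotype table.
hap_r2_oracle <- function(pA, pB, D) {
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

# Small single-SNP scenario used across tests.
basic_scenario <- function(n = 1000, freq = 0.3, beta = 0, trait = "HDL",
                           snp = "rs1", ...) {
  eff <- if (beta != 0) data.frame(snp = snp, trait = trait, beta = beta)
  args <- list(population = "EA", study = "S1", n = n,
               snp_freqs = stats::setNames(freq, snp), snp_effects = eff,
               medication_rate = 0, fasting_nonfasting_rate = 0)
  args <- utils::modifyList(args, list(...))
  do.call(cohort_scenario, args)
}
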