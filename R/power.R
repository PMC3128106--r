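#' Analytic power for an additive quantitative-trait association test
#'
#' For an additive model, a coded-allele frequency `caf` and per-allele
#' effect `beta`, the variance explained is `v = 2 caf (1 - caf) beta^2`.
#' With `n` unrelated individuals the two-sided Wald test at level `alpha`
#' has non-centrality `lambda = n v / (sd^2 - v)` (residual-variance
#' parameterisation: the marginal trait SD is what population tables report)
#' and power `1 - pnorm(z_{1-alpha/2} - sqrt(lambda)) +
#' pnorm(-z_{1-alpha/2} - sqrt(lambda))`.
#'
#' @param beta Effect per coded-allele copy (trait units).
#' @param caf Coded-allele frequency in `(0, 1)`.
#' @param n Sample size (>= 2).
#' @param trait_sd Marginal trait SD in the target population (same units).
#' @param alpha Two-sided significance level.
#' @param residual `"decomposed"` (default) computes the residual variance as
#'   `trait_sd^2 - v`; `"total"` uses `trait_sd^2` unchanged.
#' @return Power in `[0, 1]`.
#' @export
analytic_power <- function(beta, caf, n, trait_sd, alpha = 0.05,
                           residual = c("decomposed", "total")) {
  residual <- match.arg(residual)
  stopifnot(caf > 0, caf < 1, n >= 2, trait_sd > 0,
            alpha > 0, alpha < 1)
  v <- 2 * caf * (1 - caf) * beta^2
  if (v >= trait_sd^2)
    stop("genetic variance exceeds the trait variance; check beta/caf/sd")
  denom <- if (residual == "decomposed") trait_sd^2 - v else trait_sd^2
  lambda <- n * v / denom
  zc <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(zc - sqrt(lambda), lower.tail = FALSE) +
    stats::pnorm(-zc - sqrt(lambda))
}

#' Expected number of significant associations
#'
#' The expected count for a panel of tests is the sum of their individual
#' powers (each test is a Bernoulli trial with success probability equal to
#' its power).
#'
#' @param powers Per-test powers in `[0, 1]`.
#' @return Fractional expected count.
#' @export
expected_significant <- function(powers) {
  stopifnot(all(powers >= 0 & powers <= 1))
  sum(powers)
}

# Exact binomial point probabilities can underflow cleanly; the two-sided
# point-probability method sums all outcomes no more likely than the one
# observed (same convention as stats::binom.test).
.twosided_from_pmf <- function(pmf, k) {
  rel <- 1 + 1e-07
  min(1, sum(pmf[pmf <= pmf[k + 1] * rel]))
}

#' One-sample binomial test of an observed significant count
#'
#' Tests whether `k` observed significant associations among `m` tests is
#' compatible with the power-based expectation `E`, i.e. with a per-test
#' success probability `p0 = E/m`.  The two-sided p-value uses the
#' point-probability method (the sum of the probabilities of all outcomes no
#' more likely than the observed one); one-sided tails are also available.
#'
#' @param k Observed significant count, `0 <= k <= m`.
#' @param m Number of tests.
#' @param E Expected significant count, `0 <= E <= m` (see
#'   [expected_significant()]).
#' @param sided `"two"` (default), `"less"`, or `"greater"`.
#' @return P-value.
#' @export
binomial_test_observed <- function(k, m, E, sided = c("two", "less",
                                                      "greater")) {
  sided <- match.arg(sided)
  stopifnot(k >= 0, k <= m, E >= 0, E <= m, m >= 1)
  p0 <- E / m
  pmf <- stats::dbinom(0:m, m, p0)
  switch(sided,
         two = .twosided_from_pmf(pmf, k),
         less = stats::pbinom(k, m, p0),
         greater = stats::pbinom(k - 1, m, p0, lower.tail = FALSE))
}

#' Poisson-binomial distribution of the number of significant tests
#'
#' Exact probability mass function of the sum of independent Bernoulli trials
#' with unequal success probabilities (the per-test powers), computed by
#' dynamic-programming convolution.
#'
#' @param powers Success probabilities.
#' @return Numeric vector of `P(X = 0), ..., P(X = m)`.
#' @export
dpoisbinom <- function(powers) {
  stopifnot(all(powers >= 0 & powers <= 1))
  f <- 1
  for (p in powers) f <- c(f * (1 - p), 0) + c(0, f * p)
  f
}

#' Exact Poisson-binomial p-value for an observed significant count
#'
#' Reference distribution for [binomial_test_observed()] that respects
#' unequal per-test powers instead of collapsing them to their mean.
#' Two-sided p-values use the same point-probability method.
#'
#' @param k Observed count.
#' @param powers Per-test powers (at most 40 tests in exact mode).
#' @param sided `"two"`, `"less"`, or `"greater"`.
#' @return P-value.
#' @export
poisson_binomial_pvalue <- function(k, powers,
                                    sided = c("two", "less", "greater")) {
  sided <- match.arg(sided)
  m <- length(powers)
  if (m > 40)
    stop("exact mode supports at most 40 tests; use the binomial ",
         "approximation (binomial_test_observed) for larger panels")
  stopifnot(k >= 0, k <= m)
  pmf <- dpoisbinom(powers)
  switch(sided,
         two = .twosided_from_pmf(pmf, k),
         less = sum(pmf[seq_len(k + 1)]),
         greater = sum(pmf[seq(k + 1, m + 1)]))
}

#' Expected-versus-observed accounting for one trait and population
#'
#' Combines per-test powers into the expected significant count and tests
#' the observed count against it.
#'
#' @param k Observed significant count.
#' @param powers Per-test powers.
#' @param method `"binomial-two-sided"` (default), `"binomial-one-sided"`
#'   (lower tail), or `"poisson-binomial"` (exact two-sided).
#' @return One-row data frame: `m`, `k`, `E`, `p_value`, `method`.
#' @export
expected_observed <- function(k, powers,
                              method = c("binomial-two-sided",
                                         "binomial-one-sided",
                                         "poisson-binomial")) {
  method <- match.arg(method)
  m <- length(powers)
  E <- expected_significant(powers)
  p <- switch(method,
              "binomial-two-sided" = binomial_test_observed(k, m, E, "two"),
              "binomial-one-sided" = binomial_test_observed(k, m, E, "less"),
              "poisson-binomial" = poisson_binomial_pvalue(k, powers, "two"))
  data.frame(m = m, k = k, E = E, p_value = p, method = method,
             stringsAsFactors = FALSE)
}
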