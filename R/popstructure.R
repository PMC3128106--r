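#' Weir-Cockerham F_ST for two populations (allele frequencies only)
#'
#' Variance-component estimator of allele-frequency differentiation
#' (`theta = a / (a + b + c)`) for a biallelic SNP observed in two
#' populations.  Only allele frequencies are available here, so the observed
#' heterozygosity is taken at its Hardy-Weinberg value `h_i = 2 p_i (1-p_i)`.
#' With `weighting = "size"` the components use the sample-size-weighted
#' means the estimator defines (`n_c`, weighted `p_bar`, `s^2`, `h_bar`);
#' `weighting = "equal"` gives both populations the same weight (both sample
#' sizes replaced by their mean), a variant some panel summaries print.
#'
#' @param p1,p2 Coded-allele frequencies.
#' @param n1,n2 Sample sizes in individuals (>= 2).
#' @param weighting `"size"` (default) or `"equal"`.
#' @return List with the variance components `a`, `b`, `c`, the intermediates
#'   `n_bar`, `n_c`, `p_bar`, `s2`, `h_bar`, and `theta` (untruncated; `NA`
#'   with `undefined = TRUE` when both populations are monomorphic at the
#'   same allele).
#' @export
weir_cockerham_fst <- function(p1, n1, p2, n2,
                               weighting = c("size", "equal")) {
  weighting <- match.arg(weighting)
  stopifnot(p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1, n1 >= 2, n2 >= 2)
  if (weighting == "equal") n1 <- n2 <- mean(c(n1, n2))
  r <- 2
  n <- c(n1, n2); p <- c(p1, p2)
  n_bar <- mean(n)
  n_c <- (r * n_bar - sum(n^2) / (r * n_bar)) / (r - 1)
  p_bar <- sum(n * p) / (r * n_bar)
  s2 <- sum(n * (p - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- sum(n * 2 * p * (1 - p)) / (r * n_bar)
  a <- (n_bar / n_c) *
    (s2 - (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4) / (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - (r - 1) / r * s2 -
       (2 * n_bar - 1) / (4 * n_bar) * h_bar)
  cc <- h_bar / 2
  denom <- a + b + cc
  undefined <- abs(denom) < .Machine$double.eps * 8
  list(a = a, b = b, c = cc, n_bar = n_bar, n_c = n_c, p_bar = p_bar,
       s2 = s2, h_bar = h_bar,
       theta = if (undefined) NA_real_ else a / denom,
       undefined = undefined)
}

#' Build a SNP x population coded-allele-frequency panel
#'
#' Merges the long-format summary rows of several traits into one frequency
#' matrix.  A SNP reported in more than one trait table contributes the mean
#' of its frequencies after asserting that, within each population, the
#' reported values differ by at most `tol` (they describe the same sample).
#' Each cell also records a default sample size: the per-trait maximum
#' analysed `n` of the first trait table reporting the SNP.
#'
#' @param tables Named list of summary-row data frames (one per trait, as
#'   from [load_summary_table()]).
#' @param sample_sizes Data frame `trait`, `population`, `n_max`.
#' @param tol Largest tolerated within-population frequency discrepancy
#'   between trait tables for the same SNP.
#' @return List with matrices `caf` and `n` (rows SNPs, columns populations;
#'   `NA` where not genotyped).
#' @export
build_caf_table <- function(tables, sample_sizes, tol = 0.011) {
  rows <- do.call(rbind, lapply(names(tables), function(tr) {
    d <- tables[[tr]][, c("snp", "population", "caf")]
    d$trait <- tr
    d
  }))
  snps <- unique(rows$snp)
  pops <- unique(rows$population)
  caf <- n <- matrix(NA_real_, length(snps), length(pops),
                     dimnames = list(snps, pops))
  for (s in snps) for (pp in pops) {
    d <- rows[rows$snp == s & rows$population == pp, , drop = FALSE]
    if (!nrow(d)) next
    if (diff(range(d$caf)) > tol)
      stop(sprintf("CAF discrepancy > %.3g for %s in %s across trait tables",
                   tol, s, pp))
    caf[s, pp] <- mean(d$caf)
    nm <- sample_sizes$n_max[sample_sizes$trait == d$trait[1] &
                               sample_sizes$population == pp]
    n[s, pp] <- if (length(nm)) nm[1] else NA_real_
  }
  list(caf = caf, n = n)
}

#' Pearson correlation of coded-allele frequencies between two populations
#'
#' @param caf_table Frequency matrix (`caf` element of [build_caf_table()]).
#' @param pop_a,pop_b Column names to compare.
#' @return List with `r` (Pearson correlation over pairwise-complete SNPs)
#'   and `n_snps` (number of SNPs used).
#' @export
caf_correlation <- function(caf_table, pop_a, pop_b) {
  x <- caf_table[, pop_a]; y <- caf_table[, pop_b]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) stop("fewer than 3 SNPs with data in both populations")
  list(r = stats::cor(x[ok], y[ok]), n_snps = sum(ok))
}

#' Count SNPs strongly differentiated from a reference population
#'
#' Applies [weir_cockerham_fst()] per SNP between each population and the
#' reference and counts estimates strictly above `threshold`.
#'
#' @param caf_table Output of [build_caf_table()] (needs both `caf` and `n`).
#' @param ref_pop Reference population column.
#' @param threshold F_ST cut-off (strict inequality).
#' @param weighting Passed to [weir_cockerham_fst()].
#' @return Data frame per non-reference population: `population`, `n_snps`
#'   (SNPs with data in both), `n_above`, and `fraction`.
#' @export
fst_panel_summary <- function(caf_table, ref_pop = "EA", threshold = 0.15,
                              weighting = "size") {
  caf <- caf_table$caf; nn <- caf_table$n
  pops <- setdiff(colnames(caf), ref_pop)
  out <- lapply(pops, function(pp) {
    ok <- which(!is.na(caf[, ref_pop]) & !is.na(caf[, pp]))
    th <- vapply(ok, function(s) {
      weir_cockerham_fst(caf[s, ref_pop], nn[s, ref_pop],
                         caf[s, pp], nn[s, pp], weighting = weighting)$theta
    }, numeric(1))
    data.frame(population = pp, n_snps = length(ok),
               n_above = sum(!is.na(th) & th > threshold),
               fraction = sum(!is.na(th) & th > threshold) / length(ok),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Two-locus linkage disequilibrium from haplotype counts
#'
#' @param counts Haplotype counts in the order AB, Ab, aB, ab (A/B the coded
#'   alleles at the two loci), total > 0.
#' @return List with allele frequencies `pA`, `pB`, the disequilibrium `D`,
#'   `r2 = D^2 / (pA qA pB qB)`, and `Dprime` (`D` over its sign-dependent
#'   bound).  `r2` and `Dprime` are `NA` with `undefined = TRUE` when either
#'   locus is monomorphic.
#' @export
ld_r2 <- function(counts) {
  stopifnot(length(counts) == 4, all(counts >= 0), sum(counts) > 0)
  f <- counts / sum(counts)
  pA <- f[1] + f[2]; pB <- f[1] + f[3]
  qA <- 1 - pA; qB <- 1 - pB
  D <- f[1] - pA * pB
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1)
    return(list(pA = pA, pB = pB, D = D, r2 = NA_real_, Dprime = NA_real_,
                undefined = TRUE))
  Dmax <- if (D >= 0) min(pA * qB, qA * pB) else min(pA * pB, qA * qB)
  list(pA = unname(pA), pB = unname(pB), D = unname(D),
       r2 = unname(D^2 / (pA * qA * pB * qB)),
       Dprime = unname(if (Dmax == 0) NA_real_ else abs(D) / Dmax),
       undefined = FALSE)
}
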