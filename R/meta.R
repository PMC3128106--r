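#' Fixed-effects inverse-variance-weighted meta-analysis
#'
#' Pools per-stratum effect estimates with weights `w_i = 1/se_i^2`:
#' `beta_meta = sum(w b) / sum(w)`, `se_meta = 1/sqrt(sum(w))`, with the
#' pooled p-value from the standard normal reference (two-sided).
#' Heterogeneity is summarised by Cochran's
#' `Q = sum(w (b - beta_meta)^2)` with a chi-square test on `k - 1` degrees
#' of freedom (undefined for a single stratum) and
#' `I2 = max(0, (Q - (k - 1)) / Q) * 100` per cent.
#'
#' @param results Data frame of stratum results with columns `beta` and `se`
#'   (e.g. rows from [fit_additive_model()]).  If columns `snp`, `trait`, or
#'   `coded_allele` are present they must be constant across rows -- mixed
#'   coded alleles are an error, never silently flipped.
#' @return One-row data frame: `beta_meta`, `se_meta`, `z`, `p`, `k`, `Q`,
#'   `p_het`, `I2`, plus any constant identifying columns.
#' @export
ivw_meta <- function(results) {
  stopifnot(is.data.frame(results), all(c("beta", "se") %in% names(results)))
  res <- results[!is.na(results$beta) & !is.na(results$se), , drop = FALSE]
  k <- nrow(res)
  if (k == 0) stop("no estimable strata to pool")
  if (any(res$se <= 0)) stop("all standard errors must be positive")
  for (col in c("snp", "trait", "coded_allele"))
    if (col %in% names(res) && length(unique(res[[col]])) > 1)
      stop("strata disagree on '", col, "'; refusing to pool")
  w <- 1 / res$se^2
  beta <- sum(w * res$beta) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- beta / se
  Q <- sum(w * (res$beta - beta)^2)
  p_het <- if (k > 1) stats::pchisq(Q, df = k - 1, lower.tail = FALSE)
           else NA_real_
  I2 <- if (k > 1 && Q > 0) max(0, (Q - (k - 1)) / Q) * 100 else 0
  out <- data.frame(beta_meta = beta, se_meta = se, z = z,
                    p = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
                    k = k, Q = Q, p_het = p_het, I2 = I2)
  for (col in c("snp", "trait", "population", "coded_allele"))
    if (col %in% names(res)) out[[col]] <- res[[col]][1]
  out
}
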