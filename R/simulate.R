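# Run expr with a temporary RNG state so simulation calls do not disturb the
# caller's random stream.
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministic sub-seed for a named random stream.  Each variable class in a
# scenario draws from its own stream so that, e.g., adding a covariate never
# perturbs the genotypes.  Plain polynomial string hash, kept below 2^31.
.stream_seed <- function(seed, ...) {
  label <- paste(c(...), collapse = "/")
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% 1000000007
  as.integer((as.numeric(seed) %% 1046527 + 1) * 2039 + h %% 1046527) %% 2147483647L
}

#' Define a single-population simulation scenario
#'
#' A scenario bundles everything needed to simulate one population stratum
#' (one study site within one racial/ethnic group): coded-allele frequencies,
#' per-trait means/SDs on the analysis scale, additive SNP effects, covariate
#' distributions, lipid-lowering-medication use, and fasting behaviour.
#'
#' Trait values are simulated on the scale the association analysis uses:
#' HDL-C and LDL-C in mg/dl, triglycerides on the natural-log scale
#' (`lnTG`, ln of mg/dl).  Default means/SDs are typical of adult
#' population-based lipid samples (HDL-C 52 (15) mg/dl, LDL-C 120 (35) mg/dl,
#' ln(TG) 4.7 (0.5)).
#'
#' @param population,study Labels carried into the participant table.
#' @param n Number of participants (>= 1).
#' @param snp_freqs Named numeric vector of coded-allele frequencies in
#'   `[0, 1]`, one entry per SNP.
#' @param snp_effects Data frame with columns `snp`, `trait`, `beta`: additive
#'   effect per coded-allele copy on the trait's analysis scale.  May be
#'   `NULL` (no genetic effects).
#' @param trait_means,trait_sds Named numeric vectors over
#'   `c("HDL", "LDL", "lnTG")`; SDs are marginal trait SDs and must be
#'   positive.
#' @param covariate_params List overriding any of: `female` (prevalence),
#'   `age_mean`, `age_sd`, `bmi_mean`, `bmi_sd`, `smoking`, `t2d`,
#'   `menopause`, `hormone_use` (among females), `prior_mi`.
#' @param covariate_effects Optional data frame `covariate`, `trait`, `beta`
#'   introducing covariate-on-trait effects (a confounding hook; covariates
#'   and genotypes are always generated independently).
#' @param medication_rate Probability of lipid-lowering-medication use.
#' @param medication_offset Named additive shift applied to the traits of
#'   treated participants (mg/dl for HDL/LDL, ln units for lnTG; negative
#'   values lower the trait).
#' @param fasting_nonfasting_rate Probability of a non-fasting (< 8 h) draw.
#' @param linked_pairs Optional list of lists with elements `causal`, `tag`
#'   (SNP ids present in `snp_freqs`) and `target_r2`: those two SNPs are
#'   simulated jointly in linkage disequilibrium.
#' @param missing_rate Genotype missingness rate, applied uniformly at random.
#' @return An object of class `cohort_scenario`.
#' @seealso [simulate_cohort()]
#' @export
cohort_scenario <- function(population = "EA", study = "S1", n = 1000,
                            snp_freqs = c(rs1 = 0.3),
                            snp_effects = NULL,
                            trait_means = c(HDL = 52, LDL = 120, lnTG = 4.7),
                            trait_sds = c(HDL = 15, LDL = 35, lnTG = 0.5),
                            covariate_params = list(),
                            covariate_effects = NULL,
                            medication_rate = 0.05,
                            medication_offset = c(HDL = 0, LDL = -35,
                                                  lnTG = -0.2),
                            fasting_nonfasting_rate = 0.1,
                            linked_pairs = NULL,
                            missing_rate = 0) {
  stopifnot(n >= 1, length(snp_freqs) >= 1, !is.null(names(snp_freqs)))
  if (any(snp_freqs < 0 | snp_freqs > 1))
    stop("snp_freqs must lie in [0, 1]")
  if (any(trait_sds <= 0)) stop("trait_sds must be positive")
  for (p in c(medication_rate, fasting_nonfasting_rate, missing_rate))
    if (p < 0 || p > 1) stop("rates must lie in [0, 1]")
  cov_defaults <- list(female = 0.55, age_mean = 50, age_sd = 12,
                       bmi_mean = 28, bmi_sd = 5, smoking = 0.25,
                       t2d = 0.10, menopause = 0.50, hormone_use = 0.20,
                       prior_mi = 0.05)
  unknown <- setdiff(names(covariate_params), names(cov_defaults))
  if (length(unknown))
    stop("unknown covariate_params: ", paste(unknown, collapse = ", "))
  cov_defaults[names(covariate_params)] <- covariate_params
  if (!is.null(snp_effects)) {
    stopifnot(all(c("snp", "trait", "beta") %in% names(snp_effects)))
    if (!all(snp_effects$snp %in% names(snp_freqs)))
      stop("snp_effects refers to SNPs absent from snp_freqs")
  }
  structure(list(population = population, study = study, n = as.integer(n),
                 snp_freqs = snp_freqs, snp_effects = snp_effects,
                 trait_means = trait_means, trait_sds = trait_sds,
                 covariate_params = cov_defaults,
                 covariate_effects = covariate_effects,
                 medication_rate = medication_rate,
                 medication_offset = medication_offset,
                 fasting_nonfasting_rate = fasting_nonfasting_rate,
                 linked_pairs = linked_pairs,
                 missing_rate = missing_rate),
            class = "cohort_scenario")
}

#' Simulate Hardy-Weinberg genotypes
#'
#' Draws `n` independent genotypes (coded-allele counts 0/1/2) at
#' Hardy-Weinberg proportions `P(2) = f^2`, `P(1) = 2f(1-f)`,
#' `P(0) = (1-f)^2` for coded-allele frequency `f`.
#'
#' @param freq Coded-allele frequency in `[0, 1]`.
#' @param n Number of genotypes.
#' @param seed Integer seed; the draw is deterministic given `seed`.
#' @return Integer vector of length `n` with values in `{0, 1, 2}`.
#' @export
simulate_genotypes <- function(freq, n, seed = 1) {
  if (!is.finite(freq) || freq < 0 || freq > 1)
    stop("freq must lie in [0, 1]")
  stopifnot(n >= 1)
  .with_seed(seed, stats::rbinom(n, size = 2L, prob = freq))
}

# Two-locus haplotype frequencies for coded frequencies pA, pB and
# disequilibrium D (order: AB, Ab, aB, ab).
.hap_freqs <- function(pA, pB, D) {
  c(pA * pB + D, pA * (1 - pB) - D, (1 - pA) * pB - D,
    (1 - pA) * (1 - pB) + D)
}

#' Simulate a causal/tag SNP pair in linkage disequilibrium
#'
#' Draws `2n` haplotypes from the two-locus table with frequencies
#' `{pA pB + D, pA qB - D, qA pB - D, qA qB + D}` and pairs them into diploid
#' genotypes.  `D` is chosen as `sign * sqrt(r2 * pA qA pB qB)` and clipped to
#' the feasible range `max(-pA pB, -qA qB) <= D <= min(pA qB, qA pB)`; if the
#' requested `target_r2` is infeasible a warning is issued and the realized
#' (clipped) value is reported.
#'
#' @param p_causal,p_tag Coded-allele frequencies in `(0, 1)`.
#' @param target_r2 Desired squared correlation between the two loci.
#' @param n Number of diploid individuals.
#' @param seed Integer seed.
#' @param sign Sign of `D` (+1 couples the two coded alleles).
#' @return List with genotype vectors `causal` and `tag`, the four haplotype
#'   `counts` (AB, Ab, aB, ab), the `D` used, and `realized_r2` (population
#'   value implied by the clipped `D`).
#' @export
simulate_linked_pair <- function(p_causal, p_tag, target_r2, n, seed = 1,
                                 sign = 1) {
  stopifnot(p_causal > 0, p_causal < 1, p_tag > 0, p_tag < 1,
            target_r2 >= 0, target_r2 <= 1, n >= 1)
  pA <- p_causal; pB <- p_tag
  qA <- 1 - pA; qB <- 1 - pB
  D <- base::sign(sign) * sqrt(target_r2 * pA * qA * pB * qB)
  lo <- max(-pA * pB, -qA * qB)
  hi <- min(pA * qB, qA * pB)
  D_clip <- min(max(D, lo), hi)
  realized <- D_clip^2 / (pA * qA * pB * qB)
  if (abs(D_clip - D) > 1e-12)
    warning(sprintf("target r2 = %.4g infeasible for (%.3g, %.3g); realized r2 = %.4g",
                    target_r2, pA, pB, realized))
  f <- .hap_freqs(pA, pB, D_clip)
  idx <- .with_seed(seed,
                    sample.int(4L, 2L * n, replace = TRUE, prob = f))
  aA <- as.integer(idx <= 2L)            # haplotype carries coded allele at A
  aB2 <- as.integer(idx == 1L | idx == 3L)
  odd <- seq(1L, 2L * n, by = 2L)
  list(causal = aA[odd] + aA[odd + 1L],
       tag = aB2[odd] + aB2[odd + 1L],
       counts = tabulate(idx, nbins = 4L),
       D = D_clip, realized_r2 = realized)
}

# Systematic covariate contribution to a trait under the confounding hook.
.covariate_part <- function(trait, covars, effects) {
  part <- numeric(nrow(covars))
  if (is.null(effects)) return(part)
  eff <- effects[effects$trait == trait, , drop = FALSE]
  for (i in seq_len(nrow(eff))) {
    x <- covars[[eff$covariate[i]]]
    x <- ifelse(is.na(x), 0, as.numeric(x))
    part <- part + eff$beta[i] * x
  }
  part
}

#' Simulate an individual-level participant table
#'
#' Generates genotypes, covariates, medication use, fasting status, and lipid
#' traits for one scenario.  Traits follow the additive model: each trait is
#' its scenario mean plus the summed SNP effects (per coded-allele copy), plus
#' any covariate effects, plus Gaussian noise whose variance is chosen so the
#' marginal trait SD equals the scenario SD.  Triglycerides are simulated on
#' the natural-log scale and exponentiated; treated participants have the
#' per-trait medication offset added; total cholesterol is constructed as
#' `LDL + HDL + TG/5` so that the Friedewald relation recovers the intended
#' LDL-C.
#'
#' All randomness derives from `seed` through named streams (one per
#' scenario and variable class), so the same seed and scenario always yield a
#' byte-identical table.
#'
#' @param scenario A [cohort_scenario()].
#' @param seed Integer seed.
#' @return Data frame with one row per participant: identifiers, covariates,
#'   `fasting_hours`, `on_lipid_med`, traits `tc`, `hdl`, `tg` (mg/dl), and
#'   one genotype column per SNP (coded-allele count, `NA` if missing).
#' @export
simulate_cohort <- function(scenario, seed = 1) {
  stopifnot(inherits(scenario, "cohort_scenario"))
  sc <- scenario
  n <- sc$n
  lab <- paste(sc$population, sc$study, sep = ":")

  ## genotypes: independent SNPs, then LD pairs drawn jointly
  snps <- names(sc$snp_freqs)
  geno <- matrix(NA_integer_, n, length(snps), dimnames = list(NULL, snps))
  paired <- character(0)
  for (lp in sc$linked_pairs) {
    pair <- simulate_linked_pair(sc$snp_freqs[[lp$causal]],
                                 sc$snp_freqs[[lp$tag]],
                                 lp$target_r2, n,
                                 seed = .stream_seed(seed, lab, "geno",
                                                     lp$causal, lp$tag))
    geno[, lp$causal] <- pair$causal
    geno[, lp$tag] <- pair$tag
    paired <- c(paired, lp$causal, lp$tag)
  }
  for (s in setdiff(snps, paired))
    geno[, s] <- simulate_genotypes(sc$snp_freqs[[s]], n,
                                    seed = .stream_seed(seed, lab, "geno", s))

  ## covariates (independent of genotypes by construction)
  cp <- sc$covariate_params
  covars <- .with_seed(.stream_seed(seed, lab, "covariates"), {
    female <- stats::rbinom(n, 1, cp$female) == 1
    data.frame(
      sex = factor(ifelse(female, "F", "M"), levels = c("F", "M")),
      age = stats::rnorm(n, cp$age_mean, cp$age_sd),
      bmi = pmax(stats::rnorm(n, cp$bmi_mean, cp$bmi_sd), 14),
      smoking = stats::rbinom(n, 1, cp$smoking) == 1,
      t2d = stats::rbinom(n, 1, cp$t2d) == 1,
      menopause = ifelse(female, stats::rbinom(n, 1, cp$menopause) == 1, NA),
      hormone_use = ifelse(female, stats::rbinom(n, 1, cp$hormone_use) == 1, NA),
      prior_mi = stats::rbinom(n, 1, cp$prior_mi) == 1)
  })
  fasting_hours <- .with_seed(.stream_seed(seed, lab, "fasting"), {
    nonfast <- stats::rbinom(n, 1, sc$fasting_nonfasting_rate) == 1
    ifelse(nonfast, stats::runif(n, 0, 8), stats::runif(n, 8, 16))
  })
  on_med <- .with_seed(.stream_seed(seed, lab, "medication"),
                       stats::rbinom(n, 1, sc$medication_rate) == 1)

  ## traits on the analysis scale
  traits <- list()
  for (tr in names(sc$trait_means)) {
    eff <- sc$snp_effects
    genetic <- numeric(n); var_g <- 0
    if (!is.null(eff)) {
      eff <- eff[eff$trait == tr, , drop = FALSE]
      for (i in seq_len(nrow(eff))) {
        p <- sc$snp_freqs[[eff$snp[i]]]
        genetic <- genetic + eff$beta[i] * geno[, eff$snp[i]]
        var_g <- var_g + 2 * p * (1 - p) * eff$beta[i]^2
      }
    }
    cov_part <- .covariate_part(tr, covars, sc$covariate_effects)
    var_c <- if (all(cov_part == 0)) 0 else stats::var(cov_part)
    sd_y <- sc$trait_sds[[tr]]
    if (var_g + var_c >= sd_y^2)
      stop(sprintf("systematic variance (%.3g) >= trait variance (%.3g) for %s",
                   var_g + var_c, sd_y^2, tr))
    sigma_e <- sqrt(sd_y^2 - var_g - var_c)
    noise <- .with_seed(.stream_seed(seed, lab, "noise", tr),
                        stats::rnorm(n, 0, sigma_e))
    y <- sc$trait_means[[tr]] + genetic + cov_part + noise
    off <- sc$medication_offset[[tr]]
    if (!is.null(off) && !is.na(off)) y <- y + ifelse(on_med, off, 0)
    traits[[tr]] <- y
  }
  hdl <- pmax(traits$HDL, 1)
  ldl <- pmax(traits$LDL, 1)
  tg <- exp(traits$lnTG)
  tc <- ldl + hdl + tg / 5

  ## genotype missingness
  if (sc$missing_rate > 0) {
    drop <- .with_seed(.stream_seed(seed, lab, "missing"),
                       stats::runif(length(geno)) < sc$missing_rate)
    geno[drop] <- NA_integer_
  }

  out <- data.frame(
    id = sprintf("%s-%s-%06d", sc$population, sc$study, seq_len(n)),
    population = sc$population, study = sc$study,
    covars, fasting_hours = fasting_hours, on_lipid_med = on_med,
    tc = tc, hdl = hdl, tg = tg,
    stringsAsFactors = FALSE, check.names = FALSE)
  cbind(out, as.data.frame(geno))
}
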