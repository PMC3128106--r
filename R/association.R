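#' Coded-allele frequency from genotypes
#'
#' @param genotypes Coded-allele counts in `{0, 1, 2}`, `NA` allowed.
#' @return Frequency `sum(g) / (2 * n_nonmissing)`.
#' @export
compute_caf <- function(genotypes) {
  g <- genotypes[!is.na(genotypes)]
  if (!length(g)) stop("all genotypes missing")
  if (!all(g %in% 0:2)) stop("genotypes must be coded-allele counts 0/1/2")
  sum(g) / (2 * length(g))
}

# Covariate sets for the four standard adjustment models.  Models 3 and 4
# carry female-only covariates (menopause, hormone use) and are therefore
# fitted within sex strata.
.model_covariates <- function(model) {
  switch(as.character(model),
         "1" = character(0),
         "2" = c("age", "sex"),
         "3" = c("age", "bmi", "smoking", "t2d", "menopause", "hormone_use"),
         "4" = c("age", "bmi", "smoking", "t2d", "menopause", "hormone_use",
                 "prior_mi"),
         stop("model must be 1, 2, 3, or 4"))
}

# One OLS fit of trait on genotype dose plus covariates; the workhorse
# behind fit_additive_model.
.fit_one <- function(dat, snp, trait_kind, model, covs, stratum) {
  n <- nrow(dat)
  res <- data.frame(snp = snp, trait = trait_kind,
                    population = dat$population[1] %||% NA_character_,
                    study = dat$study[1] %||% NA_character_,
                    stratum = stratum, model = model,
                    n = n, caf = NA_real_, beta = NA_real_, se = NA_real_,
                    p = NA_real_, df = NA_real_, note = NA_character_,
                    stringsAsFactors = FALSE)
  if (n < length(covs) + 3) {
    res$note <- "too_few_complete_cases"
    return(res)
  }
  res$caf <- compute_caf(dat$g)
  if (length(unique(dat$g)) < 2) {
    res$note <- "monomorphic"
    return(res)
  }
  rhs <- paste(c("g", covs), collapse = " + ")
  fit <- stats::lm(stats::as.formula(paste("y ~", rhs)), data = dat)
  aliased <- is.na(stats::coef(fit))
  if (any(aliased)) {
    bad <- setdiff(names(which(aliased)), "g")
    if ("g" %in% names(which(aliased)) || length(bad))
      stop("rank-deficient design; collinear column(s): ",
           paste(names(which(aliased)), collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  res$beta <- sm["g", "Estimate"]
  res$se <- sm["g", "Std. Error"]
  res$df <- fit$df.residual
  res$p <- 2 * stats::pt(abs(res$beta / res$se), df = fit$df.residual,
                         lower.tail = FALSE)
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-stratum additive-model association test
#'
#' Ordinary least squares of a lipid trait on coded-allele count (0/1/2),
#' under one of four adjustment models: (1) unadjusted; (2) age and sex;
#' (3) age, BMI, current smoking, type-2 diabetes, post-menopausal status and
#' hormone use; (4) model 3 plus previous myocardial infarction.  Because
#' menopause and hormone use are defined for females only, models 3 and 4 are
#' fitted separately within each sex stratum and one result row is returned
#' per stratum.  Complete cases only; the p-value uses the t reference with
#' the residual degrees of freedom, two-sided.
#'
#' @param participants Filtered participant table (see [apply_exclusions()]).
#' @param snp Name of the genotype column to test.
#' @param trait_kind `"HDL"`, `"LDL"`, or `"lnTG"`.
#' @param model Adjustment model, 1-4.
#' @param site_covariate If `TRUE` and a `site` column is present, site of
#'   ascertainment enters as a categorical fixed effect.
#' @return Data frame with one row per stratum: `snp`, `trait`, `population`,
#'   `study`, `stratum`, `model`, `n`, `caf`, `beta`, `se`, `p`, `df`, and a
#'   `note` flagging inestimable fits (monomorphic SNP, too few cases).
#' @export
fit_additive_model <- function(participants, snp,
                               trait_kind = c("HDL", "LDL", "lnTG"),
                               model = 2, site_covariate = FALSE) {
  trait_kind <- match.arg(trait_kind)
  if (!(snp %in% names(participants)))
    stop("no genotype column named ", snp)
  covs <- .model_covariates(model)
  if (site_covariate) {
    if (!("site" %in% names(participants)))
      stop("site_covariate = TRUE but no 'site' column")
    covs <- c(covs, "site")
  }
  dat <- participants
  dat$y <- trait_values(participants, trait_kind)
  dat$g <- as.numeric(participants[[snp]])
  sex_stratified <- model %in% c(3, 4)
  if (!sex_stratified) {
    keep <- stats::complete.cases(dat[, c("y", "g", covs), drop = FALSE])
    dat <- dat[keep, , drop = FALSE]
    # single-sex stratum: drop sex from the design rather than fail on a
    # constant column
    if ("sex" %in% covs && length(unique(dat$sex)) < 2)
      covs <- setdiff(covs, "sex")
    return(.fit_one(dat, snp, trait_kind, model, covs, stratum = "all"))
  }
  # female-only covariates are NA for males, so complete-case filtering is
  # applied within each sex stratum with the stratum's own covariate set
  out <- lapply(split(dat, dat$sex, drop = TRUE), function(d) {
    stratum <- as.character(d$sex[1])
    cv <- covs
    if (stratum == "M") cv <- setdiff(cv, c("menopause", "hormone_use"))
    d <- d[stats::complete.cases(d[, c("y", "g", cv), drop = FALSE]), ,
           drop = FALSE]
    .fit_one(d, snp, trait_kind, model, cv, stratum = stratum)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
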