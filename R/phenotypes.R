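#' Friedewald LDL cholesterol
#'
#' `LDL-C = TC - HDL-C - TG/5` (all mg/dl).  The relation is unreliable at
#' high triglyceride levels, so values are set missing when TG exceeds
#' 400 mg/dl; missing inputs propagate.
#'
#' @param tc,hdl,tg Total cholesterol, HDL-C, and triglycerides in mg/dl
#'   (positive; `NA` allowed).
#' @return Numeric vector of LDL-C in mg/dl, `NA` where TG > 400 or any
#'   input is missing.
#' @export
friedewald_ldl <- function(tc, hdl, tg) {
  for (x in list(tc, hdl, tg))
    if (any(!is.na(x) & x <= 0)) stop("lipid inputs must be positive")
  ldl <- tc - hdl - tg / 5
  ldl[is.na(tc) | is.na(hdl) | is.na(tg) | tg > 400] <- NA_real_
  ldl
}

#' Natural-log transform for triglycerides
#'
#' Triglycerides are analysed on the natural-log scale; HDL-C and LDL-C are
#' analysed untransformed.
#'
#' @param values Trait values (mg/dl; for `lnTG`, the raw TG values).
#' @param trait_kind One of `"HDL"`, `"LDL"`, `"lnTG"`.
#' @return Transformed values (identity except `lnTG`, which returns
#'   `log(values)`).
#' @export
transform_trait <- function(values, trait_kind = c("HDL", "LDL", "lnTG")) {
  trait_kind <- match.arg(trait_kind)
  if (trait_kind != "lnTG") return(values)
  if (any(!is.na(values) & values <= 0))
    stop("TG must be positive to take logs")
  log(values)
}

#' Apply the analysis inclusion/exclusion rules
#'
#' Removes participants younger than 18 years, non-fasting participants
#' (fasting time < 8 hours), and -- for the `lnTG` analysis only --
#' participants with TG > 1,000 mg/dl.  Optionally removes participants on
#' lipid-lowering medication (the primary analysis keeps them).  Boundary
#' values (age 18, 8 fasting hours, TG exactly 1,000) are retained.  Each
#' excluded participant is charged to the first rule that removes them, in
#' the fixed order age, fasting, TG, medication, so the per-reason counts sum
#' to the number excluded.
#'
#' @param participants Participant table with columns `age`, `fasting_hours`,
#'   `tg`, `on_lipid_med` (see [simulate_cohort()]).
#' @param trait_kind Trait being analysed (TG rule applies to `"lnTG"` only).
#' @param include_medicated Keep participants on lipid-lowering medication?
#' @return List with `data` (the retained rows) and `exclusions` (data frame
#'   of `id`, `reason` for the removed rows).
#' @export
apply_exclusions <- function(participants,
                             trait_kind = c("HDL", "LDL", "lnTG"),
                             include_medicated = TRUE) {
  trait_kind <- match.arg(trait_kind)
  need <- c("age", "fasting_hours", "tg", "on_lipid_med")
  miss <- setdiff(need, names(participants))
  if (length(miss))
    stop("participant table lacks column(s): ", paste(miss, collapse = ", "))
  reason <- rep(NA_character_, nrow(participants))
  mark <- function(cond, why) {
    hit <- is.na(reason) & !is.na(cond) & cond
    reason[hit] <<- why
  }
  mark(participants$age < 18, "age_lt_18")
  mark(participants$fasting_hours < 8, "nonfasting")
  if (trait_kind == "lnTG") mark(participants$tg > 1000, "tg_gt_1000")
  if (!include_medicated) mark(participants$on_lipid_med, "lipid_medication")
  keep <- is.na(reason)
  ids <- if ("id" %in% names(participants)) participants$id
         else as.character(seq_len(nrow(participants)))
  list(data = participants[keep, , drop = FALSE],
       exclusions = data.frame(id = ids[!keep], reason = reason[!keep],
                               stringsAsFactors = FALSE))
}

#' Remove an average medication effect from treated participants
#'
#' When participants on lipid-lowering medication are analysed rather than
#' excluded, their observed trait values can be shifted back to the
#' pre-treatment scale using an average per-trait treatment effect.  For a
#' treated participant the adjusted value is `value - offset`; since
#' lowering offsets are negative this restores the higher untreated level.
#'
#' @param values Observed trait values on the analysis scale.
#' @param on_med Logical vector, medication use per participant.
#' @param trait_kind Trait being adjusted.
#' @param offsets Named numeric vector of average treatment effects per trait
#'   (same convention as `medication_offset` in [cohort_scenario()]).
#' @return Adjusted values; untreated participants are unchanged.
#' @export
adjust_for_medication <- function(values, on_med,
                                  trait_kind = c("HDL", "LDL", "lnTG"),
                                  offsets) {
  trait_kind <- match.arg(trait_kind)
  if (!(trait_kind %in% names(offsets)) || is.na(offsets[[trait_kind]]))
    stop("no medication offset supplied for trait ", trait_kind)
  stopifnot(length(on_med) == length(values))
  ifelse(!is.na(on_med) & on_med, values - offsets[[trait_kind]], values)
}

# Dependent variable for an association fit, on the analysis scale.
trait_values <- function(participants, trait_kind = c("HDL", "LDL", "lnTG")) {
  trait_kind <- match.arg(trait_kind)
  switch(trait_kind,
         HDL = participants$hdl,
         LDL = friedewald_ldl(participants$tc, participants$hdl,
                              participants$tg),
         lnTG = transform_trait(participants$tg, "lnTG"))
}
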