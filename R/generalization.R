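#' Replication call for the reference (European-American) population
#'
#' An association replicates when its pooled p-value is strictly below
#' `alpha`; ties at the threshold do not replicate.
#'
#' @param p Pooled p-value in the reference population.
#' @param alpha Significance level (0.05 in the standard analysis,
#'   uncorrected for multiple testing).
#' @return Logical.
#' @export
classify_replication <- function(p, alpha = 0.05) {
  stopifnot(length(p) >= 1)
  !is.na(p) & p < alpha
}

#' Generalization call for one SNP-trait association
#'
#' An association generalizes when it replicates in the reference population
#' (European Americans) and, in *every* non-reference population with a
#' result ("if genotyped"), is significant at `alpha` with the same effect
#' direction as the reference.  A zero effect fails the direction match; an
#' association with no non-reference result at all does not generalize.
#' Populations with `alpha <= p < 2 * alpha` are flagged as near misses
#' ("trending toward significance") but never counted as generalized.
#'
#' @param meta_by_pop Data frame of population-level results with columns
#'   `population`, `beta`, `p` (one row per population).
#' @param alpha Significance level.
#' @param ea Label of the reference population.
#' @param nonea_pops Non-reference populations considered.
#' @return List with `ea_replicated`, `generalized`, and `evidence` (a data
#'   frame with one row per non-reference population: `available`,
#'   `significant`, `direction_match`, `near_miss`).
#' @export
classify_generalization <- function(meta_by_pop, alpha = 0.05, ea = "EA",
                                    nonea_pops = c("AA", "AI", "MAH")) {
  stopifnot(all(c("population", "beta", "p") %in% names(meta_by_pop)))
  ea_row <- meta_by_pop[meta_by_pop$population == ea, , drop = FALSE]
  if (nrow(ea_row) != 1)
    stop("expected exactly one reference-population (", ea, ") result")
  ea_rep <- classify_replication(ea_row$p, alpha)
  ev <- data.frame(population = nonea_pops, available = FALSE,
                   significant = FALSE, direction_match = FALSE,
                   near_miss = FALSE, stringsAsFactors = FALSE)
  for (i in seq_along(nonea_pops)) {
    row <- meta_by_pop[meta_by_pop$population == nonea_pops[i], , drop = FALSE]
    if (nrow(row) == 0 || is.na(row$p[1])) next
    ev$available[i] <- TRUE
    ev$significant[i] <- row$p[1] < alpha
    ev$near_miss[i] <- row$p[1] >= alpha && row$p[1] < 2 * alpha
    ev$direction_match[i] <- !is.na(row$beta[1]) &&
      sign(row$beta[1]) != 0 && sign(row$beta[1]) == sign(ea_row$beta)
  }
  generalized <- isTRUE(ea_rep) && any(ev$available) &&
    all(!ev$available | (ev$significant & ev$direction_match))
  list(ea_replicated = isTRUE(ea_rep), generalized = generalized,
       evidence = ev)
}

#' Count significant associations in one population
#'
#' @param p P-values for one trait in one population (`NA` = not tested).
#' @param alpha Significance level; the comparison is strict (`p < alpha`).
#' @return List with `count`, `total` (non-missing tests), and `fraction`.
#' @export
count_significant <- function(p, alpha = 0.05) {
  p <- p[!is.na(p)]
  if (!length(p)) stop("no tested associations supplied")
  list(count = sum(p < alpha), total = length(p),
       fraction = sum(p < alpha) / length(p))
}

#' Generalization calls for every SNP in a summary table
#'
#' Applies [classify_generalization()] to each SNP of a long-format summary
#' table (one trait; one row per SNP x population).
#'
#' @param rows Summary rows with columns `snp`, `population`, `beta`, `p`
#'   (see [load_summary_table()]).
#' @param alpha Significance level.
#' @param ea,nonea_pops Population labels as in [classify_generalization()].
#' @return Data frame with one row per SNP: `snp`, `trait` (if present),
#'   `ea_replicated`, `generalized`, and `g_label` (`"Y"`/`"N"`).
#' @export
generalization_calls <- function(rows, alpha = 0.05, ea = "EA",
                                 nonea_pops = c("AA", "AI", "MAH")) {
  out <- lapply(split(rows, rows$snp), function(d) {
    call <- classify_generalization(d, alpha = alpha, ea = ea,
                                    nonea_pops = nonea_pops)
    data.frame(snp = d$snp[1],
               trait = if ("trait" %in% names(d)) d$trait[1] else NA_character_,
               ea_replicated = call$ea_replicated,
               generalized = call$generalized,
               g_label = if (call$generalized) "Y" else "N",
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res[match(unique(rows$snp), res$snp), , drop = FALSE]
}

#' Summarise generalization calls across traits
#'
#' @param calls Data frame of calls from [generalization_calls()], stacked
#'   across traits (one row per SNP-trait pair, single `alpha`).
#' @return List with `per_trait` (generalized count by trait),
#'   `n_associations` (generalized SNP-trait pairs), and `n_unique_snps`
#'   (distinct SNPs among them; the two tallies differ when a SNP
#'   generalizes for more than one trait).
#' @export
summarize_generalization <- function(calls) {
  if (anyDuplicated(calls[, c("snp", "trait")]))
    stop("duplicate snp-trait entries")
  gen <- calls[calls$generalized, , drop = FALSE]
  per_trait <- vapply(split(calls$generalized, calls$trait), sum, integer(1))
  list(per_trait = per_trait,
       n_associations = nrow(gen),
       n_unique_snps = length(unique(gen$snp)),
       snps_by_trait = split(gen$snp, gen$trait))
}
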