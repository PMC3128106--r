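.known_pops <- c("EA", "AA", "AI", "MAH")

#' Load a long-format summary-statistic table
#'
#' Reads a TSV of per-population SNP association summaries (one row per SNP x
#' population) with columns `snp`, `coded_allele`, `population`, `caf`,
#' `beta`, `se`, `p`, and optionally `gene` and `generalized`.  Missing
#' values may be written `NA` or the en dash used in print tables.  P-values
#' are kept as printed text (`p_text`) and parsed on demand, including
#' scientific notation; a value that underflows double precision is replaced
#' by the smallest representable positive number and flagged in `p_underflow`.
#'
#' @param path TSV file (UTF-8, header row).
#' @param trait Optional trait label stored in a `trait` column.
#' @return Validated data frame of summary rows.
#' @export
load_summary_table <- function(path, trait = NULL) {
  # read everything as text so printed precision (and p-value underflow)
  # survives until we parse deliberately
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character",
                         na.strings = c("NA", "–", "-", ""))
  if (!nrow(d)) stop("empty summary table: ", path)
  need <- c("snp", "coded_allele", "population", "caf", "beta", "se", "p")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("summary table lacks column(s): ", paste(miss, collapse = ", "))
  bad <- which(!(d$population %in% .known_pops))
  if (length(bad))
    stop("unknown population label '", d$population[bad[1]], "' at row ",
         bad[1])
  dup <- duplicated(d[, c("snp", "population")])
  if (any(dup))
    stop("duplicate (snp, population) entry at row ", which(dup)[1])
  d$p_text <- as.character(d$p)
  p_num <- suppressWarnings(as.numeric(d$p_text))
  bad <- which(!is.na(d$p_text) & is.na(p_num))
  if (length(bad))
    stop("malformed p-value '", d$p_text[bad[1]], "' at row ", bad[1])
  d$p_underflow <- !is.na(p_num) & p_num == 0 &
    !grepl("^0*\\.?0*$", d$p_text)
  p_num[d$p_underflow] <- .Machine$double.xmin
  d$p <- p_num
  for (col in c("caf", "beta", "se")) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(!is.na(d[[col]]) & is.na(v))
    if (length(bad))
      stop("malformed numeric in '", col, "' at row ", bad[1])
    d[[col]] <- v
  }
  if (any(!is.na(d$caf) & (d$caf < 0 | d$caf > 1)))
    stop("coded-allele frequencies must lie in [0, 1]")
  if (!is.null(trait)) d$trait <- trait
  d
}

#' Bundled multi-population lipid summary tables
#'
#' Published meta-analysis summary statistics (coded-allele frequency, beta,
#' SE, p, and the printed generalization label) for 49 GWAS-identified lipid
#' SNPs tested for HDL-C (27 SNPs), LDL-C (19), and ln(TG) (14) in European
#' American (EA), African American (AA), American Indian (AI), and Mexican
#' American/Hispanic (MAH) samples, together with the per-trait maximum
#' analysed sample sizes and the published observed-versus-expected
#' significance accounting.
#'
#' @return List with data frames `HDL`, `LDL`, `lnTG` (summary rows),
#'   `sample_sizes`, and `expected_observed`.
#' @export
lipid_summary_tables <- function() {
  ext <- function(f) system.file("extdata", f, package = "lipidgen",
                                 mustWork = TRUE)
  list(HDL = load_summary_table(ext("hdl_summary.tsv"), trait = "HDL"),
       LDL = load_summary_table(ext("ldl_summary.tsv"), trait = "LDL"),
       lnTG = load_summary_table(ext("tg_summary.tsv"), trait = "lnTG"),
       sample_sizes = utils::read.delim(ext("sample_sizes.tsv"),
                                        stringsAsFactors = FALSE),
       expected_observed = utils::read.delim(ext("expected_observed.tsv"),
                                             stringsAsFactors = FALSE))
}

#' Write summary rows to TSV
#'
#' Round-trip companion of [load_summary_table()]: `NA` is written as "NA",
#' and the printed p-value text is preserved when present.
#'
#' @param rows Summary rows.
#' @param path Output path.
#' @export
write_summary_table <- function(rows, path) {
  out <- rows
  if ("p_text" %in% names(out)) {
    out$p <- out$p_text
    out$p_text <- NULL
    out$p_underflow <- NULL
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
}

#' Recompute the headline results from the bundled summary tables
#'
#' Deterministically re-derives, from the shipped summary statistics alone:
#' the European-American replication count; per-population significant-test
#' counts per trait; generalization calls for every SNP-trait pair and their
#' diff against the printed Y/N labels (expected empty); per-trait and
#' overall generalized counts; coded-allele-frequency correlations and the
#' Weir-Cockerham F_ST panel against European Americans; and the
#' one-sample binomial p-values of the observed-versus-expected table,
#' recomputed from its printed counts.
#'
#' @param alpha Significance level for replication/generalization calls.
#' @return List of class `lipidgen_report`; see Details.
#' @export
reproduce_published <- function(alpha = 0.05) {
  fx <- lipid_summary_tables()
  traits <- c("HDL", "LDL", "lnTG")

  replication <- lapply(traits, function(tr) {
    ea <- fx[[tr]][fx[[tr]]$population == "EA", ]
    cs <- count_significant(ea$p, alpha)
    data.frame(trait = tr, replicated = cs$count, tested = cs$total)
  })
  replication <- do.call(rbind, replication)

  sig_counts <- do.call(rbind, lapply(traits, function(tr) {
    do.call(rbind, lapply(c("AA", "AI", "MAH"), function(pp) {
      rows <- fx[[tr]][fx[[tr]]$population == pp, ]
      cs <- count_significant(rows$p, alpha)
      data.frame(trait = tr, population = pp, significant = cs$count,
                 tested = cs$total, fraction = cs$fraction)
    }))
  }))

  calls <- do.call(rbind, lapply(traits, function(tr)
    generalization_calls(fx[[tr]], alpha = alpha)))
  printed <- do.call(rbind, lapply(traits, function(tr) {
    d <- fx[[tr]]
    d <- d[!duplicated(d$snp), c("snp", "generalized")]
    data.frame(trait = tr, snp = d$snp, printed_g = d$generalized)
  }))
  merged <- merge(calls, printed, by = c("snp", "trait"))
  g_diff <- merged[merged$g_label != merged$printed_g, , drop = FALSE]
  gen_summary <- summarize_generalization(calls)

  caf_panel <- build_caf_table(fx[traits], fx$sample_sizes)
  caf_cor <- do.call(rbind, lapply(c("AA", "AI", "MAH"), function(pp) {
    cc <- caf_correlation(caf_panel$caf, "EA", pp)
    data.frame(population = pp, r = cc$r, n_snps = cc$n_snps)
  }))
  fst <- fst_panel_summary(caf_panel, ref_pop = "EA", threshold = 0.15)

  eo <- fx$expected_observed
  eo$p_recomputed <- mapply(function(k, m, E)
    binomial_test_observed(k, m, E, sided = "two"),
    eo$n_observed, eo$n_tests, eo$n_expected)

  structure(list(alpha = alpha, replication = replication,
                 sig_counts = sig_counts, calls = calls, g_diff = g_diff,
                 gen_summary = gen_summary, caf_cor = caf_cor, fst = fst,
                 expected_observed = eo, caf_panel = caf_panel),
            class = "lipidgen_report")
}

#' @export
print.lipidgen_report <- function(x, ...) {
  cat("Replication in European Americans (p <", x$alpha, "):\n")
  cat(sprintf("  %s: %d/%d\n", x$replication$trait, x$replication$replicated,
              x$replication$tested), sep = "")
  cat(sprintf("  total: %d/%d\n", sum(x$replication$replicated),
              sum(x$replication$tested)))
  cat("Generalized SNPs per trait:",
      paste(names(x$gen_summary$per_trait), x$gen_summary$per_trait,
            sep = "=", collapse = ", "), "\n")
  cat("Generalized: ", x$gen_summary$n_associations, " SNP-trait pairs, ",
      x$gen_summary$n_unique_snps, " unique SNPs\n", sep = "")
  cat("Mismatches against printed generalization labels:",
      nrow(x$g_diff), "\n")
  cat("CAF correlation vs EA:\n")
  cat(sprintf("  %s: r = %.2f (%d SNPs)\n", x$caf_cor$population,
              x$caf_cor$r, x$caf_cor$n_snps), sep = "")
  invisible(x)
}
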