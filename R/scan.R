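#' Scan configuration
#'
#' @param filter a [filter_config()] for the QC cascade.
#' @param fdr_level FDR level used when counting discoveries (default 0.05).
#' @param fdr_method `"BH"` (default) or `"storey"`; see [fdr_qvalues()].
#' @param control optimizer settings, see [trd_control()].
#' @param seed integer kept for reproducibility bookkeeping. The fit itself
#'   is fully deterministic (fixed restart design), so the scan does not
#'   consume random numbers; the seed is recorded in logs so simulator-fed
#'   runs can be reproduced end to end.
#' @return A list of class `scan_config`.
#' @export
scan_config <- function(filter = filter_config(), fdr_level = 0.05,
                        fdr_method = c("BH", "storey"),
                        control = trd_control(), seed = 1L) {
  if (fdr_level <= 0 || fdr_level >= 1) stop("fdr_level must be in (0, 1)")
  structure(list(filter = filter, fdr_level = fdr_level,
                 fdr_method = match.arg(fdr_method), control = control,
                 seed = as.integer(seed)),
            class = "scan_config")
}

#' Genome-wide transmission-distortion scan
#'
#' Runs the whole per-SNP analysis: major-allele recoding (if not already
#' applied), the QC filter cascade, per-SNP transmission counts, null and
#' full maximum-likelihood fits, the likelihood ratio test, and FDR
#' correction across retained SNPs. SNP fits are independent, so the result
#' rows are a pure per-SNP function of the inputs and permuting the SNP
#' order permutes the rows identically.
#'
#' @param table a `genotype_table` covering dams and offspring.
#' @param families a `family_set`.
#' @param config a [scan_config()].
#' @param recode apply [recode_major_allele()] first (default TRUE; set to
#'   FALSE to keep a fixed, already-chosen allele orientation).
#' @return A data frame with one row per retained SNP: `snp_id`, `chrom`,
#'   `pos`, `alpha`, `pi_E`, `pi_R`, `lnL_full`, `lnL_null`, `lrt`,
#'   `p_value`, `q_value`, `call_rate`, `consistency`, `maf`, `dam_het`,
#'   `n_families_used`. Non-estimable SNPs keep their row with `NA` test
#'   fields and are excluded from the FDR correction. Attributes:
#'   `filter_report` (per-stage counts), `n_incompatible` (Mendelian
#'   incompatible pairs excluded across SNPs), `fdr_level`.
#' @export
trd_scan <- function(table, families, config = scan_config(),
                     recode = TRUE) {
  families <- family_set(families, attr(families, "dam_variety"))
  ids <- unique(c(families$dam_id, families$offspring_id))
  missing_ids <- setdiff(ids, colnames(table$geno))
  if (length(missing_ids))
    stop("individuals in the family file are missing from the genotypes: ",
         paste(missing_ids, collapse = ", "))
  table <- subset_table(table, individuals = match(ids, colnames(table$geno)))
  if (recode) table <- recode_major_allele(table)
  filt <- apply_filters(table, families, config$filter)
  tab <- filt$table
  metrics <- filt$metrics[filt$metrics$retained, , drop = FALSE]
  m <- n_snps(tab)
  if (m == 0L) warning("no SNPs retained after filtering")

  dam_cols <- match(families$dam_id, colnames(tab$geno))
  off_cols <- match(families$offspring_id, colnames(tab$geno))
  res <- data.frame(
    snp_id = tab$map$snp_id, chrom = tab$map$chrom, pos = tab$map$pos,
    alpha = NA_real_, pi_E = NA_real_, pi_R = NA_real_,
    lnL_full = NA_real_, lnL_null = NA_real_, lrt = NA_real_,
    p_value = NA_real_, q_value = NA_real_,
    call_rate = metrics$call_rate, consistency = metrics$consistency,
    maf = metrics$maf, dam_het = metrics$dam_het,
    n_families_used = NA_integer_, stringsAsFactors = FALSE
  )
  n_incompat <- 0L
  for (i in seq_len(m)) {
    row <- tab$geno[i, ]
    counts <- tabulate_transmissions(row[dam_cols], row[off_cols],
                                     families$sire_variety,
                                     families$offspring_id)
    n_incompat <- n_incompat + nrow(attr(counts, "incompatible"))
    res$n_families_used[i] <- sum(counts)
    null <- fit_trd_null(counts)
    full <- fit_trd_full(counts, config$control)
    if (!full$estimable || !null$estimable) next
    test <- lrt_pvalue(full, null)
    res$alpha[i] <- full$alpha
    res$pi_E[i] <- full$pi_E
    res$pi_R[i] <- full$pi_R
    res$lnL_full[i] <- full$lnL
    res$lnL_null[i] <- null$lnL
    res$lrt[i] <- test$statistic
    res$p_value[i] <- test$p_value
  }
  res$q_value <- fdr_qvalues(res$p_value, method = config$fdr_method)
  attr(res, "filter_report") <- filt$report
  attr(res, "n_incompatible") <- n_incompat
  attr(res, "fdr_level") <- config$fdr_level
  res
}

# round to 6 significant digits for stable text output
format_float_cols <- function(df) {
  for (j in seq_along(df)) if (is.double(df[[j]])) df[[j]] <- signif(df[[j]], 6)
  df
}

#' Write scan results as TSV
#'
#' Writes the result table with floating-point values at six significant
#' digits, and returns a small summary: the number of SNPs significant at
#' the FDR level and the fraction of those with negative distortion (excess
#' transmission of the minor allele).
#'
#' @param results data frame from [trd_scan()].
#' @param path output path.
#' @param fdr_level FDR level for the summary counts; defaults to the level
#'   recorded in `results`.
#' @return Invisibly, a list: `n_snps`, `n_significant`, `frac_negative`.
#' @export
write_results <- function(results, path,
                          fdr_level = attr(results, "fdr_level") %||% 0.05) {
  write.table(format_float_cols(as.data.frame(results)), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  sig <- !is.na(results$q_value) & results$q_value < fdr_level
  invisible(list(
    n_snps = nrow(results),
    n_significant = sum(sig),
    frac_negative = if (any(sig)) mean(results$alpha[sig] < 0) else NA_real_
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Top significant SNP per chromosome
#'
#' For each chromosome with at least one SNP below the q-value threshold,
#' reports the SNP with the smallest q-value (ties broken toward the
#' smaller base-pair position) — the annotation layer of a Manhattan plot.
#'
#' @param results data frame from [trd_scan()].
#' @param fdr_level q-value threshold (default 0.05).
#' @return Data frame of top hits, one row per chromosome that has any.
#' @export
manhattan_table <- function(results,
                            fdr_level = attr(results, "fdr_level") %||% 0.05) {
  sig <- results[!is.na(results$q_value) & results$q_value < fdr_level, ,
                 drop = FALSE]
  if (nrow(sig) == 0L) return(sig)
  picked <- lapply(split(sig, sig$chrom), function(d) {
    d <- d[order(d$q_value, d$pos), , drop = FALSE]
    d[1L, , drop = FALSE]
  })
  out <- do.call(rbind, picked)
  rownames(out) <- NULL
  out[order(out$chrom, out$pos), , drop = FALSE]
}
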