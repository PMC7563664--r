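#' Filter configuration for the SNP quality-control cascade
#'
#' Thresholds are compared with strict inequalities (`metric > threshold`),
#' so e.g. a SNP with dam heterozygosity exactly equal to `min_dam_het` is
#' removed. Defaults correspond to the standard family-based TRD screen:
#' keep SNPs with any non-missing call, family consistency above 75%, minor
#' allele frequency above 5% and dam heterozygosity above 20%. Only families
#' with a heterozygous dam inform the distortion estimate, which is why the
#' dam-heterozygosity floor matters.
#'
#' @param min_call_rate minimum call rate (fraction of individuals with a
#'   non-missing call); the default 0 removes only SNPs with no calls at all.
#' @param min_maf minimum minor allele frequency.
#' @param min_consistency minimum family consistency rate: fraction of
#'   families with both members genotyped and Mendelian-compatible.
#' @param min_dam_het minimum fraction of genotyped dams that are
#'   heterozygous.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_call_rate = 0, min_maf = 0.05,
                          min_consistency = 0.75, min_dam_het = 0.20) {
  vals <- c(min_call_rate, min_maf, min_consistency, min_dam_het)
  if (any(vals < 0) || any(vals > 1))
    stop("all filter thresholds must lie in [0, 1]")
  structure(list(min_call_rate = min_call_rate, min_maf = min_maf,
                 min_consistency = min_consistency,
                 min_dam_het = min_dam_het),
            class = "filter_config")
}

#' Per-SNP call rate
#'
#' @param snp_row integer vector of genotype codes for one SNP
#'   (0/1/2/`NA`) across individuals.
#' @return Fraction of individuals with a non-missing call.
#' @export
call_rate <- function(snp_row) {
  if (length(snp_row) == 0L) stop("call rate needs at least one individual")
  mean(!is.na(snp_row))
}

#' Per-SNP minor allele frequency
#'
#' Assumes the row is recoded so codes count the major allele A1; the MAF is
#' then the A2 frequency among all non-missing calls and lies in \[0, 0.5\].
#'
#' @inheritParams call_rate
#' @return MAF, or `NA` when every call is missing.
#' @export
maf <- function(snp_row) {
  x <- snp_row[!is.na(snp_row)]
  if (length(x) == 0L) return(NA_real_)
  # single correctly-rounded division so threshold boundaries (e.g. a count
  # of exactly 5%) compare exactly against the configured fraction
  (2 * length(x) - sum(x)) / (2 * length(x))
}

#' Per-SNP family consistency rate
#'
#' The fraction of families in which dam and offspring are both genotyped
#' and the pair is Mendelian-compatible. An A1A1 dam cannot produce an A2A2
#' offspring and vice versa (codes dam 2 with offspring 0, or dam 0 with
#' offspring 2); such pairs point to genotyping error and would carry zero
#' likelihood, so they count as inconsistent. A heterozygous dam is
#' compatible with any offspring genotype.
#'
#' @param dam_codes genotype codes of the dams, aligned with `off_codes`
#'   (one entry per family).
#' @param off_codes genotype codes of the offspring.
#' @return Consistency rate, or `NA` when there are zero families.
#' @export
family_consistency_rate <- function(dam_codes, off_codes) {
  n <- length(dam_codes)
  if (n == 0L) return(NA_real_)
  stopifnot(length(off_codes) == n)
  complete <- !is.na(dam_codes) & !is.na(off_codes)
  compat <- complete &
    !((dam_codes == 2L & off_codes == 0L) |
      (dam_codes == 0L & off_codes == 2L))
  sum(compat) / n
}

#' Per-SNP dam heterozygosity
#'
#' @param dam_codes genotype codes of the dams at one SNP (one entry per
#'   dam; pass unique dams, not one per family, if dams recur).
#' @return Fraction of genotyped dams with a heterozygous call, or `NA`
#'   when every dam is missing.
#' @export
dam_heterozygosity <- function(dam_codes) {
  x <- dam_codes[!is.na(dam_codes)]
  if (length(x) == 0L) return(NA_real_)
  mean(x == 1L)
}

#' Compute all per-SNP QC metrics
#'
#' @param table a recoded `genotype_table` whose columns cover the family
#'   individuals.
#' @param families a `family_set`.
#' @return Data frame with one row per SNP: `snp_id`, `call_rate`, `maf`,
#'   `consistency`, `dam_het`.
#' @export
qc_metrics <- function(table, families) {
  missing_ids <- ungenotyped_ids(families, table)
  if (length(missing_ids))
    stop("individuals in the family file are missing from the genotypes: ",
         paste(missing_ids, collapse = ", "))
  geno <- table$geno
  dam_cols <- match(families$dam_id, colnames(geno))
  off_cols <- match(families$offspring_id, colnames(geno))
  uniq_dam_cols <- match(unique(families$dam_id), colnames(geno))
  m <- nrow(geno)
  out <- data.frame(
    snp_id = table$map$snp_id,
    call_rate = NA_real_, maf = NA_real_,
    consistency = NA_real_, dam_het = NA_real_,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(m)) {
    row <- geno[i, ]
    out$call_rate[i] <- call_rate(row)
    out$maf[i] <- maf(row)
    out$consistency[i] <- family_consistency_rate(row[dam_cols],
                                                  row[off_cols])
    out$dam_het[i] <- dam_heterozygosity(row[uniq_dam_cols])
  }
  out
}

#' Apply the SNP quality-control cascade
#'
#' Filters are applied in a fixed order so the per-stage removal counts are
#' interpretable: (1) a pre-filter dropping SNPs with call rate not above
#' `min_call_rate` or a MAF of zero (monomorphic), (2) family consistency,
#' (3) minor allele frequency, (4) dam heterozygosity. All comparisons are
#' strict (`>`). A SNP whose metric is undefined (all calls missing, no
#' families) fails the corresponding stage. The final retained set is the
#' intersection of the per-SNP predicates and therefore does not depend on
#' the stage order; only the per-stage counts in the report do.
#'
#' @param table a recoded `genotype_table`.
#' @param families a `family_set`.
#' @param config a [filter_config()].
#' @return A list with elements `table` (the filtered `genotype_table`),
#'   `report` (data frame: `stage`, `removed`, `retained`) and `metrics`
#'   (per-SNP metric values for all input SNPs, with a logical `retained`
#'   column).
#' @export
apply_filters <- function(table, families, config = filter_config()) {
  met <- qc_metrics(table, families)
  ok_pre <- !is.na(met$call_rate) & met$call_rate > config$min_call_rate &
    !is.na(met$maf) & met$maf > 0
  ok_cons <- !is.na(met$consistency) & met$consistency > config$min_consistency
  ok_maf <- !is.na(met$maf) & met$maf > config$min_maf
  ok_het <- !is.na(met$dam_het) & met$dam_het > config$min_dam_het

  keep <- ok_pre
  report <- data.frame(stage = "call_rate_maf_zero",
                       removed = sum(!ok_pre),
                       retained = sum(keep), stringsAsFactors = FALSE)
  for (st in list(list("consistency", ok_cons),
                  list("maf", ok_maf),
                  list("dam_het", ok_het))) {
    removed <- sum(keep & !st[[2]])
    keep <- keep & st[[2]]
    report <- rbind(report, data.frame(stage = st[[1]], removed = removed,
                                       retained = sum(keep),
                                       stringsAsFactors = FALSE))
  }
  met$retained <- keep
  list(table = subset_table(table, snps = keep),
       report = report, metrics = met)
}

#' Write a filter report and per-SNP metrics as TSV
#'
#' @param filtered result of [apply_filters()].
#' @param report_path path for the per-stage report TSV.
#' @param metrics_path optional path for the per-SNP metrics TSV.
#' @return Invisibly, `filtered`.
#' @export
write_filter_report <- function(filtered, report_path, metrics_path = NULL) {
  write.table(filtered$report, report_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(metrics_path))
    write.table(format_float_cols(filtered$metrics), metrics_path,
                sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(filtered)
}
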