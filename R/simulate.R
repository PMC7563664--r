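#' Default cross design for a simulated panel
#'
#' Families in a dam-variety panel are split between Entrepelado- and
#' Retinto-sired crosses in the default study proportions: 97:32 for an
#' Entrepelado-dam panel (EE and RE crosses) and 57:61 for a Retinto-dam
#' panel (ER and RR crosses). Given a total family count, this returns the
#' per-sire-variety counts at those proportions.
#'
#' @param n_families total number of dam-offspring families.
#' @param dam_variety `"E"` or `"R"`.
#' @return Named integer vector `c(E = ..., R = ...)` summing to
#'   `n_families`.
#' @export
cross_design <- function(n_families, dam_variety = c("E", "R")) {
  dam_variety <- match.arg(dam_variety)
  prop_e <- if (dam_variety == "E") 97 / (97 + 32) else 57 / (57 + 61)
  nE <- as.integer(round(n_families * prop_e))
  c(E = nE, R = as.integer(n_families) - nE)
}

#' Simulate dam-offspring genotype panels with known distortion
#'
#' Generates a family panel under the maternal-transmission model run
#' forward: dam genotypes are drawn from Hardy-Weinberg proportions at the
#' focal-allele frequency `dam_freq`; each offspring receives one maternal
#' allele (the focal allele with probability 1, `0.5 + alpha` or 0 according
#' to the dam genotype) and one paternal allele drawn with probability
#' `pi_E` or `pi_R` according to the family's sire variety. Sire genotypes
#' are never materialized — only the transmitted allele matters to the
#' model. Missingness is applied independently per genotype call.
#'
#' Genotype codes in the returned table count the simulated focal allele,
#' and two allele labels are drawn per SNP, so [recode_major_allele()] may
#' or may not flip a SNP depending on its realized sample frequency —
#' exactly as with real data. The true parameters refer to the simulated
#' orientation; [truth_orientation()] tells which SNPs a recoded table
#' flips.
#'
#' All draws come from R's global RNG in a fixed documented order (per SNP:
#' allele labels, dam genotypes, maternal alleles, paternal alleles, then
#' the missingness mask), so a given `seed` reproduces the panel exactly.
#'
#' @param n_snps number of SNPs.
#' @param n_families named vector `c(E = , R = )` of family counts per sire
#'   variety; default `cross_design(129, "E")`, the Entrepelado-dam design
#'   (97 EE + 32 RE families).
#' @param alpha,pi_E,pi_R,dam_freq true parameters, each a scalar or a
#'   length-`n_snps` vector (recycled).
#' @param missing_rate per-call missingness probability.
#' @param dam_variety label recorded on the family set.
#' @param offspring_per_dam offspring per dam; with values > 1 consecutive
#'   families share a dam and the likelihood still treats families as
#'   independent.
#' @param chrom chromosome labels per SNP (recycled; default `"1"`).
#' @param seed optional integer seed (`NULL` = use the current RNG stream).
#' @return A list of class `trd_sim`: `table` (unrecoded `genotype_table`),
#'   `families` (`family_set`), and `truth` — a list with per-SNP data frame
#'   `params` (`snp_id`, `alpha`, `pi_E`, `pi_R`, `dam_freq`, `a1`) and the
#'   `maternal_allele` matrix (SNPs x families; 1 = focal allele
#'   transmitted).
#' @export
simulate_families <- function(n_snps,
                              n_families = cross_design(129, "E"),
                              alpha = 0, pi_E = 0.5, pi_R = 0.5,
                              dam_freq = 0.5, missing_rate = 0,
                              dam_variety = "E", offspring_per_dam = 1L,
                              chrom = "1", seed = NULL) {
  stopifnot(n_snps >= 1, all(n_families >= 0), sum(n_families) >= 1,
            offspring_per_dam >= 1)
  rec <- function(x, what, lo, hi) {
    if (any(x < lo | x > hi))
      stop(what, " must lie in [", lo, ", ", hi, "]")
    rep_len(x, n_snps)
  }
  alpha <- rec(alpha, "alpha", -ALPHA_BOUND, ALPHA_BOUND)
  pi_E <- rec(pi_E, "pi_E", 0, 1)
  pi_R <- rec(pi_R, "pi_R", 0, 1)
  dam_freq <- rec(dam_freq, "dam_freq", 0, 1)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)

  nE <- n_families[["E"]]
  nR <- n_families[["R"]]
  n_fam <- nE + nR
  sire <- c(rep("E", nE), rep("R", nR))
  n_dams <- as.integer(ceiling(n_fam / offspring_per_dam))
  dam_of_family <- rep(seq_len(n_dams), each = offspring_per_dam)[seq_len(n_fam)]
  dam_ids <- sprintf("dam%04d", seq_len(n_dams))
  off_ids <- sprintf("off%04d", seq_len(n_fam))

  snp_ids <- sprintf("snp%05d", seq_len(n_snps))
  geno <- matrix(NA_integer_, n_snps, n_dams + n_fam,
                 dimnames = list(snp_ids, c(dam_ids, off_ids)))
  alleles <- matrix(NA_character_, n_snps, 2)
  maternal <- matrix(NA_integer_, n_snps, n_fam,
                     dimnames = list(snp_ids, off_ids))
  pi_fam <- function(i) ifelse(sire == "E", pi_E[i], pi_R[i])
  for (i in seq_len(n_snps)) {
    alleles[i, ] <- sample(c("A", "C", "G", "T"), 2L)
    dams <- rbinom(n_dams, 2L, dam_freq[i])
    dam_g <- dams[dam_of_family]
    m_allele <- integer(n_fam)
    m_allele[dam_g == 2L] <- 1L
    het <- dam_g == 1L
    m_allele[het] <- rbinom(sum(het), 1L, 0.5 + alpha[i])
    p_allele <- rbinom(n_fam, 1L, pi_fam(i))
    geno[i, ] <- c(dams, m_allele + p_allele)
    maternal[i, ] <- m_allele
    if (missing_rate > 0) {
      drop <- runif(n_dams + n_fam) < missing_rate
      geno[i, drop] <- NA_integer_
    }
  }
  table <- genotype_table(
    geno,
    data.frame(snp_id = snp_ids, chrom = rep_len(as.character(chrom), n_snps),
               pos = 10000 * seq_len(n_snps), stringsAsFactors = FALSE),
    alleles
  )
  families <- family_set(
    data.frame(offspring_id = off_ids, dam_id = dam_ids[dam_of_family],
               sire_variety = sire, stringsAsFactors = FALSE),
    dam_variety = dam_variety
  )
  truth <- list(
    params = data.frame(snp_id = snp_ids, alpha = alpha, pi_E = pi_E,
                        pi_R = pi_R, dam_freq = dam_freq,
                        a1 = alleles[, 1], stringsAsFactors = FALSE),
    maternal_allele = maternal
  )
  structure(list(table = table, families = families, truth = truth),
            class = "trd_sim")
}

#' Which simulated SNPs does recoding flip?
#'
#' Major-allele recoding flips a SNP's orientation whenever the simulated
#' focal allele turns out minor in the realized sample; estimates on the
#' recoded scale then map to the simulated truth as
#' `(alpha, pi) -> (-alpha, 1 - pi)`.
#'
#' @param sim a `trd_sim` from [simulate_families()].
#' @param recoded the recoded `genotype_table`
#'   (default `recode_major_allele(sim$table)`).
#' @return Logical vector, `TRUE` where the recoded A1 differs from the
#'   simulated focal allele.
#' @export
truth_orientation <- function(sim, recoded = recode_major_allele(sim$table)) {
  recoded$alleles[, 1] != sim$truth$params$a1
}

#' Write a simulated panel as PLINK text plus family and truth files
#'
#' Emits `<prefix>.ped`, `<prefix>.map`, `<prefix>.families.tsv` and
#' `<prefix>.truth.tsv`, so simulator output feeds the command-line scan
#' unchanged.
#'
#' @param sim a `trd_sim`.
#' @param prefix output path prefix.
#' @return Invisibly, the four written paths.
#' @export
write_sim <- function(sim, prefix) {
  paths <- paste0(prefix, c(".ped", ".map", ".families.tsv", ".truth.tsv"))
  tab <- sim$table
  m <- n_snps(tab)
  map <- data.frame(chrom = tab$map$chrom, snp_id = tab$map$snp_id,
                    cM = 0, pos = tab$map$pos)
  write.table(map, paths[2], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  ids <- colnames(tab$geno)
  dam_of <- sim$families$dam_id[match(ids, sim$families$offspring_id)]
  ped <- file(paths[1], "w")
  on.exit(close(ped))
  for (j in seq_along(ids)) {
    g <- tab$geno[, j]
    a <- character(2 * m)
    a1 <- tab$alleles[, 1]
    a2 <- tab$alleles[, 2]
    a[c(TRUE, FALSE)] <- ifelse(is.na(g), "0", ifelse(g >= 1, a1, a2))
    a[c(FALSE, TRUE)] <- ifelse(is.na(g), "0", ifelse(g == 2, a1, a2))
    writeLines(paste(c(ids[j], ids[j], "0",
                       if (is.na(dam_of[j])) "0" else dam_of[j],
                       "2", "-9", a), collapse = " "), ped)
  }
  write.table(sim$families, paths[3], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(format_float_cols(sim$truth$params), paths[4], sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(setNames(paths, c("ped", "map", "families", "truth")))
}

#' Empirical type-I error of the scan under the null
#'
#' Simulates a panel with `alpha = 0` everywhere, runs the full scan
#' (recoding, QC filters, fits, LRT, FDR) and reports the fraction of
#' tested SNPs with `p < level` together with an exact binomial confidence
#' interval, plus the number of q-value discoveries. Because the LRT
#' statistic is clipped at zero at the boundary, the empirical rate can
#' fall somewhat below the nominal level; the test is conservative, never
#' anti-conservative.
#'
#' @param n_snps number of null SNPs to simulate.
#' @param n_families total families (split by [cross_design()]) or a named
#'   `c(E=, R=)` vector.
#' @param seed integer seed.
#' @param level nominal test level (default 0.05).
#' @param dam_freq,pi_E,pi_R,missing_rate simulation settings.
#' @param config scan configuration.
#' @return List: `n_tested`, `rate`, `ci` (95% Clopper-Pearson),
#'   `n_q_discoveries` (q < `config$fdr_level`), `low_information` (TRUE
#'   when fewer than 20 families).
#' @export
null_calibration <- function(n_snps, n_families = 250, seed = 1L,
                             level = 0.05, dam_freq = 0.5,
                             pi_E = 0.5, pi_R = 0.5, missing_rate = 0,
                             config = scan_config()) {
  if (n_snps < 1) stop("n_snps must be at least 1")
  if (length(n_families) == 1L) n_families <- cross_design(n_families, "E")
  sim <- simulate_families(n_snps, n_families = n_families, alpha = 0,
                           pi_E = pi_E, pi_R = pi_R, dam_freq = dam_freq,
                           missing_rate = missing_rate, seed = seed)
  res <- trd_scan(sim$table, sim$families, config)
  p <- res$p_value[!is.na(res$p_value)]
  n <- length(p)
  if (n == 0L) stop("no testable SNPs survived filtering")
  k <- sum(p < level)
  ci <- stats::binom.test(k, n)$conf.int
  list(n_tested = n, rate = k / n, ci = as.numeric(ci),
       n_q_discoveries = sum(!is.na(res$q_value) &
                               res$q_value < config$fdr_level),
       low_information = sum(n_families) < 20)
}

#' Empirical power of the scan across distortion strengths and sample sizes
#'
#' For every combination of true `alpha` and family count, repeatedly embeds
#' one distorted SNP among null SNPs, runs the full scan, and reports the
#' fraction of replicates in which the distorted SNP is discovered at
#' `q < fdr_level`.
#'
#' @param alpha_grid true distortion values.
#' @param n_grid total family counts (each split by [cross_design()]).
#' @param reps replicates per grid point.
#' @param seed integer seed.
#' @param n_null_snps null SNPs accompanying the distorted SNP in each scan.
#' @param dam_freq,pi_E,pi_R simulation settings.
#' @param fdr_level discovery threshold on the q-value.
#' @param config scan configuration.
#' @return Data frame: `alpha`, `n_families`, `power`, `reps`.
#' @export
power_curve <- function(alpha_grid, n_grid, reps = 20, seed = 1L,
                        n_null_snps = 20, dam_freq = 0.5,
                        pi_E = 0.5, pi_R = 0.5, fdr_level = 0.05,
                        config = scan_config()) {
  stopifnot(length(alpha_grid) >= 1, length(n_grid) >= 1, reps >= 1)
  set.seed(seed)
  grid <- expand.grid(alpha = alpha_grid, n_families = n_grid)
  grid$power <- NA_real_
  grid$reps <- as.integer(reps)
  for (g in seq_len(nrow(grid))) {
    hits <- logical(reps)
    fams <- cross_design(grid$n_families[g], "E")
    for (r in seq_len(reps)) {
      sim <- simulate_families(
        n_null_snps + 1L, n_families = fams,
        alpha = c(grid$alpha[g], rep(0, n_null_snps)),
        pi_E = pi_E, pi_R = pi_R, dam_freq = dam_freq
      )
      res <- trd_scan(sim$table, sim$families, config)
      q <- res$q_value[match("snp00001", res$snp_id)]
      hits[r] <- !is.na(q) && q < fdr_level
    }
    grid$power[g] <- mean(hits)
  }
  grid
}
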