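#' Read PLINK text genotypes (.ped/.map)
#'
#' Parses the whitespace-delimited PLINK text format: the `.map` file gives
#' one marker per line (`chrom`, `snp_id`, `cM`, `bp`) and each `.ped` row
#' holds the six mandatory pedigree columns followed by two allele columns
#' per SNP, with `"0"` marking a missing allele. Genotypes are converted to
#' dosages of the first-seen allele at each SNP; the orientation is fixed
#' afterwards with [recode_major_allele()]. A pair with one or both alleles
#' missing is treated as a fully missing genotype.
#'
#' @param ped_path path to the `.ped` file.
#' @param map_path path to the `.map` file.
#' @return An (unrecoded) `genotype_table`. Individual identifiers are taken
#'   from the second `.ped` column (within-family ID).
#' @export
read_plink <- function(ped_path, map_path) {
  map_raw <- read.table(map_path, header = FALSE, stringsAsFactors = FALSE,
                        colClasses = c("character", "character", "numeric",
                                       "numeric"))
  names(map_raw) <- c("chrom", "snp_id", "cM", "pos")
  m <- nrow(map_raw)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  expected <- 6L + 2L * m
  for (r in seq_along(fields)) {
    if (length(fields[[r]]) != expected)
      stop(".ped row ", r, " has ", length(fields[[r]]),
           " fields; expected ", expected, " for ", m, " mapped SNPs")
  }
  n <- length(fields)
  ids <- vapply(fields, `[[`, character(1), 2L)
  # allele matrix: individuals x 2m
  am <- matrix(unlist(lapply(fields, function(f) f[-(1:6)])),
               nrow = n, byrow = TRUE)
  geno <- matrix(NA_integer_, nrow = m, ncol = n,
                 dimnames = list(map_raw$snp_id, ids))
  alleles <- matrix(NA_character_, nrow = m, ncol = 2)
  for (j in seq_len(m)) {
    a <- am[, 2L * j - 1L]
    b <- am[, 2L * j]
    obs <- c(rbind(a, b))          # reading order: ind1 allele1, allele2, ...
    obs <- obs[obs != "0"]
    labs <- unique(obs)
    if (length(labs) > 2L)
      stop("SNP ", map_raw$snp_id[j], " has ", length(labs),
           " distinct alleles (", paste(labs, collapse = ","),
           "); only biallelic markers are supported")
    if (length(labs) == 0L) next   # fully missing SNP
    a1 <- labs[1L]                 # first-seen allele defines the raw dosage
    complete <- a != "0" & b != "0"
    geno[j, complete] <- (a[complete] == a1) + (b[complete] == a1)
    alleles[j, 1L] <- a1
    if (length(labs) == 2L) alleles[j, 2L] <- labs[2L]
  }
  genotype_table(geno, map_raw[, c("snp_id", "chrom", "pos")], alleles)
}

#' Read genotypes from a VCF file
#'
#' Reads biallelic SNP records from a VCF 4.x file (plain or gzip) through
#' the `vcfR` parser. Dosages count the REF allele prior to recoding; the
#' final A1 orientation is set by [recode_major_allele()]. Multi-allelic
#' records are skipped with a warning reporting how many were dropped.
#' `./.` (or `.|.`) genotypes become missing.
#'
#' @param vcf_path path to the VCF file.
#' @return An (unrecoded) `genotype_table`.
#' @export
read_vcf <- function(vcf_path) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  bi <- vcfR::is.biallelic(vcf)
  n_multi <- sum(!bi)
  if (n_multi > 0) {
    warning("skipped ", n_multi, " multi-allelic record",
            if (n_multi > 1) "s" else "")
    vcf <- vcf[bi, ]
  }
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  m <- nrow(fix)
  ids <- colnames(vcf@gt)[-1L]
  if (m == 0L) {
    return(genotype_table(
      matrix(NA_integer_, 0, length(ids), dimnames = list(NULL, ids)),
      data.frame(snp_id = character(), chrom = character(), pos = numeric()),
      matrix(NA_character_, 0, 2)))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  # dosage of REF: count "0" alleles in the GT string; any "." -> missing
  first <- substr(gt, 1, 1)
  third <- substr(gt, 3, 3)
  geno <- (first == "0") + (third == "0")
  geno[first == "." | third == "." | is.na(gt)] <- NA_integer_
  geno <- matrix(as.integer(geno), nrow = m)
  snp_id <- fix[, "ID"]
  noid <- is.na(snp_id) | snp_id == "."
  snp_id[noid] <- paste0(fix[noid, "CHROM"], ":", fix[noid, "POS"])
  colnames(geno) <- ids
  genotype_table(
    geno,
    data.frame(snp_id = snp_id, chrom = fix[, "CHROM"],
               pos = as.numeric(fix[, "POS"]), stringsAsFactors = FALSE),
    cbind(fix[, "REF"], fix[, "ALT"])
  )
}

#' Read the family file
#'
#' The family file is a tab-separated table with a header line and columns
#' `offspring_id`, `dam_id`, `sire_variety`, one row per dam-offspring pair.
#' `sire_variety` labels the (ungenotyped) sire's source population and must
#' be `"E"` or `"R"`. Each offspring may appear only once; a dam may appear
#' in several families.
#'
#' @param tsv_path path to the family file.
#' @param dam_variety optional label for the dam population of the whole set
#'   (analyses are run per dam variety); stored as an attribute.
#' @return A data frame of class `family_set` with the three columns above.
#' @export
read_families <- function(tsv_path, dam_variety = NA_character_) {
  fam <- read.table(tsv_path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, colClasses = "character")
  need <- c("offspring_id", "dam_id", "sire_variety")
  if (!all(need %in% names(fam)))
    stop("family file must have header columns: ",
         paste(need, collapse = ", "))
  family_set(fam[, need], dam_variety = dam_variety)
}

#' Construct a family set
#'
#' @param records data frame with columns `offspring_id`, `dam_id`,
#'   `sire_variety`.
#' @param dam_variety optional dam-population label for the whole set.
#' @return A validated data frame of class `family_set`.
#' @export
family_set <- function(records, dam_variety = NA_character_) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  bad <- !records$sire_variety %in% c("E", "R")
  if (any(bad))
    stop("sire_variety must be 'E' or 'R'; offending line(s): ",
         paste(which(bad), collapse = ", "))
  dup <- duplicated(records$offspring_id)
  if (any(dup))
    stop("offspring appearing more than once: ",
         paste(unique(records$offspring_id[dup]), collapse = ", "))
  structure(records, dam_variety = dam_variety,
            class = c("family_set", "data.frame"))
}

#' Check that family members are genotyped
#'
#' @param families a `family_set`.
#' @param table a `genotype_table`.
#' @return Character vector of ids referenced by `families` but absent from
#'   `table` (empty when all are genotyped).
#' @export
ungenotyped_ids <- function(families, table) {
  ids <- unique(c(families$dam_id, families$offspring_id))
  setdiff(ids, colnames(table$geno))
}
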