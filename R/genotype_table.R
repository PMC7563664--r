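#' Construct a genotype table
#'
#' The central genotype container: an integer matrix of A1-allele dosages
#' (rows = SNPs, columns = individuals; codes 0/1/2, `NA` = missing) together
#' with the marker map and the two allele labels per SNP. After
#' [recode_major_allele()] the A1 allele is guaranteed to be the major allele
#' at every SNP.
#'
#' @param geno integer matrix, SNPs in rows and individuals in columns, with
#'   dimnames giving SNP and individual identifiers; entries in `{0, 1, 2, NA}`
#'   counting copies of the A1 allele.
#' @param map data frame with columns `snp_id`, `chrom`, `pos` (1-based
#'   base-pair position), one row per SNP in `geno` order.
#' @param alleles character matrix with two columns `a1`, `a2`: the allele
#'   labels per SNP. `a2` may be `NA` at a monomorphic SNP.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(geno, map, alleles) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(geno) != nrow(map))
    stop("map has ", nrow(map), " rows but genotype matrix has ", nrow(geno))
  if (anyDuplicated(map$snp_id))
    stop("duplicated SNP identifiers: ",
         paste(unique(map$snp_id[duplicated(map$snp_id)]), collapse = ", "))
  if (!is.null(colnames(geno)) && anyDuplicated(colnames(geno)))
    stop("duplicated individual identifiers")
  bad <- geno[!is.na(geno)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop("genotype codes must be 0, 1, 2 or NA")
  rownames(geno) <- map$snp_id
  alleles <- as.matrix(alleles)
  colnames(alleles) <- c("a1", "a2")
  rownames(alleles) <- map$snp_id
  structure(
    list(geno = geno, map = as.data.frame(map, stringsAsFactors = FALSE),
         alleles = alleles),
    class = "genotype_table"
  )
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table: ", nrow(x$geno), " SNPs x ", ncol(x$geno),
      " individuals\n", sep = "")
  miss <- mean(is.na(x$geno))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) dim(x$geno)

#' Number of SNPs / individuals in a genotype table
#' @param x a `genotype_table`.
#' @return Integer count.
#' @export
n_snps <- function(x) nrow(x$geno)

#' @rdname n_snps
#' @export
n_individuals <- function(x) ncol(x$geno)

#' Subset a genotype table
#'
#' @param x a `genotype_table`.
#' @param snps SNP index (integer, logical or character) or `NULL` for all.
#' @param individuals individual index or `NULL` for all.
#' @return A `genotype_table` restricted to the selected SNPs/individuals.
#' @export
subset_table <- function(x, snps = NULL, individuals = NULL) {
  if (is.null(snps)) snps <- seq_len(nrow(x$geno))
  if (is.null(individuals)) individuals <- seq_len(ncol(x$geno))
  genotype_table(x$geno[snps, individuals, drop = FALSE],
                 x$map[snps, , drop = FALSE],
                 x$alleles[snps, , drop = FALSE])
}

#' Recode genotypes so that A1 is the major allele
#'
#' Reorients every SNP so that the A1 allele (the allele whose copies the
#' dosage codes count) is the one with the higher frequency among all
#' non-missing calls of all individuals in the table, dams and offspring
#' pooled. Where the orientation flips, each code `c` becomes `2 - c` and the
#' allele labels are swapped. Using a fixed orientation means every distortion
#' estimate refers to the major allele, so scan results share one sign
#' convention: a negative `alpha` always means excess transmission of the
#' minor allele.
#'
#' Ties at frequency exactly 0.5 are broken deterministically: the
#' lexicographically smaller allele label becomes A1. Monomorphic SNPs keep
#' the single observed allele as A1 (all codes 2); they carry no information
#' and are removed later by the MAF filter.
#'
#' The operation is idempotent: applying it twice equals applying it once.
#'
#' @param table a `genotype_table`.
#' @return The recoded `genotype_table`.
#' @export
recode_major_allele <- function(table) {
  geno <- table$geno
  alleles <- table$alleles
  n_called <- rowSums(!is.na(geno))
  a1_copies <- rowSums(geno, na.rm = TRUE)
  for (i in seq_len(nrow(geno))) {
    if (n_called[i] == 0L) next
    f1 <- a1_copies[i] / (2 * n_called[i])
    flip <- if (f1 < 0.5) {
      TRUE
    } else if (f1 > 0.5) {
      FALSE
    } else {
      # exact tie: lexicographically smaller label becomes A1
      a2 <- alleles[i, 2L]
      !is.na(a2) && a2 < alleles[i, 1L]
    }
    if (f1 == 1 && !is.na(alleles[i, 2L])) {
      # monomorphic for current A1: orientation already major, nothing to do
      flip <- FALSE
    }
    if (f1 == 0) flip <- TRUE  # monomorphic for A2: make it A1, codes all 2
    if (flip) {
      geno[i, ] <- 2L - geno[i, ]
      alleles[i, ] <- alleles[i, c(2L, 1L)]
    }
  }
  out <- genotype_table(geno, table$map, alleles)
  attr(out, "recoded") <- TRUE
  out
}
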