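test_that("read_plink round-trips a hand-written fixture", {
  fx <- write_toy_plink()
  tab <- read_plink(fx$ped, fx$map)
  expect_s3_class(tab, "genotype_table")
  expect_equal(dim(tab), c(2L, 3L))
  expect_equal(tab$map$snp_id, c("snp1", "snp2"))
  expect_equal(tab$map$pos, c(1000, 2000))
  # snp1 alleles A (first seen) / C: dosages of A
  expect_equal(unname(tab$geno["snp1", ]), c(2L, 1L, 0L))
  # snp2 alleles G (first seen) / T
  expect_equal(unname(tab$geno["snp2", ]), c(1L, 2L, 0L))
  expect_false(anyNA(tab$geno))
})

test_that("read_plink treats any '0' allele as a missing genotype", {
  fx <- write_toy_plink(c(
    "f1 ind1 0 0 2 -9 0 0 G T",
    "f1 ind2 0 0 2 -9 A C G 0",   # half-missing pair is fully missing
    "f1 ind3 0 0 2 -9 C C T T"
  ))
  tab <- read_plink(fx$ped, fx$map)
  expect_true(is.na(tab$geno["snp1", "ind1"]))
  expect_true(is.na(tab$geno["snp2", "ind2"]))
  expect_equal(sum(is.na(tab$geno)), 2L)
})

test_that("read_plink rejects malformed rows and non-biallelic markers", {
  short <- write_toy_plink(c(
    "f1 ind1 0 0 2 -9 A A G T",
    "f1 ind2 0 0 2 -9 A C G"     # one allele column short
  ))
  expect_error(read_plink(short$ped, short$map), "row 2")
  tri <- write_toy_plink(c(
    "f1 ind1 0 0 2 -9 A A G T",
    "f1 ind2 0 0 2 -9 A C G G",
    "f1 ind3 0 0 2 -9 T C T T"   # snp1 sees A, C and T
  ))
  expect_error(read_plink(tri$ped, tri$map), "snp1")
})

test_that("read_vcf decodes GT fields and skips multi-allelic records", {
  one <- write_toy_vcf("1\t100\trs1\tA\tC\t.\tPASS\t.\tGT\t0/1\t0/0\t1/1")
  tab <- read_vcf(one)
  expect_equal(unname(tab$geno["rs1", ]), c(1L, 2L, 0L))  # REF dosage
  expect_equal(unname(tab$alleles["rs1", ]), c("A", "C"))

  miss <- write_toy_vcf("1\t100\trs1\tA\tC\t.\tPASS\t.\tGT\t./.\t0|1\t1/1")
  tabm <- read_vcf(miss)
  expect_true(is.na(tabm$geno["rs1", "ind1"]))
  expect_equal(tabm$geno["rs1", "ind2"], 1L)

  tri <- write_toy_vcf("1\t100\trs1\tA\tC,G\t.\tPASS\t.\tGT\t0/1\t0/0\t1/2")
  expect_warning(tabt <- read_vcf(tri), "multi-allelic")
  expect_equal(n_snps(tabt), 0L)
})

test_that("read_families validates sire variety and duplicate offspring", {
  fam <- read_families(write_toy_families())
  expect_s3_class(fam, "family_set")
  expect_equal(nrow(fam), 4L)
  expect_equal(as.vector(table(fam$sire_variety)), c(2L, 2L))

  expect_error(
    read_families(write_toy_families(c("o1\td1\tE", "o2\td2\tX"))),
    "sire_variety"
  )
  expect_error(
    read_families(write_toy_families(c("o1\td1\tE", "o1\td2\tR"))),
    "o1"
  )
})

test_that("recode_major_allele reorients SNPs to the major allele", {
  geno <- rbind(c(2L, 2L, 1L, 1L),   # A-dosage 6/8: A already major
                c(2L, 1L, 1L, 0L),   # A-dosage 4/8: tie
                c(0L, 0L, 1L, 1L))   # A-dosage 2/8: flip to B
  map <- data.frame(snp_id = paste0("s", 1:3), chrom = "1", pos = 1:3)
  alleles <- cbind(c("A", "C", "A"), c("C", "A", "B"))
  tab <- genotype_table(geno, map, alleles)
  rec <- recode_major_allele(tab)
  expect_equal(unname(rec$geno[1, ]), c(2L, 2L, 1L, 1L))       # unchanged
  expect_equal(unname(rec$alleles[1, ]), c("A", "C"))
  # tie: lexicographically smaller label (A) becomes A1 -> flips from C
  expect_equal(unname(rec$alleles[2, ]), c("A", "C"))
  expect_equal(unname(rec$geno[2, ]), 2L - c(2L, 1L, 1L, 0L))
  expect_equal(unname(rec$alleles[3, ]), c("B", "A"))
  expect_equal(unname(rec$geno[3, ]), c(2L, 2L, 1L, 1L))
})

test_that("recoding is idempotent and double allele-flip is the identity", {
  set.seed(42)
  geno <- matrix(sample(c(0:2, NA), 200, replace = TRUE), nrow = 20)
  map <- data.frame(snp_id = sprintf("s%02d", 1:20), chrom = "1", pos = 1:20)
  alleles <- cbind(rep("A", 20), rep("G", 20))
  tab <- genotype_table(geno, map, alleles)
  once <- recode_major_allele(tab)
  twice <- recode_major_allele(once)
  expect_identical(once$geno, twice$geno)
  expect_identical(once$alleles, twice$alleles)
  # flipping all codes twice restores the original table
  flip <- function(t) genotype_table(2L - t$geno, t$map, t$alleles[, 2:1])
  expect_identical(flip(flip(tab))$geno, tab$geno)
})

test_that("PLINK and VCF readers agree after recoding on equivalent data", {
  fx <- write_toy_plink()   # snp1: A A / A C / C C ; snp2: G T / G G / T T
  vcf <- write_toy_vcf(c(
    "1\t1000\tsnp1\tA\tC\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t2000\tsnp2\tG\tT\t.\tPASS\t.\tGT\t0/1\t0/0\t1/1"
  ))
  a <- recode_major_allele(read_plink(fx$ped, fx$map))
  b <- recode_major_allele(read_vcf(vcf))
  expect_identical(a$geno, b$geno)
  expect_identical(a$alleles, b$alleles)
  expect_equal(a$map$pos, b$map$pos)
})

test_that("monomorphic SNPs keep the observed allele as A1 with all codes 2", {
  geno <- rbind(c(0L, 0L, 0L))
  tab <- genotype_table(geno,
                        data.frame(snp_id = "s1", chrom = "1", pos = 1),
                        cbind("A", "G"))
  rec <- recode_major_allele(tab)
  expect_equal(unname(rec$geno[1, ]), c(2L, 2L, 2L))
  expect_equal(unname(rec$alleles[1, ]), c("G", "A"))
})
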