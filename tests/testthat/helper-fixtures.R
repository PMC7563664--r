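# Shared fixtures: small text-format writers, random count tables drawn from
# the transmission model, and an exhaustive grid-search oracle for the fit.

write_lines_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# two-SNP, three-individual PLINK text fixture used across reader tests
write_toy_plink <- function(ped_rows = NULL) {
  map <- c("1\tsnp1\t0\t1000",
           "1\tsnp2\t0\t2000")
  if (is.null(ped_rows)) {
    ped_rows <- c(
      "f1 ind1 0 0 2 -9 A A G T",
      "f1 ind2 0 0 2 -9 A C G G",
      "f1 ind3 0 0 2 -9 C C T T"
    )
  }
  list(ped = write_lines_tmp(ped_rows, ".ped"),
       map = write_lines_tmp(map, ".map"))
}

write_toy_vcf <- function(body, samples = c("ind1", "ind2", "ind3")) {
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  write_lines_tmp(c(header, body), ".vcf")
}

write_toy_families <- function(rows = NULL) {
  if (is.null(rows)) {
    rows <- c("o1\td1\tE", "o2\td2\tE", "o3\td3\tR", "o4\td4\tR")
  }
  write_lines_tmp(c("offspring_id\tdam_id\tsire_variety", rows), ".tsv")
}

# A 6-SNP panel over 5 dam-offspring families built so that exactly one SNP
# is removed at each cascade stage and two survive. snp2 fails family
# consistency (0.6), snp3 MAF (exactly 0.05), snp4 dam heterozygosity
# (exactly 0.20 -> removed under the strict inequality).
toy_panel <- function() {
  dams <- paste0("d", 1:5)
  offs <- paste0("o", 1:5)
  # columns: d1..d5, o1..o5
  geno <- rbind(
    snp1 = rep(NA_integer_, 10),                       # call rate 0 (pre)
    snp2 = c(0L, 0L, 1L, 1L, 2L, 2L, 2L, 1L, 0L, 2L), # consistency 0.6
    snp3 = c(1L, 2L, 2L, 2L, 2L, 2L, 2L, 2L, 2L, 2L), # MAF exactly 0.05
    snp4 = c(1L, 2L, 2L, 2L, 2L, 1L, 1L, 2L, 2L, 2L), # dam het exactly 0.20
    snp5 = c(1L, 1L, 0L, 2L, 2L, 1L, 0L, 1L, 2L, 1L), # passes everything
    snp6 = c(1L, 1L, 1L, 2L, 0L, 2L, 1L, 1L, 1L, 0L)  # passes everything
  )
  colnames(geno) <- c(dams, offs)
  tab <- genotype_table(
    geno,
    data.frame(snp_id = rownames(geno), chrom = "1", pos = 1:6 * 100),
    cbind(rep("A", 6), rep("G", 6))
  )
  fam <- family_set(data.frame(
    offspring_id = offs, dam_id = dams,
    sire_variety = c("E", "E", "E", "R", "R"), stringsAsFactors = FALSE
  ))
  list(table = tab, families = fam)
}

# build a count array by naming cells: cells is a list of c(dam, off, sire, n)
make_counts <- function(cells) {
  n <- array(0L, dim = c(3, 3, 2),
             dimnames = list(dam = 0:2, off = 0:2, sire = c("E", "R")))
  for (cell in cells) {
    s <- if (cell[[3]] == "E") 1L else 2L
    n[cell[[1]] + 1L, cell[[2]] + 1L, s] <- as.integer(cell[[4]])
  }
  n
}

# random transmission-count table drawn from the generative model, so the
# structural zeros (dam 2 / off 0 and dam 0 / off 2) hold automatically
random_counts <- function(n_fam = 60) {
  alpha <- runif(1, -0.45, 0.45)
  pis <- runif(2)
  dam_freq <- runif(1, 0.2, 0.8)
  n <- array(0L, dim = c(3, 3, 2),
             dimnames = list(dam = 0:2, off = 0:2, sire = c("E", "R")))
  for (i in seq_len(n_fam)) {
    s <- sample(1:2, 1)
    d <- rbinom(1, 2, dam_freq)
    m <- if (d == 2) 1L else if (d == 0) 0L else rbinom(1, 1, 0.5 + alpha)
    o <- m + rbinom(1, 1, pis[s])
    n[d + 1, o + 1, s] <- n[d + 1, o + 1, s] + 1L
  }
  n
}

# Exhaustive grid-search oracle: maximum log-likelihood over the box
# (alpha, pi_E, pi_R) at the given step. Exploits the separation of the
# likelihood by sire variety: for each alpha, each pi is maximized
# independently, so the 3-D grid collapses to two alpha x pi surfaces.
grid_loglik_max <- function(counts, alpha_step = 0.001, pi_step = 0.001) {
  alphas <- seq(-0.495, 0.495, by = alpha_step)
  pis <- seq(0, 1, by = pi_step)
  a <- 0.5 + alphas
  nA <- length(alphas)
  nP <- length(pis)
  row_of <- function(v) matrix(v, nA, nP, byrow = TRUE)
  total <- numeric(nA)
  for (s in 1:2) {
    ns <- counts[, , s]
    if (all(ns == 0L)) next
    M <- matrix(0, nA, nP)
    hom_ref <- ns[1, 1] + ns[3, 2]   # cells with probability 1 - pi
    hom_alt <- ns[1, 2] + ns[3, 3]   # cells with probability pi
    if (hom_ref > 0) M <- M + hom_ref * row_of(log(1 - pis))
    if (hom_alt > 0) M <- M + hom_alt * row_of(log(pis))
    if (ns[2, 1] > 0)
      M <- M + ns[2, 1] * (log(1 - a) %o% rep(1, nP) + row_of(log(1 - pis)))
    if (ns[2, 2] > 0)
      M <- M + ns[2, 2] * log(outer(a, pis, function(a, p) a + p - 2 * a * p))
    if (ns[2, 3] > 0)
      M <- M + ns[2, 3] * (log(a) %o% rep(1, nP) + row_of(log(pis)))
    total <- total + apply(M, 1, max)
  }
  max(total)
}

# label-swap of a count table: relabel A1 <-> A2 (reverse dam and offspring
# genotype codes)
swap_counts <- function(counts) {
  counts[3:1, 3:1, , drop = FALSE]
}

# simulate one SNP's counts directly from the model (fast path used by the
# sampling-distribution tests; no genotype table is materialized)
model_counts <- function(n_fam_E, n_fam_R, alpha, pi_E, pi_R,
                         dam_freq = 0.5) {
  sim_side <- function(n_fam, pi, s) {
    d <- rbinom(n_fam, 2, dam_freq)
    m <- integer(n_fam)
    m[d == 2] <- 1L
    het <- d == 1
    m[het] <- rbinom(sum(het), 1, 0.5 + alpha)
    o <- m + rbinom(n_fam, 1, pi)
    cbind(d, o, s)
  }
  x <- rbind(sim_side(n_fam_E, pi_E, 1L), sim_side(n_fam_R, pi_R, 2L))
  n <- array(0L, dim = c(3, 3, 2),
             dimnames = list(dam = 0:2, off = 0:2, sire = c("E", "R")))
  for (i in seq_len(nrow(x)))
    n[x[i, 1] + 1L, x[i, 2] + 1L, x[i, 3]] <-
      n[x[i, 1] + 1L, x[i, 2] + 1L, x[i, 3]] + 1L
  n
}
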