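# Upper bound on |alpha|. Kept strictly inside 0.5 so every transmission
# probability from a heterozygous dam stays positive and the log-likelihood
# remains finite on the whole box.
ALPHA_BOUND <- 0.495

#' Offspring genotype probabilities given the dam genotype
#'
#' Under the maternal-transmission model the offspring genotype is the sum
#' of one maternal and one paternal allele. A heterozygous dam transmits A1
#' with probability `0.5 + alpha` (so `alpha = 0` is Mendelian segregation);
#' homozygous dams transmit their only allele with probability 1. The
#' ungenotyped sire contributes A1 with probability `pi`, the A1 frequency
#' in his source population. The three offspring genotype probabilities are
#' the products
#' \deqn{p_2 = p_{dam}(A1)\,\pi,\quad
#'       p_1 = p_{dam}(A1)(1-\pi) + p_{dam}(A2)\,\pi,\quad
#'       p_0 = p_{dam}(A2)(1-\pi)}
#' with \eqn{p_{dam}(A1) = 0, 0.5+\alpha, 1} for dam genotypes 0, 1, 2.
#'
#' @param dam_genotype dam genotype code: 0, 1 or 2 copies of A1.
#' @param alpha distortion parameter in `[-0.495, 0.495]`; only used when
#'   the dam is heterozygous.
#' @param pi A1 allele frequency among sires, in `[0, 1]`.
#' @return Named numeric vector `c(p0, p1, p2)` summing to 1.
#' @examples
#' offspring_probs(1, 0, 0.5)     # Mendelian: 0.25 0.50 0.25
#' offspring_probs(2, 0.3, 0.3)   # A1A1 dam: 0, 1 - pi, pi
#' @export
offspring_probs <- function(dam_genotype, alpha, pi) {
  if (length(dam_genotype) != 1L || !dam_genotype %in% c(0, 1, 2))
    stop("dam_genotype must be a single value in {0, 1, 2}")
  if (pi < 0 || pi > 1) stop("pi must lie in [0, 1]")
  if (abs(alpha) > ALPHA_BOUND + 1e-12)
    stop("alpha must lie in [-", ALPHA_BOUND, ", ", ALPHA_BOUND, "]")
  a <- switch(as.character(dam_genotype), "0" = 0, "1" = 0.5 + alpha, "2" = 1)
  c(p0 = (1 - a) * (1 - pi),
    p1 = a * (1 - pi) + (1 - a) * pi,
    p2 = a * pi)
}

#' Tabulate per-SNP transmission counts
#'
#' Reduces one SNP to its sufficient statistics: a 3 x 3 x 2 array of family
#' counts indexed by dam genotype (0/1/2), offspring genotype (0/1/2) and
#' sire variety (E/R). Only complete, Mendelian-compatible dam-offspring
#' pairs are counted; pairs where either member is missing are dropped and
#' incompatible pairs (dam 2 with offspring 0, dam 0 with offspring 2) are
#' excluded and reported in the `"incompatible"` attribute, since they have
#' zero probability under the model and indicate genotyping error.
#'
#' @param table a `genotype_table`.
#' @param families a `family_set`.
#' @param snp SNP identifier or row index.
#' @return Integer array of dimension `c(3, 3, 2)` with dimnames
#'   `dam` (0:2), `off` (0:2), `sire` (E, R), and attribute `incompatible`:
#'   a data frame of excluded pairs (`offspring_id`, `dam_geno`, `off_geno`).
#' @export
transmission_counts <- function(table, families, snp) {
  if (is.character(snp)) snp <- match(snp, table$map$snp_id)
  row <- table$geno[snp, ]
  tabulate_transmissions(row[match(families$dam_id, colnames(table$geno))],
                         row[match(families$offspring_id,
                                   colnames(table$geno))],
                         families$sire_variety,
                         families$offspring_id)
}

#' @rdname transmission_counts
#' @param dam_codes,off_codes,sire_variety aligned per-family vectors of dam
#'   genotype, offspring genotype and sire variety (`"E"`/`"R"`).
#' @param offspring_id optional per-family identifiers used when reporting
#'   incompatible pairs.
#' @export
tabulate_transmissions <- function(dam_codes, off_codes, sire_variety,
                                   offspring_id = NULL) {
  n <- array(0L, dim = c(3L, 3L, 2L),
             dimnames = list(dam = 0:2, off = 0:2, sire = c("E", "R")))
  complete <- !is.na(dam_codes) & !is.na(off_codes)
  incompat <- complete &
    ((dam_codes == 2L & off_codes == 0L) |
     (dam_codes == 0L & off_codes == 2L))
  use <- complete & !incompat
  if (any(use)) {
    tab <- table(factor(dam_codes[use], levels = 0:2),
                 factor(off_codes[use], levels = 0:2),
                 factor(sire_variety[use], levels = c("E", "R")))
    n[] <- as.integer(tab)
  }
  if (is.null(offspring_id)) offspring_id <- as.character(seq_along(dam_codes))
  attr(n, "incompatible") <- data.frame(
    offspring_id = offspring_id[incompat],
    dam_geno = dam_codes[incompat],
    off_geno = off_codes[incompat],
    stringsAsFactors = FALSE
  )
  n
}

#' Transmission log-likelihood
#'
#' The log-likelihood of a table of transmission counts:
#' \deqn{\ln L = \sum_{d,o,s} n_{dos} \ln p_o(d, \alpha, \pi_s)}
#' where the cell probabilities come from [offspring_probs()] with the sire
#' frequency of the family's sire variety. Empty cells contribute zero even
#' where the cell probability is zero; a non-empty cell with zero
#' probability yields `-Inf`.
#'
#' @param counts 3 x 3 x 2 array from [transmission_counts()].
#' @param alpha distortion parameter.
#' @param pi_E,pi_R sire A1 frequencies for varieties E and R. `NA` is
#'   allowed for a variety with no counted families.
#' @return The log-likelihood (<= 0).
#' @export
trd_loglik <- function(counts, alpha, pi_E, pi_R) {
  a <- 0.5 + alpha
  ll <- 0
  pis <- c(pi_E, pi_R)
  for (s in 1:2) {
    ns <- counts[, , s]
    if (all(ns == 0L)) next
    pi <- pis[s]
    if (is.na(pi))
      stop("families of sire variety ", c("E", "R")[s],
           " are present but its pi is NA")
    p <- rbind(c(1 - pi, pi, 0),
               c((1 - a) * (1 - pi), a * (1 - pi) + (1 - a) * pi, a * pi),
               c(0, 1 - pi, pi))
    pos <- ns > 0L
    if (any(p[pos] <= 0)) return(-Inf)
    ll <- ll + sum(ns[pos] * log(p[pos]))
  }
  ll
}

# Flatten one variety's counts for the fast fit path:
# returns the 9 counts as a list of named scalars used by .ll_variety/.grad.
.variety_counts <- function(counts, s) {
  ns <- counts[, , s]
  list(n00 = ns[1, 1], n01 = ns[1, 2],
       n10 = ns[2, 1], n11 = ns[2, 2], n12 = ns[2, 3],
       n21 = ns[3, 2], n22 = ns[3, 3],
       total = sum(ns), het = sum(ns[2, ]))
}

# log-likelihood contribution of one sire variety (a = 0.5 + alpha)
.ll_variety <- function(v, a, pi) {
  ll <- 0
  p0 <- (1 - a) * (1 - pi)
  p1 <- a * (1 - pi) + (1 - a) * pi
  p2 <- a * pi
  if (v$n10 > 0) { if (p0 <= 0) return(-Inf); ll <- ll + v$n10 * log(p0) }
  if (v$n11 > 0) { if (p1 <= 0) return(-Inf); ll <- ll + v$n11 * log(p1) }
  if (v$n12 > 0) { if (p2 <= 0) return(-Inf); ll <- ll + v$n12 * log(p2) }
  if (v$n00 + v$n21 > 0) {
    if (1 - pi <= 0) return(-Inf)
    ll <- ll + (v$n00 + v$n21) * log(1 - pi)
  }
  if (v$n01 + v$n22 > 0) {
    if (pi <= 0) return(-Inf)
    ll <- ll + (v$n01 + v$n22) * log(pi)
  }
  ll
}

# gradient (d/da, d/dpi) of one variety's contribution
.grad_variety <- function(v, a, pi) {
  ga <- 0
  gp <- 0
  p0 <- (1 - a) * (1 - pi)
  p1 <- a * (1 - pi) + (1 - a) * pi
  p2 <- a * pi
  if (v$n10 > 0) { ga <- ga - v$n10 * (1 - pi) / p0
                   gp <- gp - v$n10 * (1 - a) / p0 }
  if (v$n11 > 0) { ga <- ga + v$n11 * (1 - 2 * pi) / p1
                   gp <- gp + v$n11 * (1 - 2 * a) / p1 }
  if (v$n12 > 0) { ga <- ga + v$n12 * pi / p2
                   gp <- gp + v$n12 * a / p2 }
  if (v$n00 + v$n21 > 0) gp <- gp - (v$n00 + v$n21) / (1 - pi)
  if (v$n01 + v$n22 > 0) gp <- gp + (v$n01 + v$n22) / pi
  c(ga, gp)
}
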