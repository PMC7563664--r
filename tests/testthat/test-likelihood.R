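test_that("offspring probabilities match the closed forms", {
  expect_equal(offspring_probs(1, 0, 0.5),
               c(p0 = 0.25, p1 = 0.5, p2 = 0.25), tolerance = 1e-12)
  # homozygous A1A1 dam: (0, 1 - pi, pi) for any alpha
  expect_equal(offspring_probs(2, 0.3, 0.3),
               c(p0 = 0, p1 = 0.7, p2 = 0.3), tolerance = 1e-12)
  expect_equal(offspring_probs(1, -0.25, 0.4),
               c(p0 = 0.45, p1 = 0.45, p2 = 0.10), tolerance = 1e-12)
  expect_error(offspring_probs(3, 0, 0.5), "dam_genotype")
  expect_error(offspring_probs(1, 0, 1.2), "pi")
})

test_that("offspring probabilities sum to one over a dense parameter grid", {
  for (d in 0:2)
    for (a in seq(-0.495, 0.495, by = 0.045))
      for (p in seq(0, 1, by = 0.1))
        expect_equal(sum(offspring_probs(d, a, p)), 1, tolerance = 1e-12)
})

test_that("transmission counts tally complete compatible pairs only", {
  n <- tabulate_transmissions(rep(1L, 3), rep(2L, 3), rep("E", 3))
  expect_equal(n["1", "2", "E"], 3L)
  expect_equal(sum(n), 3L)

  # incompatible pair excluded and logged
  n2 <- tabulate_transmissions(c(2L, 1L), c(0L, 1L), c("E", "E"),
                               offspring_id = c("kid1", "kid2"))
  expect_equal(sum(n2), 1L)
  expect_equal(attr(n2, "incompatible")$offspring_id, "kid1")

  # mixed fixture of 6 families matches a hand tally
  dams <- c(1L, 1L, 2L, 0L, NA, 1L)
  offs <- c(2L, 1L, 1L, 0L, 1L, 2L)
  sire <- c("E", "E", "R", "R", "E", "R")
  n3 <- tabulate_transmissions(dams, offs, sire)
  expect_equal(sum(n3), 5L)  # the dam-missing family is dropped
  expect_equal(n3["1", "2", "E"], 1L)
  expect_equal(n3["1", "1", "E"], 1L)
  expect_equal(n3["2", "1", "R"], 1L)
  expect_equal(n3["0", "0", "R"], 1L)
  expect_equal(n3["1", "2", "R"], 1L)
})

test_that("the log-likelihood matches hand evaluation", {
  n <- make_counts(list(list(1, 2, "E", 3), list(1, 1, "E", 4),
                        list(1, 0, "E", 3)))
  expect_equal(trd_loglik(n, 0, 0.5, 0.5), 6 * log(0.25) + 4 * log(0.5),
               tolerance = 1e-12)
  empty <- make_counts(list())
  expect_equal(trd_loglik(empty, 0.2, 0.3, 0.7), 0)
  # a non-empty cell with zero probability yields -Inf
  n2 <- make_counts(list(list(2, 2, "E", 5)))
  expect_identical(trd_loglik(n2, 0, 0, 0.5), -Inf)
})

test_that("label swap (alpha, pi) -> (-alpha, 1 - pi) leaves lnL invariant", {
  set.seed(101)
  for (rep in 1:30) {
    n <- random_counts(50)
    a <- runif(1, -0.49, 0.49)
    pE <- runif(1, 0.01, 0.99)
    pR <- runif(1, 0.01, 0.99)
    expect_equal(trd_loglik(n, a, pE, pR),
                 trd_loglik(swap_counts(n), -a, 1 - pE, 1 - pR),
                 tolerance = 1e-10)
  }
})

test_that("null fit recovers the binomial MLE for homozygous-dam designs", {
  n <- make_counts(list(list(2, 2, "E", 30), list(2, 1, "E", 70)))
  fit <- fit_trd_null(n)
  expect_equal(fit$pi_E, 0.30, tolerance = 1e-6)
  expect_true(is.na(fit$pi_R))
  # mirror case with A2A2 dams: offspring A1 copies all paternal
  n2 <- make_counts(list(list(0, 1, "E", 12), list(0, 0, "E", 28)))
  expect_equal(fit_trd_null(n2)$pi_E, 0.30, tolerance = 1e-6)
  # mixed dam genotypes: matches a 1-D grid search
  set.seed(5)
  n3 <- random_counts(80)
  fit3 <- fit_trd_null(n3)
  pis <- seq(0.001, 0.999, by = 0.001)
  for (s in 1:2) {
    ll <- vapply(pis, function(p)
      trd_loglik(array(c(n3[, , s], 0 * n3[, , s]), dim = c(3, 3, 2)),
                 0, p, 0.5), numeric(1))
    pi_hat <- if (s == 1) fit3$pi_E else fit3$pi_R
    expect_equal(pi_hat, pis[which.max(ll)], tolerance = 2e-3)
  }
})

test_that("full fit attains the exhaustive grid-search maximum", {
  set.seed(202)
  for (rep in 1:5) {
    n <- random_counts(60)
    fit <- fit_trd_full(n)
    expect_gte(fit$lnL, grid_loglik_max(n, 0.005, 0.005) - 1e-6)
    expect_true(fit$converged)
    expect_lte(abs(fit$alpha), 0.495 + 1e-12)
  }
})

test_that("full fit never falls below the null fit", {
  set.seed(303)
  for (rep in 1:25) {
    n <- random_counts(sample(10:80, 1))
    full <- fit_trd_full(n)
    null <- fit_trd_null(n)
    if (full$estimable && null$estimable)
      expect_gte(full$lnL, null$lnL - 1e-9)
  }
})

test_that("full fit recovers a null alpha and hits the boundary when forced", {
  set.seed(404)
  n <- model_counts(1500, 500, alpha = 0, pi_E = 0.6, pi_R = 0.4)
  fit <- fit_trd_full(n)
  expect_lt(abs(fit$alpha), 0.05)
  expect_lt(abs(fit$pi_E - 0.6), 0.05)
  expect_lt(abs(fit$pi_R - 0.4), 0.05)

  # every het-dam offspring carries two A1 copies: alpha and pi at the bounds
  nb <- make_counts(list(list(1, 2, "E", 50)))
  fb <- fit_trd_full(nb)
  expect_lt(abs(fb$alpha - 0.495), 1e-3)
  expect_gt(fb$pi_E, 0.99)

  # no heterozygous-dam family: alpha is not estimable
  nh <- make_counts(list(list(2, 2, "E", 10), list(2, 1, "E", 10)))
  fh <- fit_trd_full(nh)
  expect_false(fh$estimable)
})

test_that("the likelihood ratio test maps statistics to chi-square tails", {
  n <- model_counts(100, 30, alpha = -0.3, pi_E = 0.5, pi_R = 0.5)
  full <- fit_trd_full(n)
  null <- fit_trd_null(n)
  test <- lrt_pvalue(full, null)
  expect_equal(test$statistic, 2 * (full$lnL - null$lnL), tolerance = 1e-12)
  expect_equal(test$p_value, pchisq(test$statistic, 1, lower.tail = FALSE))
  # identical fits give statistic 0 and p = 1
  same <- lrt_pvalue(null, null)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # landmark chi-square(1) quantiles
  expect_lt(abs(pchisq(3.841, 1, lower.tail = FALSE) - 0.05), 1e-3)
  expect_lt(abs(pchisq(10.83, 1, lower.tail = FALSE) - 0.001), 1e-4)
  # non-estimable input propagates missing test fields
  ne <- fit_trd_full(make_counts(list()))
  expect_true(is.na(lrt_pvalue(ne, null)$p_value))
})

test_that("median LRT grows with the number of informative families", {
  # dam genotypes are mixed: homozygous-dam families anchor the sire
  # frequency, against which the heterozygous-dam transmissions testify
  set.seed(505)
  med <- vapply(c(25, 100, 400), function(nfam) {
    stats <- vapply(1:30, function(r) {
      counts <- model_counts(round(0.75 * nfam), nfam - round(0.75 * nfam),
                             alpha = -0.3, pi_E = 0.5, pi_R = 0.5)
      lrt_pvalue(fit_trd_full(counts), fit_trd_null(counts))$statistic
    }, numeric(1))
    median(stats)
  }, numeric(1))
  expect_true(all(diff(med) > 0))
})

test_that("estimator error shrinks with sample size", {
  set.seed(606)
  mae <- vapply(c(50, 400), function(nfam) {
    errs <- vapply(1:40, function(r) {
      n <- model_counts(round(0.75 * nfam), nfam - round(0.75 * nfam),
                        alpha = -0.2, pi_E = 0.6, pi_R = 0.4)
      fit <- fit_trd_full(n)
      abs(fit$alpha + 0.2)
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_lt(mae[2], mae[1])
})

test_that("null LRT statistics follow the chi-square(1) law", {
  # tested in the asymptotic regime (1000 families): the chi-square
  # reference is a large-sample law, and at a few hundred families the
  # usual O(1/n) likelihood-ratio inflation is still visible
  set.seed(707)
  n_sims <- 2000
  stats <- vapply(seq_len(n_sims), function(r) {
    n <- model_counts(750, 250, alpha = 0, pi_E = 0.5, pi_R = 0.5)
    lrt_pvalue(fit_trd_full(n), fit_trd_null(n))$statistic
  }, numeric(1))
  pos <- stats[stats > 1e-8]
  # clipping only removes (numerically) zero statistics; the positive part
  # must not be stochastically larger than chi-square(1), which is the
  # anti-conservative direction
  ks <- suppressWarnings(
    stats::ks.test(pos, function(q) pchisq(q, df = 1), alternative = "less")
  )
  expect_gt(ks$p.value, 0.01)
})
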