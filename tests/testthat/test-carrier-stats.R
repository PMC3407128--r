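test_that("carrier frequency is k/n with domain checks", {
  expect_equal(carrier_frequency(10, 46), 10 / 46)
  expect_identical(carrier_frequency(0, 46), 0)
  expect_identical(carrier_frequency(46, 46), 1)
  expect_error(carrier_frequency(1, 0), "n must be")
  expect_error(carrier_frequency(5, 4), "0 <= k <= n")
})

test_that("the Wald interval for 10/46 renders 10-34% and the score/exact intervals do not", {
  ci <- wald_ci(10, 46, 0.95)
  expect_equal(unname(ci["low"]), 10 / 46 - stats::qnorm(0.975) *
                 sqrt((10 / 46) * (36 / 46) / 46), tolerance = 1e-12)
  expect_identical(round(100 * unname(ci)), c(10, 34))
  # negative controls documenting the method choice
  wilson <- binom_ci(10, 46, 0.95, method = "wilson")
  exact <- binom_ci(10, 46, 0.95, method = "exact")
  expect_false(identical(round(100 * unname(wilson)), c(10, 34)))
  expect_false(identical(round(100 * unname(exact)), c(10, 34)))
  # clipping at zero
  expect_identical(unname(wald_ci(0, 46)["low"]), 0)
  expect_error(wald_ci(10, 46, 1.2), "confidence")
})

test_that("CI width shrinks with n at fixed proportion", {
  widths <- vapply(c(46, 100, 500, 2000), function(n) {
    ci <- wald_ci(round(0.22 * n), n)
    unname(ci["high"] - ci["low"])
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("Wald coverage at n=46 is close to nominal and matches exact binomial enumeration", {
  n <- 46L
  exact_coverage <- function(p) {
    k <- 0:n
    covers <- vapply(k, function(ki) {
      ci <- wald_ci(ki, n)
      ci["low"] <= p && p <= ci["high"]
    }, logical(1))
    sum(stats::dbinom(k, n, p) * covers)
  }
  set.seed(314)
  for (p in c(0.05, 0.22, 0.4)) {
    draws <- stats::rbinom(2000L, n, p)
    emp <- mean(vapply(draws, function(ki) {
      ci <- wald_ci(ki, n)
      ci["low"] <= p && p <= ci["high"]
    }, logical(1)))
    ex <- exact_coverage(p)
    mc_se <- sqrt(ex * (1 - ex) / 2000)
    expect_lt(abs(emp - ex), 3.5 * mc_se)
    expect_lt(abs(emp - 0.95), 0.05)
  }
})

test_that("null mutation rate uses per-individual counts when available", {
  expect_equal(null_mutation_rate(10, 46), 10 / 46)
  counts <- c(rep(0L, 36L), rep(1L, 9L), 2L)
  expect_equal(null_mutation_rate(10, 46, per_individual_counts = counts),
               11 / 46)
  expect_identical(null_mutation_rate(0, 46), 0)
  scr <- cached_fixture_screen()
  expect_equal(null_mutation_rate(scr), 10 / 46)
})

test_that("the missense and unknown-gene extrapolations reproduce the one-in-2.5 and one-in-1.7 figures", {
  m <- 10 / 46
  e1 <- extrapolate_one_in_x(m, include_unknown_genes = FALSE)
  expect_equal(e1$inflated_rate, m * 1.87, tolerance = 1e-12)
  expect_identical(e1$one_in_x_display, 2.5)
  e2 <- extrapolate_one_in_x(m, include_unknown_genes = TRUE)
  expect_equal(e2$inflated_rate, m * 1.87 / 0.7, tolerance = 1e-12)
  expect_identical(e2$one_in_x_display, 1.7)
  # null-only reciprocal: one in 4-5 individuals
  e0 <- extrapolate_one_in_x(m, null_to_missense_ratio = 0)
  expect_identical(e0$one_in_x_display, 4.6)
  # the Poisson-carrier convention deliberately differs
  ep <- extrapolate_one_in_x(m, convention = "poisson_carrier")
  expect_gt(ep$one_in_x, e1$one_in_x)
  expect_error(extrapolate_one_in_x(0), "positive rate")
})

test_that("one_in_x falls as the missense ratio grows and rises with the known-gene fraction", {
  m <- 10 / 46
  ratios <- seq(0, 2, by = 0.25)
  xs <- vapply(ratios, function(r)
    extrapolate_one_in_x(m, null_to_missense_ratio = r)$one_in_x, numeric(1))
  expect_true(all(diff(xs) < 0))
  fracs <- seq(0.3, 1, by = 0.1)
  xs2 <- vapply(fracs, function(f)
    extrapolate_one_in_x(m, known_gene_case_fraction = f,
                         include_unknown_genes = TRUE)$one_in_x, numeric(1))
  expect_true(all(diff(xs2) > 0))
})

test_that("consanguinity risk follows inbreeding-load arithmetic, validated by genotype enumeration and a mating simulation", {
  # F = 0 limit: random-mating value sum(q^2)
  q <- c(0.001, 0.002, 0.0005)
  r0 <- consanguinity_risk(q, inbreeding = 0)
  expect_equal(r0$p_affected, sum(q^2), tolerance = 1e-15)
  expect_equal(r0$risk_ratio_vs_panmixia, 1)

  # single gene, first-cousin mating: closed form against direct
  # enumeration over the IBD decomposition
  r <- consanguinity_risk(0.001, inbreeding = 1 / 16)
  enum <- (1 / 16) * 0.001 + (15 / 16) * 0.001^2
  expect_equal(r$p_affected, enum, tolerance = 1e-15)
  expect_equal(r$p_affected, 6.34375e-05, tolerance = 1e-9)
  expect_equal(r$risk_ratio_vs_panmixia, enum / 1e-6, tolerance = 1e-9)
  expect_gt(r$risk_ratio_vs_panmixia, 60)

  # 106 genes with the fixture aggregate spread evenly, F = 0: compare
  # sum(q_i^2) against a direct Monte-Carlo mating simulation
  qs <- rep(0.22 / (2 * 106), 106)
  expected <- consanguinity_risk(qs, inbreeding = 0)$p_affected
  set.seed(271)
  n_matings <- 1e6
  affected <- sum(stats::rbinom(length(qs), n_matings, qs^2))
  emp <- affected / n_matings
  mc_se <- sqrt(expected / n_matings)
  expect_lt(abs(emp - expected), 4 * mc_se)

  # risk ratio exceeds 1 whenever F > 0 and blows up as alleles rarefy
  expect_gt(consanguinity_risk(0.01, 1 / 16)$risk_ratio_vs_panmixia, 1)
  rr <- vapply(c(1e-2, 1e-3, 1e-4, 1e-5), function(qi)
    consanguinity_risk(qi, 1 / 16)$risk_ratio_vs_panmixia, numeric(1))
  expect_true(all(diff(rr) > 0))
  expect_error(consanguinity_risk(0.7, 0), "0, 0.5")
  expect_error(consanguinity_risk(0.001, 1.5), "inbreeding")
})

test_that("simulated cohorts at several true carrier frequencies keep Wald coverage near nominal", {
  set.seed(159)
  n <- 46L
  for (p in c(0.05, 0.22, 0.4)) {
    draws <- stats::rbinom(2000L, n, p)
    emp <- mean(vapply(draws, function(ki) {
      ci <- wald_ci(ki, n)
      ci["low"] <= p && p <= ci["high"]
    }, logical(1)))
    expect_gt(emp, 0.88)
    expect_lt(emp, 0.99)
  }
})
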