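test_that("allele_frequency divides counts by the sampled total", {
  expect_equal(allele_frequency(make_counts(A = 3, B = 3), "A"), 0.5)
  expect_equal(allele_frequency(make_counts(A = 6, B = 0), "B"), 0)
  expect_equal(allele_frequency(make_counts(`80` = 47, `83` = 139), "80"),
               47 / 186)
  expect_error(allele_frequency(make_counts(A = 0, B = 0), "A"),
               class = "temposel_validation_error")
})

test_that("the G statistic matches a direct evaluation of 2*sum O log(O/E)", {
  a <- make_counts(A = 60, B = 40)
  b <- make_counts(A = 40, B = 60)
  out <- g_test(a, b)
  # independent hand evaluation on the 2x2 table
  O <- c(60, 40, 40, 60)
  E <- c(50, 50, 50, 50)
  expect_equal(out$g_stat, 2 * sum(O * log(O / E)), tolerance = 1e-12)
  expect_equal(out$g_stat, 8.0542, tolerance = 1e-4)
  expect_equal(out$df, 1L)

  eq <- g_test(a, a)
  expect_equal(eq$g_stat, 0)
  expect_equal(eq$p_value, 1)
})

test_that("zero cells follow the 0*log(0) convention and df counts pooled alleles", {
  # allele C present in only one sample: kept, G finite, df = 2
  a <- make_counts(A = 5, B = 5, C = 0)
  b <- make_counts(A = 4, B = 4, C = 2)
  out <- g_test(a, b)
  expect_true(is.finite(out$g_stat))
  expect_equal(out$df, 2L)
  # allele C absent from both samples: dropped, df = 1
  out2 <- g_test(make_counts(A = 5, B = 5, C = 0),
                 make_counts(A = 6, B = 4, C = 0))
  expect_equal(out2$df, 1L)
  expect_error(g_test(make_counts(A = 0, B = 0), a),
               class = "temposel_validation_error")
})

test_that("the G-test p-value is calibrated under a common frequency", {
  set.seed(42)
  n_rep <- 2000
  x1 <- rbinom(n_rep, 100, 0.3)
  x2 <- rbinom(n_rep, 100, 0.3)
  p <- vapply(seq_len(n_rep), function(i) {
    g_test(make_counts(A = x1[i], B = 100 - x1[i]),
           make_counts(A = x2[i], B = 100 - x2[i]))$p_value
  }, numeric(1))
  expect_gte(mean(p <= 0.05), 0.03)
  expect_lte(mean(p <= 0.05), 0.07)
})

test_that("frequency change is the signed focal-allele difference, seed minus seedling", {
  loci <- tiny_loci()
  pair <- make_pair(loci, focal = list(
    GeneA = list(seedling = c(25, 50, 25), seed = c(36, 45, 19))
  ))
  # seedling focal freq 0.500, seed (2*36+45)/200 = 0.585
  out <- frequency_change(pair, "GeneA")
  expect_equal(out$delta, 0.085)
  expect_equal(out$site, "X")

  same <- make_pair(loci, focal = list(
    GeneA = list(seedling = c(25, 50, 25), seed = c(25, 50, 25))
  ))
  out2 <- frequency_change(same, "GeneA")
  expect_equal(out2$delta, 0)
  expect_equal(out2$p_value, 1)

  expect_error(frequency_change(pair, "MsatM"),
               class = "temposel_validation_error")
})

test_that("swapping the two stages negates delta", {
  set.seed(5)
  for (i in 1:20) {
    g1 <- as.vector(rmultinom(1, 100, c(0.3, 0.5, 0.2)))
    g2 <- as.vector(rmultinom(1, 120, c(0.25, 0.5, 0.25)))
    a <- make_pair(tiny_loci(), focal = list(GeneA = list(seedling = g1, seed = g2)))
    b <- make_pair(tiny_loci(), focal = list(GeneA = list(seedling = g2, seed = g1)))
    expect_equal(frequency_change(a, "GeneA")$delta,
                 -frequency_change(b, "GeneA")$delta)
  }
})

test_that("the multiplicity probability is the exact binomial upper tail", {
  expect_equal(binomial_multiplicity(17, 0, 0.05), 1)
  expect_equal(binomial_multiplicity(17, 17, 1), 1)
  # independent term-by-term summation oracle
  tail_oracle <- function(n, k, a) {
    sum(choose(n, k:n) * a^(k:n) * (1 - a)^(n - (k:n)))
  }
  expect_equal(binomial_multiplicity(17, 2, 0.05), tail_oracle(17, 2, 0.05),
               tolerance = 1e-12)
  expect_equal(binomial_multiplicity(17, 2, 0.05), 0.20777, tolerance = 1e-4)
  for (k in 0:17) {
    expect_equal(binomial_multiplicity(17, k, 0.05), tail_oracle(17, k, 0.05),
                 tolerance = 1e-12)
  }
  # non-increasing in k
  vals <- vapply(0:17, binomial_multiplicity, numeric(1),
                 n_tests = 17, alpha = 0.05)
  expect_true(all(diff(vals) <= 1e-15))
  expect_error(binomial_multiplicity(17, 18, 0.05),
               class = "temposel_validation_error")
})

test_that("gene-flow effect is m * delta_p", {
  expect_equal(migration_effect(0.01, 0.24), 0.0024)
  expect_equal(migration_effect(0, 0.24), 0)
  expect_equal(migration_effect(0.01, 0), 0)
  expect_error(migration_effect(1.5, 0), class = "temposel_validation_error")
  expect_error(migration_effect(0.5, 2), class = "temposel_validation_error")
})
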