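test_that("post-selection genotype frequencies match the closed form", {
  # direct evaluation of each printed expression, independent of the
  # implementation's shared denominator code
  q <- 0.3; s <- 0.44; h <- 0
  D <- 2 * h * s * q * (q - 1) + 1 - s * q^2
  expect_equal(D, 0.9604)
  f <- genotype_freqs_after_selection(q, s, h)
  expect_equal(f$AA, (1 - q)^2 / D, tolerance = 1e-14)
  expect_equal(f$Aa, 2 * (1 - q) * q * (1 - h * s) / D, tolerance = 1e-14)
  expect_equal(f$aa, q^2 * (1 - s) / D, tolerance = 1e-14)

  # no-selection limit: Hardy-Weinberg
  hw <- genotype_freqs_after_selection(0.37, 0, 0.8)
  expect_equal(unlist(hw), c(AA = 0.63^2, Aa = 2 * 0.63 * 0.37, aa = 0.37^2),
               tolerance = 1e-14)

  # lethal recessive at q = 0.5
  lethal <- genotype_freqs_after_selection(0.5, 1, 0)
  expect_equal(unlist(lethal), c(AA = 1 / 3, Aa = 2 / 3, aa = 0),
               tolerance = 1e-14)

  # frequencies sum to one over random admissible parameters
  set.seed(1)
  q <- runif(1e4); s <- runif(1e4); h <- runif(1e4)
  D <- 2 * h * s * q * (q - 1) + 1 - s * q^2
  keep <- D > 1e-6
  f <- genotype_freqs_after_selection(q[keep], s[keep], h[keep])
  expect_lt(max(abs(f$AA + f$Aa + f$aa - 1)), 1e-12)

  expect_error(genotype_freqs_after_selection(1, 1, 0),
               class = "temposel_validation_error")
  expect_error(genotype_freqs_after_selection(0.5, 1.2, 0),
               class = "temposel_validation_error")
})

test_that("offspring sampling is deterministic and mean-faithful", {
  cfg <- abc_config(Ne = 1e6, Ns = 1e4)
  set.seed(8)
  a <- simulate_offspring_sample(q = 0.5, s = 0, h = 0, cfg = cfg)
  set.seed(8)
  b <- simulate_offspring_sample(q = 0.5, s = 0, h = 0, cfg = cfg)
  expect_identical(a, b)
  expect_equal(sum(a), 1e4)
  # HWE limit: no selection, negligible drift and large sample
  expect_equal(unname(a / 1e4), c(0.25, 0.5, 0.25), tolerance = 0.02)

  # mean over replicates matches the analytic post-selection frequencies
  q <- 0.4; s <- 0.6; h <- 0.3
  f <- unlist(genotype_freqs_after_selection(q, s, h))
  cfg2 <- abc_config(Ne = 300, Ns = 100)
  set.seed(9)
  n_rep <- 1e4
  sims <- matrix(0, 3, n_rep)
  for (i in seq_len(n_rep)) {
    sims[, i] <- simulate_offspring_sample(q, s, h, cfg2)
  }
  props <- sims / 100
  se <- sqrt(apply(props, 1, stats::var) / n_rep)
  expect_true(all(abs(rowMeans(props) - f) < 3 * se + 1e-9))

  expect_error(abc_config(Ne = 100, Ns = 200),
               class = "temposel_validation_error")
})

test_that("the ABC posterior recovers strong selection and stays low for neutral data", {
  # observed counts are the rounded expectation at q=0.5, s=0.5, h=0
  f <- unlist(genotype_freqs_after_selection(0.5, 0.5, 0))
  expect_equal(round(100 * f), c(AA = 29, Aa = 57, aa = 14))
  cfg <- abc_config(Ne = 300, Ns = 100, n_target_accepted = 800,
                    max_sims = 3e5, rng_seed = 12)
  post <- abc_estimate_s(c(29, 57, 14), q = 0.5, h = 0, cfg = cfg)
  expect_gt(post$median, 0.3)
  expect_lt(post$median, 0.7)
  expect_true(post$ci95[1] <= post$median && post$median <= post$ci95[2])
  expect_true(all(post$accepted_s >= 0 & post$accepted_s <= 1))

  # Hardy-Weinberg counts carry no signal of selection
  cfg2 <- abc_config(Ne = 1e5, Ns = 100, n_target_accepted = 800,
                     max_sims = 3e5, rng_seed = 13)
  neutral <- abc_estimate_s(c(25, 50, 25), q = 0.5, h = 0, cfg = cfg2)
  expect_lt(neutral$median, 0.2)

  # determinism
  post2 <- abc_estimate_s(c(29, 57, 14), q = 0.5, h = 0, cfg = cfg)
  expect_identical(post$accepted_s, post2$accepted_s)

  expect_error(abc_estimate_s(c(29, 57, 14), q = 0, h = 0, cfg = cfg),
               class = "temposel_validation_error")
  expect_error(abc_estimate_s(c(0, 0, 0), q = 0.5, h = 0, cfg = cfg),
               class = "temposel_validation_error")
})

test_that("the posterior median rises with the deficit of disfavoured homozygotes", {
  cfg <- function(seed) abc_config(Ne = 300, Ns = 100,
                                   n_target_accepted = 600,
                                   max_sims = 3e5, rng_seed = seed)
  m1 <- abc_estimate_s(c(25, 50, 25), 0.5, 0, cfg(21))$median
  m3 <- abc_estimate_s(c(35, 57, 8), 0.5, 0, cfg(23))$median
  expect_gt(m3, m1)
})

test_that("the goodness-of-fit validation accepts matching counts and rejects gross misfits", {
  cfg <- abc_config(Ne = 300, Ns = 100, rng_seed = 31)
  ok <- validate_fit(0.5, c(29, 57, 14), q = 0.5, h = 0, cfg = cfg)
  expect_gt(ok$p_value, 0.9)
  expect_equal(ok$df, 2L)
  bad <- validate_fit(0.5, c(100, 0, 0), q = 0.5, h = 0, cfg = cfg)
  expect_lt(bad$p_value, 0.01)
})

test_that("the recovery grid is the quoted 108-cell design", {
  g <- power_grid()
  expect_equal(nrow(g), 108L)
  expect_setequal(unique(g$s_true),
                  c(0.02, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5, 0.7, 0.9))
  expect_setequal(unique(g$Ne), c(1e5, 300))
  expect_setequal(unique(g$h), c(0, 1))
  expect_true(all(g$n <= g$Ne)) # census cells run with n = Ne
  expect_true(any(g$n == g$Ne))
})

test_that("power_study runs a grid subset and reports posterior summaries", {
  sub <- power_grid() |> dplyr::filter(s_true %in% c(0.5, 0.9), Ne == 300,
                                       n == 100, h == 0)
  out <- power_study(sub, n_target_accepted = 200, max_sims = 1e5,
                     rng_seed = 99)
  expect_equal(nrow(out), 2L)
  expect_true(all(out$ci_low <= out$median_s_hat &
                    out$median_s_hat <= out$ci_high))
  expect_true(all(out$n_accepted > 0))
})
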