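test_that("theta behaves at the fixed points of the estimator", {
  a <- make_counts(A = 50, B = 50)
  expect_lte(wc_theta_biallelic(a, a, "A"), 0) # no excess differentiation

  fixed1 <- make_counts(A = 100, B = 0)
  fixed2 <- make_counts(A = 0, B = 100)
  expect_equal(wc_theta_biallelic(fixed1, fixed2, "A"), 1)

  # relabelling the two alleles of a biallelic locus leaves theta unchanged
  c1 <- make_counts(A = 60, B = 140)
  c2 <- make_counts(A = 90, B = 110)
  expect_equal(wc_theta_biallelic(c1, c2, "A"),
               wc_theta_biallelic(c1, c2, "B"), tolerance = 1e-12)

  mono <- make_counts(A = 100, B = 0)
  expect_error(wc_theta_biallelic(mono, mono, "A"),
               class = "temposel_monomorphic_error")
  expect_error(wc_theta_biallelic(c1, c2, "Z"),
               class = "temposel_validation_error")
})

test_that("the simulated null is deterministic and centred on the drift expectation", {
  cfg <- drift_sampling_config(Ne = 500, n1 = 80, n2 = 90, reps = 2000,
                               rng_seed = 3)
  a <- simulate_null(cfg)
  b <- simulate_null(cfg)
  expect_identical(a$values, b$values)
  expect_length(a$values, 2000L)

  # no drift, huge samples: theta concentrates at 0
  big <- simulate_null(drift_sampling_config(1e6, 1e6, 1e6, reps = 1e4,
                                             rng_seed = 4))
  expect_lt(abs(mean(big$values)), 1e-3)

  # one generation of drift at Ne=160 with samples 93/144: the two-sample
  # estimator splits the single-branch drift variance between the samples,
  # so the mean sits near 1/(4*Ne) = 0.0016
  drift <- simulate_null(drift_sampling_config(160, 93, 144, reps = 1e5,
                                               rng_seed = 5))
  expect_gt(mean(drift$values), 0.0012)
  expect_lt(mean(drift$values), 0.0020)

  expect_error(drift_sampling_config(100, 200, 100),
               class = "temposel_validation_error")
})

test_that("the empirical null holds one theta per segregating microsatellite allele", {
  loci <- tiny_loci()
  # a microsatellite with two segregating alleles: the two allele-vs-rest
  # theta values are identical (complementary split)
  pair <- make_pair(loci, msat = list(
    MsatM = list(seedling = c(`150` = 120, `153` = 80, `156` = 0),
                 seed = c(`150` = 100, `153` = 100, `156` = 0))
  ))
  null <- empirical_null(pair)
  expect_length(null$values, 2L)
  expect_equal(null$values[1], null$values[2], tolerance = 1e-12)
  expect_equal(null$provenance, "empirical")

  # the empirical null and the direct estimator share one code path
  c1 <- pair_counts(pair, "seedling", "MsatM")
  c2 <- pair_counts(pair, "seed", "MsatM")
  expect_equal(null$values[1], wc_theta_biallelic(c1, c2, "150"))

  mono <- make_pair(loci, msat = list(
    MsatM = list(seedling = c(`150` = 200, `153` = 0, `156` = 0),
                 seed = c(`150` = 200, `153` = 0, `156` = 0))
  ))
  expect_error(empirical_null(mono), class = "temposel_validation_error")
})

test_that("empirical-null size equals the segregating allele count of a synthetic pair", {
  tpl <- study_template(n_sites = 1)
  sim <- simulate_site_year(tpl$params[[1]], tpl$loci, rng_seed = 21)
  null <- empirical_null(sim$pair)
  # independent recount from the aggregated tables
  seg <- sim$pair$alleles |>
    dplyr::filter(locus %in% tpl$loci$locus[tpl$loci$kind == "microsatellite"]) |>
    tidyr::pivot_wider(names_from = stage, values_from = count) |>
    dplyr::group_by(locus) |>
    dplyr::mutate(tot = seedling + seed) |>
    dplyr::filter(tot > 0, tot < sum(tot)) |>
    nrow()
  expect_equal(length(null$values), seg)
})

test_that("outlier p-values follow the rank convention with a resolution floor", {
  null <- structure(list(values = seq(0.001, 0.1, length.out = 100),
                         provenance = "simulated", config = NULL),
                    class = "fst_null")
  expect_equal(outlier_pvalue(-1, null)$p_value, 1)
  top <- outlier_pvalue(0.2, null)
  expect_equal(top$p_value, 0.01)
  expect_true(top$below_resolution)
  med <- outlier_pvalue(stats::median(null$values), null)
  expect_equal(med$p_value, 0.5, tolerance = 0.02)
  # monotone non-increasing in the observed value
  obs <- seq(-0.01, 0.12, length.out = 30)
  ps <- vapply(obs, function(o) outlier_pvalue(o, null)$p_value, numeric(1))
  expect_true(all(diff(ps) <= 0))
  expect_error(
    outlier_pvalue(0.1, structure(list(values = numeric(0)), class = "fst_null")),
    class = "temposel_validation_error"
  )
})

test_that("outlier tests flag strong selection and spare neutral loci", {
  tpl <- study_template(n_sites = 1)
  loci <- tpl$loci

  run_once <- function(s, q0, seed) {
    p <- tpl$params[[1]]
    p$focal$s <- c(s, 0)
    p$focal$q0 <- c(q0, 0.5)
    sim <- simulate_site_year(p, loci, rng_seed = seed)
    run_outlier_tests(sim$pair, ne_lower_bound = 300, reps = 4000,
                      rng_seed = seed + 1)
  }

  # neutral: per focal locus, both p-values exceed 0.05 in the vast
  # majority of runs
  neutral <- unlist(lapply(1:40, function(i) {
    r <- run_once(0, 0.5, 3000 + i)
    r$p_empirical > 0.05 & r$p_simulated > 0.05
  }))
  expect_gte(mean(neutral), 0.8)

  # strong selection at the first focal locus: flagged in the majority
  hits <- vapply(1:40, function(i) {
    r <- run_once(0.9, 0.6, 6000 + i)
    r$p_simulated[r$locus == "PgPHYC"] <= 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.5)

  # empirical and simulated p-values agree closely under neutrality
  r <- run_once(0, 0.5, 77)
  expect_lt(max(abs(r$p_empirical - r$p_simulated)), 0.1)

  sim <- simulate_site_year(tpl$params[[1]], loci, rng_seed = 1)
  expect_error(run_outlier_tests(sim$pair, ne_lower_bound = 50, reps = 100),
               class = "temposel_validation_error")
})
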