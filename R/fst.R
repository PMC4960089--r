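# Temporal F_ST outlier machinery: per-allele two-sample Weir-Cockerham
# theta from allele counts, empirical and Wright-Fisher simulated null
# distributions, and rank-based upper-tail p-values.

# Vectorised two-sample theta on allele counts. x1, x2 are counts of the
# focal allele; m1, m2 the allele totals (2 x individuals). This is the
# haploid-ANOVA (method-of-moments) form: samples are treated as draws of
# alleles, the only form computable from pooled allele counts. The same code
# path scores observed loci, the empirical null and the simulated null.
theta_from_counts <- function(x1, m1, x2, m2) {
  p1 <- x1 / m1
  p2 <- x2 / m2
  N <- m1 + m2
  pbar <- (x1 + x2) / N
  msb <- m1 * (p1 - pbar)^2 + m2 * (p2 - pbar)^2 # df = 1
  msw <- (m1 * p1 * (1 - p1) + m2 * p2 * (1 - p2)) / (N - 2) # df = N - 2
  nc <- N - (m1^2 + m2^2) / N
  (msb - msw) / (msb + (nc - 1) * msw)
}

#' Two-sample Weir-Cockerham theta for one allele
#'
#' Treats the named allele against all others as biallelic and computes the
#' method-of-moments theta between the two samples from allele counts (sample
#' sizes are `n_alleles_sampled`). Theta can be negative; it is 1 for a fixed
#' difference and undefined when the pooled sample is monomorphic (an error
#' of class `temposel_monomorphic_error`, distinct from validation errors).
#'
#' @param counts1,counts2 Tibbles `allele,count` for the two temporal samples.
#' @param allele Allele label to score against the rest.
#' @return A single theta value.
#' @export
wc_theta_biallelic <- function(counts1, counts2, allele) {
  m1 <- sum(counts1$count)
  m2 <- sum(counts2$count)
  if (m1 <= 0 || m2 <= 0) stop_validation("empty sample")
  if (!allele %in% c(counts1$allele, counts2$allele)) {
    stop_validation(paste0("allele ", allele, " absent from both count tables"))
  }
  x1 <- sum(counts1$count[counts1$allele == allele])
  x2 <- sum(counts2$count[counts2$allele == allele])
  if (x1 + x2 == 0 || x1 + x2 == m1 + m2) {
    stop_monomorphic(paste0(
      "pooled sample monomorphic for allele ", allele, ": theta undefined"
    ))
  }
  theta_from_counts(x1, m1, x2, m2)
}

#' Configuration of the simulated Wright-Fisher null
#'
#' @param Ne Diploid effective size used for one generation of drift.
#' @param n1,n2 Diploid sample sizes of the seedling and seed samples.
#' @param reps Number of simulated theta values.
#' @param rng_seed Optional integer seed (determinism).
#' @return A list of class `drift_sampling_config`.
#' @export
drift_sampling_config <- function(Ne, n1, n2, reps = 1e5, rng_seed = NULL) {
  if (n1 > Ne || n2 > Ne) {
    stop_validation("sample sizes must not exceed the effective size Ne")
  }
  if (reps < 1) stop_validation("reps must be >= 1")
  # gamete draws need an integer population; never round below the samples
  Ne <- max(round(Ne), ceiling(n1), ceiling(n2))
  structure(list(Ne = Ne, n1 = n1, n2 = n2, reps = as.integer(reps),
                 rng_seed = rng_seed),
            class = "drift_sampling_config")
}

#' Simulated neutral null distribution of temporal theta
#'
#' One generation of Wright-Fisher drift: an initial frequency `p` is drawn
#' uniform on (0,1); the post-drift frequency is `Binomial(2*Ne, p)/(2*Ne)`;
#' allele counts are sampled binomially from each generation
#' (`2*n1` and `2*n2` allele draws); theta is computed from the two count
#' pairs. Replicates whose pooled sample is monomorphic are redrawn so the
#' null holds exactly `reps` defined values.
#'
#' @param cfg A [drift_sampling_config()].
#' @return An object of class `fst_null` with elements `values`,
#'   `provenance = "simulated"`, `config`.
#' @export
simulate_null <- function(cfg) {
  stopifnot(inherits(cfg, "drift_sampling_config"))
  if (!is.null(cfg$rng_seed)) set.seed(cfg$rng_seed)
  m1 <- 2L * cfg$n1
  m2 <- 2L * cfg$n2
  gam <- 2L * cfg$Ne
  vals <- numeric(0)
  while (length(vals) < cfg$reps) {
    b <- max(cfg$reps - length(vals), 1000L)
    b <- ceiling(b * 1.1) # headroom for monomorphic redraws
    p <- runif(b)
    pp <- rbinom(b, gam, p) / gam
    x1 <- rbinom(b, m1, p)
    x2 <- rbinom(b, m2, pp)
    ok <- (x1 + x2) > 0 & (x1 + x2) < (m1 + m2)
    vals <- c(vals, theta_from_counts(x1[ok], m1, x2[ok], m2))
  }
  structure(
    list(values = vals[seq_len(cfg$reps)], provenance = "simulated",
         config = cfg),
    class = "fst_null"
  )
}

#' Empirical null distribution of temporal theta
#'
#' One theta per allele observed at each microsatellite locus of the pair
#' (allele against the rest), using the same estimator as the observed loci.
#' Alleles monomorphic in the pooled sample are skipped.
#'
#' @param pair A [temporal_pair][build_temporal_pair()].
#' @param msat_loci Microsatellite loci to use; default all in the registry.
#' @return An object of class `fst_null` with `provenance = "empirical"`; its
#'   `config` records the number of contributing alleles.
#' @export
empirical_null <- function(pair, msat_loci = NULL) {
  if (is.null(msat_loci)) {
    msat_loci <- pair$loci$locus[pair$loci$kind == "microsatellite"]
  }
  if (!length(msat_loci)) stop_validation("no microsatellite loci supplied")
  vals <- numeric(0)
  for (loc in msat_loci) {
    c1 <- pair_counts(pair, "seedling", loc)
    c2 <- pair_counts(pair, "seed", loc)
    tot <- c1$count + c2$count
    seg <- c1$allele[tot > 0 & tot < sum(tot)]
    for (al in seg) {
      vals <- c(vals, wc_theta_biallelic(c1, c2, al))
    }
  }
  if (!length(vals)) {
    stop_validation("no polymorphic microsatellite alleles: empirical null empty")
  }
  structure(
    list(values = vals, provenance = "empirical",
         config = list(n_alleles = length(vals), loci = msat_loci)),
    class = "fst_null"
  )
}

#' Rank-based upper-tail outlier p-value
#'
#' `p = (# null values >= observed) / N`. When the observed value exceeds the
#' whole null, the p-value is reported at the resolution floor `1/N` with
#' `below_resolution = TRUE` rather than 0.
#'
#' @param observed Observed theta.
#' @param null An [fst_null][simulate_null()].
#' @return One-row tibble `p_value, below_resolution`.
#' @export
outlier_pvalue <- function(observed, null) {
  stopifnot(inherits(null, "fst_null"))
  n <- length(null$values)
  if (n == 0) stop_validation("empty null distribution")
  k <- sum(null$values >= observed)
  if (k == 0) {
    tibble(p_value = 1 / n, below_resolution = TRUE)
  } else {
    tibble(p_value = k / n, below_resolution = FALSE)
  }
}

#' Temporal F_ST outlier tests for the focal loci of one site-year
#'
#' For each focal locus: the observed theta of the focal allele is scored
#' against (i) the empirical null built from the pair's microsatellite
#' alleles and (ii) a simulated Wright-Fisher null parameterised by
#' `ne_lower_bound` (conservatively, the 95% lower bound of the effective
#' size: a smaller Ne means more drift, hence a wider null) and the locus's
#' own diploid sample sizes.
#'
#' @param pair A [temporal_pair][build_temporal_pair()].
#' @param focal_loci Focal loci to test; default all in the registry.
#' @param ne_lower_bound Diploid Ne for the simulated null; must be at least
#'   as large as both sample sizes.
#' @param reps Simulated-null size (the observed rank is divided by this).
#' @param rng_seed Optional integer seed.
#' @return Tibble `site, year, locus, observed_fst, p_empirical, p_simulated,
#'   below_resolution, ne_used, reps`.
#' @export
run_outlier_tests <- function(pair, focal_loci = NULL, ne_lower_bound,
                              reps = 1e5, rng_seed = NULL) {
  if (is.null(focal_loci)) {
    focal_loci <- pair$loci$locus[pair$loci$kind == "biallelic_focal"]
  }
  emp <- empirical_null(pair)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  map_dfr(focal_loci, function(loc) {
    def <- pair$loci[pair$loci$locus == loc, ]
    c1 <- pair_counts(pair, "seedling", loc)
    c2 <- pair_counts(pair, "seed", loc)
    n1 <- sum(c1$count) / 2
    n2 <- sum(c2$count) / 2
    if (ne_lower_bound < max(n1, n2)) {
      stop_validation(
        "ne_lower_bound must be >= both diploid sample sizes"
      )
    }
    obs <- wc_theta_biallelic(c1, c2, def$focal_allele)
    sim <- simulate_null(drift_sampling_config(
      Ne = ne_lower_bound, n1 = n1, n2 = n2, reps = reps
    ))
    p_emp <- outlier_pvalue(obs, emp)
    p_sim <- outlier_pvalue(obs, sim)
    tibble(
      site = pair$site, year = pair$year, locus = loc,
      observed_fst = obs,
      p_empirical = p_emp$p_value,
      p_simulated = p_sim$p_value,
      below_resolution = p_sim$below_resolution,
      ne_used = ne_lower_bound, reps = as.integer(reps)
    )
  })
}
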