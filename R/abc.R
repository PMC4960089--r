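# Viability-selection model (fitnesses 1, 1-hs, 1-s for AA, Aa, aa) and the
# ABC estimator of the selection coefficient s. The generative model per
# simulation: deterministic selection on the seedling-stage genotype
# frequencies, genotype-level multinomial drift with Ne individuals, then a
# multinomial sample of Ns individuals. Candidate s values (uniform prior on
# (0,1)) are kept when a chi-square comparison of the simulated and observed
# genotype classes has p >= 0.5.

# vectorised over q/s/h; returns 3 x B matrix of (AA, Aa, aa) frequencies
sel_freqs <- function(q, s, h) {
  p <- 1 - q
  D <- 2 * h * s * q * (q - 1) + 1 - s * q^2
  if (any(D <= 0)) stop_validation("selection denominator D <= 0")
  rbind(
    AA = p^2 / D,
    Aa = 2 * p * q * (1 - h * s) / D,
    aa = q^2 * (1 - s) / D
  )
}

#' Genotype frequencies after one round of viability selection
#'
#' Starting from Hardy-Weinberg proportions at frequency `q` of allele `a`
#' (the allele whose homozygote has fitness `1 - s`; the heterozygote has
#' fitness `1 - h*s`), returns the post-selection frequencies
#' `(1-q)^2 / D`, `2*(1-q)*q*(1-h*s) / D`, `q^2*(1-s) / D` with
#' `D = 2*h*s*q*(q-1) + 1 - s*q^2`. At `s = 0` this reduces to
#' Hardy-Weinberg.
#'
#' @param q Seedling-stage frequency of the disfavoured allele `a`, in
#'   `[0, 1]`.
#' @param s Selection coefficient in `[0, 1]`.
#' @param h Dominance of the disfavoured allele in `[0, 1]`.
#' @return A tibble with columns `AA`, `Aa`, `aa` (one row per parameter
#'   combination; arguments are recycled).
#' @examples
#' genotype_freqs_after_selection(q = 0.5, s = 1, h = 0) # (1/3, 2/3, 0)
#' @export
genotype_freqs_after_selection <- function(q, s, h) {
  if (any(q < 0 | q > 1 | s < 0 | s > 1 | h < 0 | h > 1)) {
    stop_validation("q, s and h must all lie in [0, 1]")
  }
  f <- sel_freqs(q, s, h)
  tibble(AA = unname(f["AA", ]), Aa = unname(f["Aa", ]),
         aa = unname(f["aa", ]))
}

#' ABC configuration
#'
#' @param Ne Diploid population size used for the genotype-level drift step.
#' @param Ns Diploid sampling size (`Ns <= Ne`; `Ns = Ne` is full-census
#'   sampling).
#' @param n_target_accepted Stop once this many draws are accepted.
#' @param max_sims Hard cap on the number of simulations.
#' @param accept_threshold Chi-square p-value cutoff for acceptance.
#' @param rng_seed Optional integer seed.
#' @return A list of class `abc_config`.
#' @export
abc_config <- function(Ne, Ns, n_target_accepted = 1000, max_sims = 1e6,
                       accept_threshold = 0.5, rng_seed = NULL) {
  if (Ns > Ne) stop_validation("Ns must not exceed Ne")
  if (n_target_accepted < 1) stop_validation("n_target_accepted must be >= 1")
  structure(
    list(Ne = as.integer(Ne), Ns = as.integer(Ns),
         n_target_accepted = as.integer(n_target_accepted),
         max_sims = as.integer(max_sims),
         accept_threshold = accept_threshold, rng_seed = rng_seed),
    class = "abc_config"
  )
}

# B multinomial draws with per-column probabilities (3 x B), via sequential
# binomials (rbinom is vectorised over prob; rmultinom is not).
rmultinom_cols <- function(size, probs) {
  B <- ncol(probs)
  p1 <- probs[1, ]
  x1 <- rbinom(B, size, p1)
  p2c <- ifelse(p1 < 1, probs[2, ] / (1 - p1), 0)
  x2 <- rbinom(B, size - x1, pmin(p2c, 1))
  rbind(x1, x2, size - x1 - x2)
}

# selection -> drift -> sampling for a vector of s values; 3 x B counts
simulate_offspring_batch <- function(s, q, h, Ne, Ns) {
  f <- sel_freqs(rep_len(q, length(s)), s, rep_len(h, length(s)))
  pop <- rmultinom_cols(Ne, f)
  rmultinom_cols(Ns, pop / Ne)
}

#' Simulate one offspring genotype sample under selection, drift and sampling
#'
#' Population genotype counts are drawn `Multinomial(Ne, post-selection
#' frequencies)`; the sample is then `Multinomial(Ns, population
#' proportions)`. Drift acts on genotypes directly (no re-pairing of gametes
#' between the two stages) and sampling is with replacement. Uses the current
#' RNG stream, so results are deterministic after `set.seed()`.
#'
#' @inheritParams genotype_freqs_after_selection
#' @param cfg An [abc_config()] (only `Ne` and `Ns` are used).
#' @return Named integer vector `c(AA=, Aa=, aa=)` of `Ns` individuals.
#' @export
simulate_offspring_sample <- function(q, s, h, cfg) {
  stopifnot(inherits(cfg, "abc_config"))
  x <- simulate_offspring_batch(s, q, h, cfg$Ne, cfg$Ns)
  c(AA = x[1, 1], Aa = x[2, 1], aa = x[3, 1])
}

# chi-square acceptance p-values for a 3 x B matrix of simulated samples
# against observed counts: a two-sample (contingency) chi-square of the
# 2 x 3 table (observed row, simulated row), expectations from the margins.
# This form credits sampling noise on both sides of the comparison, which
# is what makes the posterior appropriately wide when the data carry little
# information about s. Genotype classes absent from both rows are dropped
# and the df reduced; df = retained classes - 1.
abc_accept_pvalues <- function(sim, observed, Ns) {
  B <- ncol(sim)
  O <- matrix(observed, nrow = 3, ncol = B)
  colsum <- O + sim
  N <- sum(observed) + Ns
  E1 <- colsum * (sum(observed) / N)
  E2 <- colsum * (Ns / N)
  t1 <- (O - E1)^2 / E1
  t2 <- (sim - E2)^2 / E2
  dropped <- colsum == 0
  t1[dropped] <- 0
  t2[dropped] <- 0
  stat <- colSums(t1) + colSums(t2)
  df <- 3L - colSums(dropped) - 1L
  ifelse(df > 0, pchisq(stat, df, lower.tail = FALSE),
         as.numeric(stat == 0))
}

#' ABC posterior for the selection coefficient
#'
#' Draws `s ~ Uniform(0, 1)`, simulates a seed-stage genotype sample via
#' [simulate_offspring_sample()], and keeps the draw when a two-sample
#' chi-square test of the `2 x 3` table (observed vs simulated genotype
#' counts) has `p >= accept_threshold`. The two-sample form credits sampling
#' noise on both sides, so the posterior stays wide when the data are
#' uninformative about `s`. Stops at `n_target_accepted` accepted draws or
#' `max_sims` simulations.
#'
#' @param observed Named or ordered numeric vector `(AA, Aa, aa)` of observed
#'   seed-stage genotype counts, `AA` being the favoured homozygote.
#' @param q Seedling-stage frequency of the disfavoured allele `a`, in
#'   `(0, 1)` (the pre-selection state of the model).
#' @param h Dominance (fixed input, not estimated).
#' @param cfg An [abc_config()].
#' @return An object of class `abc_posterior`: list with `accepted_s`,
#'   `median`, `ci95` (2.5% and 97.5% quantiles), `n_accepted`,
#'   `n_sims_run`, `acceptance_rate`.
#' @export
abc_estimate_s <- function(observed, q, h, cfg) {
  stopifnot(inherits(cfg, "abc_config"))
  observed <- as.numeric(observed)
  if (length(observed) != 3 || sum(observed) <= 0) {
    stop_validation("observed must be 3 genotype-class counts with a positive total")
  }
  if (q <= 0 || q >= 1) stop_validation("q must be in (0, 1)")
  if (!is.null(cfg$rng_seed)) set.seed(cfg$rng_seed)

  accepted <- numeric(0)
  n_run <- 0L
  batch <- 5000L
  while (length(accepted) < cfg$n_target_accepted && n_run < cfg$max_sims) {
    b <- min(batch, cfg$max_sims - n_run)
    s <- runif(b)
    sim <- simulate_offspring_batch(s, q, h, cfg$Ne, cfg$Ns)
    p <- abc_accept_pvalues(sim, observed, cfg$Ns)
    accepted <- c(accepted, s[p >= cfg$accept_threshold])
    n_run <- n_run + b
  }
  rate <- length(accepted) / n_run
  if (rate < 1e-4 && length(accepted) < cfg$n_target_accepted) {
    abort(paste0(
      "ABC acceptance rate ", signif(rate, 2), " after ", n_run,
      " simulations; increase max_sims or reconsider the model inputs"
    ), class = "temposel_abc_error")
  }
  accepted <- head(accepted, cfg$n_target_accepted)
  structure(
    list(
      accepted_s = accepted,
      median = median(accepted),
      ci95 = unname(quantile(accepted, c(0.025, 0.975))),
      n_accepted = length(accepted),
      n_sims_run = n_run,
      acceptance_rate = rate
    ),
    class = "abc_posterior"
  )
}

#' @export
print.abc_posterior <- function(x, ...) {
  cat("<abc_posterior> median s:", round(x$median, 3),
      " 95% interval: [", round(x$ci95[1], 3), ",", round(x$ci95[2], 3), "]\n")
  cat("  accepted:", x$n_accepted, "of", x$n_sims_run,
      "simulations (rate", signif(x$acceptance_rate, 3), ")\n")
  invisible(x)
}

#' Goodness-of-fit check of the ABC point estimate
#'
#' Simulates the average seed-stage genotype frequencies at `s = median_s`
#' (over `n_sims` replicates) and G-tests the observed counts against
#' `total x averaged frequencies`. A large p-value means the point estimate
#' reproduces the observed genotype classes.
#'
#' @param median_s Point estimate of `s` (typically the posterior median).
#' @inheritParams abc_estimate_s
#' @param n_sims Number of simulations used for the averaged expectation.
#' @return One-row tibble `g_stat, df, p_value`.
#' @export
validate_fit <- function(median_s, observed, q, h, cfg, n_sims = 1e4) {
  stopifnot(inherits(cfg, "abc_config"))
  observed <- as.numeric(observed)
  if (!is.null(cfg$rng_seed)) set.seed(cfg$rng_seed + 1L)
  sim <- simulate_offspring_batch(rep(median_s, n_sims), q, h, cfg$Ne, cfg$Ns)
  avg <- rowMeans(sim / cfg$Ns)
  keep <- avg > 0 | observed > 0
  E <- sum(observed) * avg
  terms <- ifelse(observed > 0, observed * log(observed / E), 0)
  g <- 2 * sum(terms[keep])
  df <- sum(avg > 0) - 1L
  tibble(g_stat = g, df = df,
         p_value = pchisq(g, df, lower.tail = FALSE))
}

#' The validation grid of the ABC estimator
#'
#' @return Tibble of the 108 cells: `s_true` in 0.02-0.9, `Ne` 100000 or 300,
#'   sample size `n` of 100, 200 or full census (`n = Ne`), dominance `h` 0
#'   or 1.
#' @export
power_grid <- function() {
  tidyr::expand_grid(
    s_true = c(0.02, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5, 0.7, 0.9),
    Ne = c(1e5, 300),
    n_kind = c("100", "200", "Ne"),
    h = c(0, 1)
  ) |>
    mutate(n = ifelse(.data$n_kind == "Ne", .data$Ne,
                      suppressWarnings(as.numeric(.data$n_kind)))) |>
    # a sample cannot exceed the population it is drawn from
    mutate(n = pmin(.data$n, .data$Ne)) |>
    select("s_true", "Ne", "n", "h")
}

#' Recovery study of the ABC estimator over a parameter grid
#'
#' For each grid cell, one observed genotype sample is generated at the true
#' `s` (frequency of the disfavoured allele fixed at `q = 0.5`), the ABC
#' posterior is computed, and the posterior median and 95% interval are
#' recorded next to the truth.
#'
#' @param grid Tibble `s_true, Ne, n, h`; default [power_grid()].
#' @param q True (and assumed) seedling-stage frequency of allele `a`.
#' @param n_target_accepted,max_sims,accept_threshold Passed to
#'   [abc_config()].
#' @param rng_seed Optional integer seed.
#' @return `grid` with columns `median_s_hat, ci_low, ci_high, n_accepted`
#'   appended.
#' @export
power_study <- function(grid = power_grid(), q = 0.5,
                        n_target_accepted = 500, max_sims = 2e5,
                        accept_threshold = 0.5, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  res <- pmap(grid, function(s_true, Ne, n, h) {
    cfg <- abc_config(Ne = Ne, Ns = n,
                      n_target_accepted = n_target_accepted,
                      max_sims = max_sims,
                      accept_threshold = accept_threshold)
    obs <- simulate_offspring_sample(q = q, s = s_true, h = h, cfg = cfg)
    post <- abc_estimate_s(obs, q = q, h = h, cfg = cfg)
    tibble(median_s_hat = post$median,
           ci_low = post$ci95[1], ci_high = post$ci95[2],
           n_accepted = post$n_accepted)
  }) |> bind_rows()
  bind_cols(grid, res)
}
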