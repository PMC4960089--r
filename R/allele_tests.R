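# Allele-frequency estimation, signed change, G-test, the probability of k or
# more significant tests among n sites, and the gene-flow back-of-envelope.

#' Allele frequency from a count table
#'
#' @param counts Tibble `allele,count` (one locus, one sample).
#' @param allele Allele label.
#' @return `count(allele) / n_alleles_sampled`.
#' @export
allele_frequency <- function(counts, allele) {
  n <- sum(counts$count)
  if (n <= 0) stop_validation("no sampled alleles (total count is zero)")
  sum(counts$count[counts$allele == allele]) / n
}

#' Log-likelihood-ratio (G) test on two allele-count samples
#'
#' Compares the allele composition of two samples of the same locus with the
#' plain (uncorrected) G statistic, `G = 2 * sum O * ln(O/E)` over the `2 x k`
#' table of allele counts, expectations from the row/column margins. Cells
#' with `O = 0` contribute 0; alleles absent from both samples are dropped and
#' `df = k' - 1` counts only alleles with a nonzero pooled total. The p-value
#' is the upper chi-square tail.
#'
#' @param counts1,counts2 Tibbles `allele,count` for the two samples
#'   (seedling and seed stage).
#' @return One-row tibble `g_stat, df, p_value`.
#' @examples
#' a <- tibble::tibble(allele = c("A", "B"), count = c(60, 40))
#' b <- tibble::tibble(allele = c("A", "B"), count = c(40, 60))
#' g_test(a, b)
#' @export
g_test <- function(counts1, counts2) {
  tab <- full_join(
    counts1 |> select("allele", c1 = "count"),
    counts2 |> select("allele", c2 = "count"),
    by = "allele"
  ) |>
    mutate(across(c("c1", "c2"), ~ tidyr::replace_na(.x, 0)))
  if (sum(tab$c1) == 0 || sum(tab$c2) == 0) {
    stop_validation("one sample has no alleles at this locus")
  }
  tab <- tab |> filter(.data$c1 + .data$c2 > 0)
  O <- rbind(tab$c1, tab$c2)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  terms <- O * log(O / E)
  terms[O == 0] <- 0 # 0 * log(0) convention
  g <- 2 * sum(terms)
  df <- ncol(O) - 1L
  tibble(g_stat = g, df = df,
         p_value = pchisq(g, df, lower.tail = FALSE))
}

#' Signed allele-frequency change at a focal locus, with G-test
#'
#' The change is `freq(focal allele, seed) - freq(focal allele, seedling)`:
#' positive values mean the focal (favoured-hypothesis) allele increased over
#' the season.
#'
#' @param pair A [temporal_pair][build_temporal_pair()].
#' @param locus A biallelic focal locus of the pair.
#' @return One-row tibble `site, year, locus, delta, g_stat, df, p_value`.
#' @export
frequency_change <- function(pair, locus) {
  def <- pair$loci |> filter(.data$locus == !!locus)
  if (!nrow(def)) stop_validation(paste0("locus ", locus, " not in registry"))
  if (def$kind != "biallelic_focal") {
    stop_validation(paste0(locus, " is not a biallelic focal locus"))
  }
  c1 <- pair_counts(pair, "seedling", locus)
  c2 <- pair_counts(pair, "seed", locus)
  delta <- allele_frequency(c2, def$focal_allele) -
    allele_frequency(c1, def$focal_allele)
  g <- g_test(c1, c2)
  tibble(site = pair$site, year = pair$year, locus = locus, delta = delta) |>
    bind_cols(g)
}

#' Probability of k or more significant tests among n
#'
#' Exact binomial upper tail `P(X >= k)` with `X ~ Binomial(n_tests, alpha)`:
#' the chance of observing at least `k` nominally significant results among
#' `n_tests` independent true-null tests. Used to judge whether the number of
#' significant per-site frequency changes exceeds what multiplicity alone
#' would produce.
#'
#' @param n_tests Number of tests (e.g. 17 sites).
#' @param k Observed number of significant tests.
#' @param alpha Per-test significance level.
#' @return The exact upper-tail probability.
#' @examples
#' binomial_multiplicity(17, 2, 0.05)
#' @export
binomial_multiplicity <- function(n_tests, k, alpha) {
  if (k > n_tests || k < 0) {
    stop_validation("k must satisfy 0 <= k <= n_tests")
  }
  if (k == 0) return(1)
  pbinom(k - 1, n_tests, alpha, lower.tail = FALSE)
}

#' Expected one-generation frequency change caused by gene flow
#'
#' With a migration rate `m` and an allele-frequency difference `delta_p`
#' between the source and recipient populations, one generation of migration
#' shifts the recipient frequency by `m * delta_p`. Used as an order-of-
#' magnitude check that pollen flow between neighbouring fields cannot
#' explain the observed changes.
#'
#' @param m Migration rate in `[0, 1]`.
#' @param delta_p Frequency difference between recipient and source,
#'   in `[-1, 1]`.
#' @return The expected change `m * delta_p`.
#' @examples
#' migration_effect(m = 0.01, delta_p = 0.24) # 0.0024, i.e. 0.24%
#' @export
migration_effect <- function(m, delta_p) {
  if (m < 0 || m > 1) stop_validation("m must be in [0, 1]")
  if (abs(delta_p) > 1) stop_validation("delta_p must be in [-1, 1]")
  m * delta_p
}
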