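# Temporal (two-sample) effective-size estimation. Each segregating allele,
# scored against the rest, contributes a likelihood that integrates the
# unknown initial frequency (uniform prior) and sums the exact binomial
# drift transition over one generation; the per-allele log-likelihoods are
# added into a pseudo-likelihood (within-locus dependence between alleles is
# ignored). The likelihood is profiled on an Ne grid; 95% bounds are where
# the relative curve drops by 1.92 (half the chi-square(1) 95% quantile).

# Single-allele likelihood of Ne.
#
#   L(Ne) = I[ Bin(x1; m1, p) * sum_j Bin(j; 2Ne, p) Bin(x2; m2, j/(2Ne)) ]
#           / I[ Bin(x1; m1, p) ]      with I[.] = integral dp over (0,1).
#
# The p-integral has a closed form: conditional on x1, the prior-weighted
# drift outcome j follows a beta-binomial with shape (x1+1, m1-x1+1), so
#
#   L(Ne) = E_{j ~ BetaBin(2Ne, x1+1, m1-x1+1)} [ Bin(x2; m2, j/(2Ne)) ].
#
# The sum over j is evaluated exactly when the plausible window is small and
# by a strided (renormalised) sum when 2Ne is large; the integrand is smooth
# in j so the stride error is far below the MC noise of any downstream use.
allele_loglik_ne <- function(Ne, x1, m1, x2, m2, max_pts = 2001L) {
  n <- 2L * round(Ne)
  a <- x1 + 1
  b <- m1 - x1 + 1
  mu <- n * a / (a + b)
  sd <- sqrt(n * a * b * (a + b + n) / ((a + b)^2 * (a + b + 1)))
  lo <- max(0, floor(mu - 12 * sd))
  hi <- min(n, ceiling(mu + 12 * sd))
  stride <- max(1L, ceiling((hi - lo + 1) / max_pts))
  j <- seq(lo, hi, by = stride)
  lpmf <- lchoose(n, j) + lbeta(j + a, n - j + b) - lbeta(a, b)
  w <- exp(lpmf - max(lpmf))
  f <- dbinom(x2, m2, j / n)
  log(max(sum(w * f) / sum(w), 1e-300))
}

#' Log-likelihood of Ne from one allele's temporal counts
#'
#' The probability of observing `x2` copies (of `m2` sampled alleles) at the
#' seed stage given `x1` of `m1` at the seedling stage, after one generation
#' of binomial drift in a diploid population of size `Ne`, with a uniform
#' prior on the unknown population frequency. Both samples are taken
#' independently of reproduction.
#'
#' @param Ne Diploid effective size (must be at least both diploid sample
#'   sizes).
#' @param counts1,counts2 Tibbles `allele,count`: seedling and seed samples.
#' @param allele Which allele to score (against all others pooled).
#' @return The log-likelihood (an additive constant independent of `Ne` is
#'   fixed by the uniform-prior normalisation).
#' @export
temporal_allele_loglik <- function(Ne, counts1, counts2, allele) {
  m1 <- sum(counts1$count)
  m2 <- sum(counts2$count)
  if (m1 <= 0 || m2 <= 0) stop_validation("empty sample")
  if (2 * Ne < max(m1, m2)) {
    stop_validation("Ne is below the sample size: no such population")
  }
  x1 <- sum(counts1$count[counts1$allele == allele])
  x2 <- sum(counts2$count[counts2$allele == allele])
  allele_loglik_ne(Ne, x1, m1, x2, m2)
}

#' Default logarithmic Ne grid
#'
#' @param ne_min,ne_max Grid range (diploid individuals).
#' @param length Number of grid points.
#' @return Increasing integer vector of candidate Ne values.
#' @export
ne_grid <- function(ne_min, ne_max = 1e5, length = 50) {
  unique(round(exp(seq(log(ne_min), log(ne_max), length.out = length))))
}

#' Temporal effective-size estimate for one site-year
#'
#' Adds the per-allele log-likelihoods of every segregating microsatellite
#' allele (allele against the rest) into a pseudo-log-likelihood, profiles it
#' over an Ne grid, and reports the grid MLE with profile 95% bounds (curve
#' crossings of -1.92 relative to the maximum, interpolated on log Ne).
#' When the sample is much smaller than the true Ne the curve is flat at the
#' top of the grid: the upper bound (and the MLE itself) is then unreliable
#' and `upper_unresolved` is set; the lower bound remains informative.
#'
#' @param pair A [temporal_pair][build_temporal_pair()].
#' @param msat_loci Microsatellite loci to use; default all in the registry.
#' @param grid Ne grid; default [ne_grid()] from the larger diploid sample
#'   size up to 1e5.
#' @return An object of class `ne_estimate`: list with `grid` (tibble
#'   `ne, rel_loglik`), `mle`, `lower95`, `upper95`, `upper_unresolved`,
#'   `n_alleles`, `site`, `year`.
#' @export
estimate_ne <- function(pair, msat_loci = NULL, grid = NULL) {
  if (is.null(msat_loci)) {
    msat_loci <- pair$loci$locus[pair$loci$kind == "microsatellite"]
  }
  if (!length(msat_loci)) stop_validation("no microsatellite loci supplied")

  # collect (x1, m1, x2, m2) for every segregating allele
  obs <- map_dfr(msat_loci, function(loc) {
    c1 <- pair_counts(pair, "seedling", loc)
    c2 <- pair_counts(pair, "seed", loc)
    tot <- c1$count + c2$count
    keep <- tot > 0 & tot < sum(tot)
    tibble(x1 = c1$count[keep], m1 = sum(c1$count),
           x2 = c2$count[keep], m2 = sum(c2$count))
  })
  if (!nrow(obs)) stop_validation("no polymorphic microsatellite alleles")

  n_max <- max(obs$m1, obs$m2) / 2
  if (is.null(grid)) grid <- ne_grid(ne_min = ceiling(n_max))
  grid <- sort(unique(round(grid)))
  if (min(grid) < n_max) {
    stop_validation("Ne grid extends below the diploid sample size")
  }

  ll <- vapply(grid, function(ne) {
    sum(purrr::pmap_dbl(obs, function(x1, m1, x2, m2) {
      allele_loglik_ne(ne, x1, m1, x2, m2)
    }))
  }, numeric(1))
  rel <- ll - max(ll)
  i_max <- which.max(rel)

  cross <- function(idx_from, idx_to) {
    # interpolate the -1.92 crossing between consecutive grid points
    path <- seq(idx_from, idx_to)
    below <- which(rel[path] < -1.92)
    if (!length(below)) return(NA_real_)
    if (idx_to > idx_from) {
      i <- path[min(below)] # first point below, moving up
      j <- i - 1L
    } else {
      i <- path[min(below)] # first point below, moving down
      j <- i + 1L
    }
    lam <- (-1.92 - rel[j]) / (rel[i] - rel[j])
    exp(log(grid[j]) + lam * (log(grid[i]) - log(grid[j])))
  }

  lower95 <- if (i_max == 1L || all(rel[1:i_max] >= -1.92)) {
    grid[1]
  } else {
    cross(i_max, 1L)
  }
  upper_unresolved <- rel[length(grid)] > -1.92
  upper95 <- if (upper_unresolved) NA_real_ else cross(i_max, length(grid))

  structure(
    list(
      grid = tibble(ne = grid, rel_loglik = rel),
      mle = grid[i_max], lower95 = lower95, upper95 = upper95,
      upper_unresolved = upper_unresolved,
      n_alleles = nrow(obs), site = pair$site, year = pair$year
    ),
    class = "ne_estimate"
  )
}

#' @export
print.ne_estimate <- function(x, ...) {
  cat("<ne_estimate>", if (!is.null(x$site)) paste("site", x$site, "year", x$year), "\n")
  cat("  MLE:", x$mle, "  95% lower bound:", round(x$lower95, 1), "\n")
  if (x$upper_unresolved) {
    cat("  upper bound unresolved (likelihood still flat at the top of the grid)\n")
  } else {
    cat("  95% upper bound:", round(x$upper95, 1), "\n")
  }
  cat("  alleles used:", x$n_alleles, "\n")
  invisible(x)
}
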