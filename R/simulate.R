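# Synthetic genotype data with known truth. Each site-year is simulated by
# the same generative model the inference assumes: the seedling sample is
# drawn from the initial state (Hardy-Weinberg at the focal loci, the given
# allele-frequency vectors at the microsatellites); the population then
# experiences viability selection at the focal loci followed by one
# generation of multinomial drift with Ne (genotype-level at focal loci,
# allele-level at microsatellites; loci drift independently); the seed
# sample is drawn from the post-drift population.

#' Parameters of one simulated site-year
#'
#' @param site,year Identifiers.
#' @param Ne Diploid effective size (>= 2).
#' @param n_seedling,n_seed Diploid sample sizes (each <= `Ne`).
#' @param focal Tibble `locus, q0, s, h`: per focal locus, the initial
#'   frequency `q0` of the disfavoured allele `a`, the selection coefficient
#'   and the dominance.
#' @param msat_freqs Named list: per microsatellite locus, a named numeric
#'   vector of allele frequencies summing to 1.
#' @return A list of class `site_year_params`.
#' @export
site_year_params <- function(site, year, Ne, n_seedling, n_seed,
                             focal, msat_freqs) {
  if (Ne < 2) stop_validation("Ne must be >= 2")
  if (n_seedling > Ne || n_seed > Ne) {
    stop_validation("sample sizes must not exceed Ne")
  }
  if (any(focal$q0 < 0 | focal$q0 > 1 | focal$s < 0 | focal$s > 1 |
            focal$h < 0 | focal$h > 1)) {
    stop_validation("focal q0, s, h must lie in [0, 1]")
  }
  for (fr in msat_freqs) {
    if (any(fr < 0) || abs(sum(fr) - 1) > 1e-8) {
      stop_validation("microsatellite frequency vectors must be non-negative and sum to 1")
    }
  }
  structure(
    list(site = site, year = as.integer(year), Ne = as.integer(Ne),
         n_seedling = as.integer(n_seedling), n_seed = as.integer(n_seed),
         focal = focal, msat_freqs = msat_freqs),
    class = "site_year_params"
  )
}

# genotype records for n individuals at a focal locus given class counts
focal_records <- function(counts, def) {
  other <- setdiff(def$alleles[[1]], def$focal_allele)
  g <- rep(c(2, 1, 0), counts)
  tibble(
    locus = def$locus,
    allele_a = ifelse(g >= 1, def$focal_allele, other),
    allele_b = ifelse(g == 2, def$focal_allele, other)
  )
}

#' Simulate one site-year
#'
#' @param params A [site_year_params()].
#' @param loci Locus registry covering the parameterised loci.
#' @param rng_seed Integer seed; the output is deterministic given the seed.
#' @return List with `table` (genotype records), `pair` (the aggregated
#'   [temporal_pair][build_temporal_pair()]), and `truth` (tibble of realised
#'   post-drift frequencies per locus, plus the parameters used).
#' @export
simulate_site_year <- function(params, loci, rng_seed) {
  stopifnot(inherits(params, "site_year_params"))
  set.seed(rng_seed)
  recs <- list()
  truth <- list()

  for (i in seq_len(nrow(params$focal))) {
    fp <- params$focal[i, ]
    def <- loci |> filter(.data$locus == fp$locus)
    if (!nrow(def) || def$kind != "biallelic_focal") {
      stop_validation(paste0(fp$locus, " is not a biallelic focal locus of the registry"))
    }
    hw <- c((1 - fp$q0)^2, 2 * fp$q0 * (1 - fp$q0), fp$q0^2)
    g_seedling <- as.vector(rmultinom(1, params$n_seedling, hw))
    f_sel <- as.numeric(genotype_freqs_after_selection(fp$q0, fp$s, fp$h)[1, ])
    g_pop <- as.vector(rmultinom(1, params$Ne, f_sel)) / params$Ne
    g_seed <- as.vector(rmultinom(1, params$n_seed, g_pop))
    recs[[length(recs) + 1]] <- bind_rows(
      focal_records(g_seedling, def) |> mutate(stage = "seedling"),
      focal_records(g_seed, def) |> mutate(stage = "seed")
    )
    truth[[length(truth) + 1]] <- tibble(
      locus = fp$locus, kind = "biallelic_focal",
      q0 = fp$q0, s = fp$s, h = fp$h,
      # realised post-drift frequency of the disfavoured allele a
      post_freq_a = g_pop[3] + g_pop[2] / 2
    )
  }

  msat_names <- names(params$msat_freqs)
  for (loc in msat_names) {
    fr <- params$msat_freqs[[loc]]
    labs <- names(fr)
    draw_inds <- function(n, freqs) {
      a <- sample(labs, 2 * n, replace = TRUE, prob = freqs)
      tibble(locus = loc, allele_a = a[seq_len(n)],
             allele_b = a[n + seq_len(n)])
    }
    seedling <- draw_inds(params$n_seedling, fr)
    pop <- as.vector(rmultinom(1, 2 * params$Ne, fr)) / (2 * params$Ne)
    seed <- draw_inds(params$n_seed, pop)
    recs[[length(recs) + 1]] <- bind_rows(
      seedling |> mutate(stage = "seedling"),
      seed |> mutate(stage = "seed")
    )
    truth[[length(truth) + 1]] <- tibble(
      locus = loc, kind = "microsatellite",
      q0 = NA_real_, s = 0, h = NA_real_,
      post_freq_a = NA_real_
    )
  }

  table <- bind_rows(recs) |>
    group_by(.data$stage, .data$locus) |>
    mutate(individual = paste0(.data$stage, "_", row_number())) |>
    ungroup() |>
    mutate(site = params$site, year = params$year) |>
    select(all_of(GENOTYPE_COLS))

  truth <- bind_rows(truth) |>
    mutate(site = params$site, year = params$year,
           Ne = params$Ne, n_seedling = params$n_seedling,
           n_seed = params$n_seed, rng_seed = rng_seed, .before = 1)

  pair <- build_temporal_pair(table, loci, params$site, params$year)
  list(table = table, pair = pair, truth = truth)
}

#' Simulate a whole multi-site, multi-year study
#'
#' @param all_params List of [site_year_params()] with unique (site, year)
#'   keys.
#' @param loci Locus registry.
#' @param rng_seed Master seed; per-site-year seeds are derived from it.
#' @return List with `table` (concatenated genotype records), `truth`
#'   (one row per locus per site-year) and `loci`.
#' @export
simulate_study <- function(all_params, loci, rng_seed) {
  keys <- vapply(all_params, function(p) paste(p$site, p$year), "")
  if (anyDuplicated(keys)) {
    stop_validation("duplicate site-year in parameter list")
  }
  if (!length(all_params)) {
    return(list(table = tibble(), truth = tibble(), loci = loci))
  }
  seeds <- derive_seeds(rng_seed, length(all_params))
  out <- map2(all_params, seeds, function(p, sd) {
    simulate_site_year(p, loci, sd)
  })
  list(
    table = bind_rows(map(out, "table")),
    truth = bind_rows(map(out, "truth")),
    loci = loci
  )
}

#' Default locus registry of the synthetic study
#'
#' Two biallelic focal flowering-time genes (fragment-size alleles 80/83 and
#' 363/387, the 80 and 363 alleles being focal) and nine microsatellite
#' loci whose allele counts total 173.
#'
#' @return A locus registry tibble.
#' @export
default_loci <- function() {
  msat_names <- c("PSMP2085", "PSMP2202", "PSMP2218", "PSMP2220", "PSMP2237",
                  "PSMP2263", "PSMP2270", "PSMP2271", "PSMP2273")
  msat_k <- c(25, 23, 22, 21, 19, 18, 17, 15, 13) # 173 alleles in total
  msat_alleles <- map2(msat_names, msat_k, function(nm, k) {
    as.character(seq(150, by = 3, length.out = k))
  })
  locus_table(
    locus = c("PgPHYC", "PgMADS11", msat_names),
    kind = c("biallelic_focal", "biallelic_focal",
             rep("microsatellite", length(msat_names))),
    alleles = c(list(c("80", "83"), c("363", "387")), msat_alleles),
    focal_allele = c("80", "363", rep(NA_character_, length(msat_names)))
  )
}

#' Template of the default 17-site x 2-year synthetic study
#'
#' Emulates the field design the package is built for: 17 sites sampled in
#' two years, ~100 diploid individuals per stage, true diploid `Ne = 300`
#' per site-year (within the 130-400 range a temporal estimate would give
#' for such fields), two focal genes and nine microsatellites totalling 173
#' alleles. A minority of site-year x focal-locus combinations (14 of 68)
#' experience strong viability selection (`s = 0.9`, `h = 0`, with the
#' disfavoured allele starting at `q0 = 0.6`); the pattern mirrors a design
#' with more selection events in the first year. The selected regime was
#' chosen at design time so the outlier test has >= 90% planned power
#' against the conservative lower-bound null; weaker selection is
#' deliberately not part of the default study because no test of this design
#' can resolve it (see the methods vignette).
#'
#' Microsatellite allele frequencies are drawn per site-year from a
#' symmetric Dirichlet(5) (moderately even, so most of the 173 alleles are
#' actually observed in samples of 100 individuals), deterministically from
#' `seed`.
#'
#' @param n_sites Number of sites.
#' @param years Years sampled.
#' @param Ne,n_seedling,n_seed Per-site-year sizes.
#' @param s_selected,h_selected,q0_selected Selection regime of the selected
#'   site-year x locus combinations.
#' @param seed Seed for the template's frequency draws (not for the study
#'   simulation itself).
#' @return List with `loci`, `params` (list of [site_year_params()]) and
#'   `selection` (tibble `site, year, locus, s` of the truly selected
#'   combinations).
#' @export
study_template <- function(n_sites = 17, years = c(2008L, 2009L),
                           Ne = 300, n_seedling = 100, n_seed = 100,
                           s_selected = 0.9, h_selected = 0,
                           q0_selected = 0.6, seed = 20160726) {
  loci <- default_loci()
  sites <- sprintf("S%02d", seq_len(n_sites))
  msat <- loci |> filter(.data$kind == "microsatellite")

  # selected combinations: more events in the first year, two loci involved
  pick <- function(idx, yr, locus) {
    idx <- idx[idx <= n_sites]
    if (!length(idx) || length(years) < match(yr, years)) return(NULL)
    tibble(site = sites[idx], year = yr, locus = locus)
  }
  selection <- bind_rows(
    pick(1:6, years[1], "PgPHYC"),
    if (length(years) > 1) pick(1:3, years[2], "PgPHYC"),
    pick(7:9, years[1], "PgMADS11"),
    if (length(years) > 1) pick(7:8, years[2], "PgMADS11")
  ) |> mutate(s = s_selected)

  freq_seeds <- derive_seeds(seed, n_sites * length(years))
  params <- list()
  k <- 0
  for (yr in years) {
    for (si in sites) {
      k <- k + 1
      set.seed(freq_seeds[k])
      msat_freqs <- setNames(map(msat$alleles, function(al) {
        g <- rgamma(length(al), shape = 5)
        setNames(g / sum(g), al)
      }), msat$locus)
      sel_here <- selection |> filter(.data$site == si, .data$year == yr)
      focal <- tibble(
        locus = c("PgPHYC", "PgMADS11"),
        q0 = c(0.5, 0.4),
        s = 0, h = 0
      ) |>
        mutate(
          s = ifelse(.data$locus %in% sel_here$locus, s_selected, .data$s),
          h = ifelse(.data$locus %in% sel_here$locus, h_selected, .data$h),
          q0 = ifelse(.data$locus %in% sel_here$locus, q0_selected, .data$q0)
        )
      params[[k]] <- site_year_params(
        site = si, year = yr, Ne = Ne,
        n_seedling = n_seedling, n_seed = n_seed,
        focal = focal, msat_freqs = msat_freqs
      )
    }
  }
  list(loci = loci, params = params, selection = selection)
}
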