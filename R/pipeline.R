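# End-to-end orchestration: frequency-change G-tests, temporal Ne at the
# reference sites, F_ST outlier tests for every site-year against the
# conservative lower-bound null, ABC selection-coefficient estimation on the
# flagged loci only, and CSV reports.

#' Pipeline configuration
#'
#' @param genotypes Genotype-record tibble, or a path to a `genotypes.csv`.
#' @param loci Locus registry tibble, or a path to a `loci.csv`.
#' @param reference_sites Sites at which the effective size is estimated
#'   each year; the smallest 95% lower bound per year parameterises the
#'   simulated null for every site of that year.
#' @param alpha Significance level for flags.
#' @param null_reps Simulated-null size per site-year.
#' @param abc_h Dominance assumed by the ABC stage.
#' @param abc_n_target,abc_max_sims,abc_accept ABC stopping rule and
#'   acceptance threshold.
#' @param seed Master seed; all stage seeds derive from it.
#' @param outdir Output directory for the CSV reports and run log, or `NULL`
#'   to skip writing.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(genotypes, loci, reference_sites,
                            alpha = 0.05, null_reps = 1e4,
                            abc_h = 0, abc_n_target = 1000,
                            abc_max_sims = 1e6, abc_accept = 0.5,
                            seed = 1L, outdir = NULL) {
  if (alpha <= 0 || alpha >= 1) stop_validation("alpha must be in (0, 1)")
  for (x in list(genotypes, loci)) {
    if (is.character(x) && !file.exists(x)) {
      stop_validation(paste0("input file not found: ", x))
    }
  }
  structure(
    list(genotypes = genotypes, loci = loci,
         reference_sites = reference_sites, alpha = alpha,
         null_reps = null_reps, abc_h = abc_h,
         abc_n_target = abc_n_target, abc_max_sims = abc_max_sims,
         abc_accept = abc_accept, seed = seed, outdir = outdir),
    class = "pipeline_config"
  )
}

with_stage <- function(stage, site, year, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", stage, "' failed at site ", site,
                 " year ", year, ": ", conditionMessage(e)),
          class = "temposel_pipeline_error", parent = e)
  })
}

#' Run the full analysis pipeline
#'
#' Stages, in order: (1) per-site-year signed frequency change and G-test at
#' every focal locus; (2) temporal Ne estimation at the reference sites of
#' each year; (3) F_ST outlier tests for every site-year, with the simulated
#' null parameterised by the year's smallest reference lower bound (raised
#' to the site-year's sample size when necessary, since no population can be
#' smaller than a sample drawn from it); (4) ABC estimation of `s` with
#' goodness-of-fit validation, run only on the locus/site-years flagged by
#' the simulated-null outlier test. Deterministic given `seed`; when
#' `outdir` is set, writes `freq_changes.csv`, `ne_estimates.csv`,
#' `fst_tests.csv`, `abc_results.csv` and `run_log.txt`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of the four result tibbles.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  loci <- if (is.character(config$loci)) read_loci(config$loci) else config$loci
  genotypes <- if (is.character(config$genotypes)) {
    read_genotype_table(config$genotypes, loci)
  } else {
    validate_genotype_table(config$genotypes, loci)
  }

  site_years <- genotypes |> distinct(.data$site, .data$year) |>
    arrange(.data$site, .data$year)
  missing_ref <- setdiff(config$reference_sites, site_years$site)
  if (length(missing_ref)) {
    stop_validation(paste0("reference site(s) absent from the data: ",
                           paste(missing_ref, collapse = ", ")))
  }
  seeds <- derive_seeds(config$seed, nrow(site_years) + 1L)
  pairs <- Map(function(site, year) {
    with_stage("aggregate", site, year,
               build_temporal_pair(genotypes, loci, site, year))
  }, site_years$site, site_years$year)
  names(pairs) <- paste(site_years$site, site_years$year)

  focal_loci <- loci$locus[loci$kind == "biallelic_focal"]

  # stage 1: frequency changes -----------------------------------------------
  freq_changes <- bind_rows(lapply(pairs, function(pr) {
    bind_rows(lapply(focal_loci, function(loc) {
      with_stage("freqtest", pr$site, pr$year, frequency_change(pr, loc))
    }))
  })) |>
    mutate(signif = .data$p_value <= config$alpha)

  # stage 2: temporal Ne at the reference sites ------------------------------
  ref_keys <- site_years |> filter(.data$site %in% config$reference_sites)
  ne_estimates <- Map(function(site, year) {
    est <- with_stage("ne", site, year,
                      estimate_ne(pairs[[paste(site, year)]]))
    tibble(site = site, year = year, mle = est$mle,
           lower95 = est$lower95, upper95 = est$upper95,
           upper_unresolved = est$upper_unresolved,
           n_alleles = est$n_alleles)
  }, ref_keys$site, ref_keys$year) |> bind_rows()
  ne_by_year <- ne_estimates |>
    group_by(.data$year) |>
    summarise(ne_lower = min(.data$lower95))

  # stage 3: outlier tests ----------------------------------------------------
  fst_tests <- Map(function(pr, sd) {
    ne_low <- ne_by_year$ne_lower[ne_by_year$year == pr$year]
    n_max <- max(pr$n_ind$n)
    with_stage("fst", pr$site, pr$year,
               run_outlier_tests(pr, focal_loci,
                                 ne_lower_bound = max(ne_low, n_max),
                                 reps = config$null_reps, rng_seed = sd))
  }, pairs, seeds[seq_len(nrow(site_years))]) |> bind_rows() |>
    mutate(flagged = .data$p_simulated <= config$alpha)

  # stage 4: ABC on flagged loci only -----------------------------------------
  flagged <- fst_tests |> filter(.data$flagged)
  abc_seeds <- derive_seeds(seeds[length(seeds)], max(nrow(flagged), 1L))
  abc_results <- Map(
    function(site, year, loc, ne_used, sd) {
      with_stage("abc", site, year, {
        pr <- pairs[[paste(site, year)]]
        def <- pr$loci[pr$loci$locus == loc, ]
        q_seedling <- 1 - allele_frequency(
          pair_counts(pr, "seedling", loc), def$focal_allele
        )
        obs <- pair_genotype_counts(pr, "seed", loc)
        cfg <- abc_config(
          Ne = max(round(ne_used), sum(obs)), Ns = sum(obs),
          n_target_accepted = config$abc_n_target,
          max_sims = config$abc_max_sims,
          accept_threshold = config$abc_accept, rng_seed = sd
        )
        post <- abc_estimate_s(obs, q = q_seedling, h = config$abc_h,
                               cfg = cfg)
        val <- validate_fit(post$median, obs, q = q_seedling,
                            h = config$abc_h, cfg = cfg)
        tibble(
          site = site, year = year, locus = loc, h = config$abc_h,
          ne_used = cfg$Ne, ns = cfg$Ns,
          median_s = post$median, ci_low = post$ci95[1],
          ci_high = post$ci95[2], n_accepted = post$n_accepted,
          acceptance_rate = post$acceptance_rate,
          validation_g = val$g_stat, validation_p = val$p_value
        )
      })
    },
    flagged$site, flagged$year, flagged$locus, flagged$ne_used,
    abc_seeds[seq_len(nrow(flagged))]
  ) |> bind_rows()

  results <- list(freq_changes = freq_changes, ne_estimates = ne_estimates,
                  fst_tests = fst_tests, abc_results = abc_results)

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(freq_changes, file.path(config$outdir, "freq_changes.csv"))
    readr::write_csv(ne_estimates, file.path(config$outdir, "ne_estimates.csv"))
    readr::write_csv(fst_tests, file.path(config$outdir, "fst_tests.csv"))
    readr::write_csv(abc_results, file.path(config$outdir, "abc_results.csv"))
    writeLines(c(
      paste0("temposel ", as.character(utils::packageVersion("temposel"))),
      paste0("R ", R.version.string),
      paste0("seed ", config$seed),
      paste0("alpha ", config$alpha),
      paste0("null_reps ", config$null_reps),
      paste0("site_years ", nrow(site_years)),
      paste0("flagged ", nrow(flagged))
    ), file.path(config$outdir, "run_log.txt"))
  }
  invisible(results)
}
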