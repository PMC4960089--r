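# Long-format genotype tables and their aggregation into per-site-year
# temporal pairs (seedling-stage vs seed-stage counts).

GENOTYPE_COLS <- c("site", "year", "stage", "individual", "locus",
                   "allele_a", "allele_b")
STAGES <- c("seedling", "seed")

#' Read a long-format genotype table
#'
#' One row per individual per locus, columns
#' `site,year,stage,individual,locus,allele_a,allele_b`. `stage` must be
#' `"seedling"` or `"seed"`. A row with a missing allele call (empty cell or
#' `NA`) is dropped for that locus only; dropped rows are counted in the
#' `parse_report` attribute of the result, so per-locus genotype totals may
#' differ (as they do in real fragment-genotyping data).
#'
#' @param path CSV file path.
#' @param loci Locus registry (see [locus_table()]); used to validate locus
#'   and allele labels.
#' @return A validated tibble of genotype records with attribute
#'   `parse_report` (tibble of dropped-row counts per locus).
#' @seealso [write_genotype_table()], [build_temporal_pair()]
#' @export
read_genotype_table <- function(path, loci) {
  if (!file.exists(path)) stop_validation(paste0("file not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(
    site = readr::col_character(),
    year = readr::col_integer(),
    stage = readr::col_character(),
    individual = readr::col_character(),
    locus = readr::col_character(),
    allele_a = readr::col_character(),
    allele_b = readr::col_character()
  ), na = c("", "NA"))
  validate_genotype_table(raw, loci)
}

#' @rdname read_genotype_table
#' @param table A genotype-record tibble.
#' @export
write_genotype_table <- function(table, path) {
  readr::write_csv(table[, GENOTYPE_COLS], path, na = "")
  invisible(path)
}

#' Validate a genotype-record tibble
#'
#' Checks the column schema, the stage enum, locus and allele labels against
#' the registry, and uniqueness of (site, year, stage, individual, locus)
#' keys. Rows with a missing allele call are dropped and reported.
#'
#' @inheritParams read_genotype_table
#' @return The validated tibble (missing-call rows removed), with a
#'   `parse_report` attribute.
#' @export
validate_genotype_table <- function(table, loci) {
  if (!all(GENOTYPE_COLS %in% names(table))) {
    stop_validation(paste0(
      "genotype table must have columns ", paste(GENOTYPE_COLS, collapse = ", ")
    ))
  }
  table <- as_tibble(table)[, GENOTYPE_COLS]
  table$year <- as.integer(table$year)

  bad_stage <- setdiff(unique(table$stage), STAGES)
  if (length(bad_stage)) {
    stop_validation(paste0(
      "invalid stage value(s): ", paste(bad_stage, collapse = ", "),
      " (must be 'seedling' or 'seed')"
    ))
  }
  bad_locus <- setdiff(unique(table$locus), loci$locus)
  if (length(bad_locus)) {
    stop_validation(paste0(
      "unknown locus label(s): ", paste(bad_locus, collapse = ", ")
    ))
  }

  missing_call <- is.na(table$allele_a) | is.na(table$allele_b)
  report <- table[missing_call, ] |>
    count(.data$locus, name = "n_dropped")
  kept <- table[!missing_call, ]

  # allele labels must belong to their locus's allele set
  allele_sets <- setNames(loci$alleles, loci$locus)
  long <- tidyr::pivot_longer(kept, c("allele_a", "allele_b"),
                              values_to = "allele")
  bad <- long |>
    distinct(.data$locus, .data$allele) |>
    rowwise() |>
    filter(!.data$allele %in% allele_sets[[.data$locus]]) |>
    ungroup()
  if (nrow(bad)) {
    stop_validation(paste0(
      "allele label(s) not in locus allele set: ",
      paste(paste0(bad$locus, ":", bad$allele), collapse = ", ")
    ))
  }

  dup <- kept |>
    count(.data$site, .data$year, .data$stage, .data$individual, .data$locus) |>
    filter(.data$n > 1)
  if (nrow(dup)) {
    stop_validation(paste0(
      "duplicate genotype record key(s), e.g. ",
      paste(dup$site[1], dup$year[1], dup$stage[1], dup$individual[1],
            dup$locus[1], sep = "/")
    ))
  }
  attr(kept, "parse_report") <- report
  kept
}

# per-stage aggregation helpers ----------------------------------------------

count_alleles <- function(records, allele_set) {
  obs <- c(records$allele_a, records$allele_b)
  n <- table(factor(obs, levels = allele_set))
  tibble(allele = allele_set, count = as.integer(n))
}

count_genotypes <- function(records, focal) {
  nf <- (records$allele_a == focal) + (records$allele_b == focal)
  tibble(
    n2 = sum(nf == 2L), # focal homozygotes
    n1 = sum(nf == 1L), # heterozygotes
    n0 = sum(nf == 0L)  # non-focal homozygotes
  )
}

#' Aggregate one site-year into a temporal pair
#'
#' A temporal pair holds, for one site and one year, the per-locus allele
#' counts of the seedling-stage and seed-stage samples (and, for biallelic
#' focal loci, the three genotype-class counts). It is the unit of analysis
#' for all downstream tests. `n_alleles_sampled` for a locus/stage is always
#' `2 x` the number of individuals with a non-missing genotype there.
#'
#' @param table Genotype-record tibble (see [read_genotype_table()]).
#' @param loci Locus registry.
#' @param site,year Which site-year to aggregate.
#' @return An object of class `temporal_pair`: a list with elements `site`,
#'   `year`, `loci`, `alleles` (tibble `stage,locus,allele,count`),
#'   `genotypes` (tibble `stage,locus,n2,n1,n0` for focal loci), and `n_ind`
#'   (tibble `stage,locus,n` of genotyped individuals).
#' @export
build_temporal_pair <- function(table, loci, site, year) {
  sub <- table |> filter(.data$site == !!site, .data$year == !!year)
  for (st in STAGES) {
    if (!any(sub$stage == st)) {
      stop_validation(paste0(
        "site ", site, " year ", year, " is missing the ", st, " stage"
      ))
    }
  }
  grid <- tidyr::expand_grid(stage = STAGES, locus = loci$locus)
  allele_sets <- setNames(loci$alleles, loci$locus)

  alleles <- grid |>
    pmap(function(stage, locus) {
      recs <- sub[sub$stage == stage & sub$locus == locus, ]
      count_alleles(recs, allele_sets[[locus]]) |>
        mutate(stage = stage, locus = locus, .before = 1)
    }) |>
    bind_rows()

  focal_loci <- loci |> filter(.data$kind == "biallelic_focal")
  genotypes <- tidyr::expand_grid(stage = STAGES, locus = focal_loci$locus) |>
    pmap(function(stage, locus) {
      recs <- sub[sub$stage == stage & sub$locus == locus, ]
      focal <- focal_loci$focal_allele[focal_loci$locus == locus]
      count_genotypes(recs, focal) |>
        mutate(stage = stage, locus = locus, .before = 1)
    }) |>
    bind_rows()

  n_ind <- sub |>
    count(.data$stage, .data$locus, name = "n")

  structure(
    list(site = site, year = year, loci = loci, alleles = alleles,
         genotypes = genotypes, n_ind = n_ind),
    class = "temporal_pair"
  )
}

#' @export
print.temporal_pair <- function(x, ...) {
  cat("<temporal_pair> site", x$site, "year", x$year, "\n")
  cat("  loci:", nrow(x$loci), "(",
      sum(x$loci$kind == "biallelic_focal"), "focal,",
      sum(x$loci$kind == "microsatellite"), "microsatellite )\n")
  n <- x$n_ind |> group_by(.data$stage) |> summarise(n = max(.data$n))
  for (i in seq_len(nrow(n))) {
    cat("  ", n$stage[i], "individuals (max over loci):", n$n[i], "\n")
  }
  invisible(x)
}

#' Allele counts of one locus/stage of a temporal pair
#'
#' @param pair A `temporal_pair`.
#' @param stage `"seedling"` or `"seed"`.
#' @param locus Locus name.
#' @return Tibble `allele,count` covering the locus's full allele set.
#' @export
pair_counts <- function(pair, stage, locus) {
  out <- pair$alleles |>
    filter(.data$stage == !!stage, .data$locus == !!locus) |>
    select("allele", "count")
  if (!nrow(out)) {
    stop_validation(paste0("locus ", locus, " not present in pair"))
  }
  out
}

#' Genotype-class counts of one focal locus/stage of a temporal pair
#'
#' @inheritParams pair_counts
#' @return Named vector `c(AA=, Aa=, aa=)`, `AA` being the focal homozygote.
#' @export
pair_genotype_counts <- function(pair, stage, locus) {
  g <- pair$genotypes |>
    filter(.data$stage == !!stage, .data$locus == !!locus)
  if (!nrow(g)) {
    stop_validation(paste0("no genotype classes for locus ", locus,
                           " (not a biallelic focal locus?)"))
  }
  c(AA = g$n2, Aa = g$n1, aa = g$n0)
}
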