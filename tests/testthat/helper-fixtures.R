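# Shared fixtures, all built in code.

make_counts <- function(...) {
  x <- c(...)
  tibble::tibble(allele = names(x), count = unname(as.numeric(x)))
}

# A minimal registry: one focal gene and one microsatellite.
tiny_loci <- function() {
  locus_table(
    locus = c("GeneA", "MsatM"),
    kind = c("biallelic_focal", "microsatellite"),
    alleles = list(c("80", "83"), c("150", "153", "156")),
    focal_allele = c("80", NA)
  )
}

# Assemble a temporal_pair directly from per-stage count vectors.
# focal: named list locus -> list(seedling = c(AA, Aa, aa), seed = ...)
# msat:  named list locus -> list(seedling = named allele counts, seed = ...)
make_pair <- function(loci, focal = list(), msat = list(),
                      site = "X", year = 2000L) {
  alleles <- list()
  genotypes <- list()
  n_ind <- list()
  for (loc in names(focal)) {
    def <- loci[loci$locus == loc, ]
    other <- setdiff(def$alleles[[1]], def$focal_allele)
    for (st in c("seedling", "seed")) {
      g <- focal[[loc]][[st]]
      alleles[[length(alleles) + 1]] <- tibble::tibble(
        stage = st, locus = loc,
        allele = c(def$focal_allele, other),
        count = c(2 * g[1] + g[2], 2 * g[3] + g[2])
      )
      genotypes[[length(genotypes) + 1]] <- tibble::tibble(
        stage = st, locus = loc, n2 = g[1], n1 = g[2], n0 = g[3]
      )
      n_ind[[length(n_ind) + 1]] <- tibble::tibble(
        stage = st, locus = loc, n = sum(g)
      )
    }
  }
  for (loc in names(msat)) {
    for (st in c("seedling", "seed")) {
      x <- msat[[loc]][[st]]
      alleles[[length(alleles) + 1]] <- tibble::tibble(
        stage = st, locus = loc, allele = names(x), count = unname(x)
      )
      n_ind[[length(n_ind) + 1]] <- tibble::tibble(
        stage = st, locus = loc, n = sum(x) / 2
      )
    }
  }
  structure(
    list(site = site, year = year, loci = loci,
         alleles = dplyr::bind_rows(alleles),
         genotypes = dplyr::bind_rows(genotypes),
         n_ind = dplyr::bind_rows(n_ind)),
    class = "temporal_pair"
  )
}

# Site-year parameters with a single focal locus and optional flat-frequency
# microsatellites; cheap enough for calibration loops.
light_params <- function(q0, s = 0, h = 0, Ne = 300, n = 100,
                         loci = tiny_loci(), with_msat = FALSE) {
  msat <- list()
  if (with_msat) {
    m <- loci[loci$kind == "microsatellite", ]
    msat <- stats::setNames(lapply(m$alleles, function(al) {
      stats::setNames(rep(1 / length(al), length(al)), al)
    }), m$locus)
  }
  site_year_params(
    site = "X", year = 2000L, Ne = Ne, n_seedling = n, n_seed = n,
    focal = tibble::tibble(locus = "GeneA", q0 = q0, s = s, h = h),
    msat_freqs = msat
  )
}
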