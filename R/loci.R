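# Locus registry: which loci exist, their allele sets, and (for biallelic
# focal genes) which allele is the focal one whose increase is counted
# positive.

#' Build a locus registry
#'
#' The registry is a tibble with one row per locus. Focal loci are the
#' candidate genes under a selection hypothesis: strictly biallelic, with a
#' declared focal allele (the allele whose frequency increase is reported as a
#' positive change, i.e. the allele favoured under the alternative).
#' Microsatellite loci are multi-allelic neutral markers used for the
#' empirical F_ST null and for effective-size estimation.
#'
#' @param locus Character vector of locus names (unique).
#' @param kind `"biallelic_focal"` or `"microsatellite"`, recycled.
#' @param alleles List of character vectors: the allele labels of each locus.
#'   Labels are opaque strings (fragment sizes such as `"80"` are labels, not
#'   numbers).
#' @param focal_allele Character vector; required (non-`NA`) for
#'   `biallelic_focal` loci, must be `NA` for microsatellites.
#' @return A tibble of class `temposel_loci` with columns `locus`, `kind`,
#'   `alleles` (list column), `focal_allele`.
#' @examples
#' locus_table(
#'   locus = c("PgPHYC", "PSMP2085"),
#'   kind = c("biallelic_focal", "microsatellite"),
#'   alleles = list(c("80", "83"), c("150", "153", "156")),
#'   focal_allele = c("80", NA)
#' )
#' @export
locus_table <- function(locus, kind, alleles, focal_allele = NA_character_) {
  tbl <- tibble(
    locus = as.character(locus),
    kind = rep_len(as.character(kind), length(locus)),
    alleles = alleles,
    focal_allele = rep_len(as.character(focal_allele), length(locus))
  )
  validate_loci(tbl)
}

validate_loci <- function(tbl) {
  need <- c("locus", "kind", "alleles", "focal_allele")
  if (!all(need %in% names(tbl))) {
    stop_validation(paste0(
      "locus registry must have columns ",
      paste(need, collapse = ", ")
    ))
  }
  if (anyDuplicated(tbl$locus)) {
    stop_validation("duplicate locus names in registry")
  }
  bad_kind <- setdiff(unique(tbl$kind), c("biallelic_focal", "microsatellite"))
  if (length(bad_kind)) {
    stop_validation(paste0("unknown locus kind: ", paste(bad_kind, collapse = ", ")))
  }
  for (i in seq_len(nrow(tbl))) {
    al <- as.character(tbl$alleles[[i]])
    if (anyDuplicated(al)) {
      stop_validation(paste0("duplicate allele labels at locus ", tbl$locus[i]))
    }
    if (tbl$kind[i] == "biallelic_focal") {
      if (length(al) != 2) {
        stop_validation(paste0(
          "biallelic focal locus ", tbl$locus[i], " must have exactly 2 alleles"
        ))
      }
      if (is.na(tbl$focal_allele[i]) || !tbl$focal_allele[i] %in% al) {
        stop_validation(paste0(
          "focal_allele of ", tbl$locus[i], " must be one of its alleles"
        ))
      }
    } else {
      if (length(al) < 2) {
        stop_validation(paste0(
          "microsatellite locus ", tbl$locus[i], " must have >= 2 alleles"
        ))
      }
    }
  }
  class(tbl) <- c("temposel_loci", class(tbl))
  tbl
}

#' Read / write a locus registry CSV
#'
#' The CSV schema is `locus,kind,alleles,focal_allele` with allele labels
#' separated by semicolons, e.g. `PSMP2085,microsatellite,150;153;156,`.
#'
#' @param path File path.
#' @return `read_loci()` returns a validated locus registry tibble;
#'   `write_loci()` returns `path` invisibly.
#' @export
read_loci <- function(path) {
  if (!file.exists(path)) stop_validation(paste0("file not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  locus_table(
    locus = raw$locus,
    kind = raw$kind,
    alleles = strsplit(raw$alleles, ";", fixed = TRUE),
    focal_allele = raw$focal_allele
  )
}

#' @rdname read_loci
#' @param loci A locus registry tibble.
#' @export
write_loci <- function(loci, path) {
  out <- tibble(
    locus = loci$locus,
    kind = loci$kind,
    alleles = vapply(loci$alleles, paste, "", collapse = ";"),
    focal_allele = loci$focal_allele
  )
  readr::write_csv(out, path, na = "")
  invisible(path)
}
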