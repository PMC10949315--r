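#' Tally per-species asparaginase repertoires
#'
#' Counts, for every bacterial species, its long-chain asparaginases by
#' localization (cytoplasmic, SPI-secreted, SPII-lipoprotein) and its
#' short-chain enzymes. When a species is represented by several genomes,
#' counting is presence-based by default: exact duplicate loci (same
#' genome, strand and interval) are dropped first, then identical protein
#' sequences within a species are collapsed, so re-sequenced genomes do
#' not inflate counts. Set `collapse = "genome"` to tally every genome
#' separately (one repertoire per genome).
#'
#' @param records Data frame with columns `species`, `length_class`,
#'   `localization` (and optionally `genome_id`/`strand`/`start`/`end`
#'   and `protein`, used for deduplication).
#' @param roster Optional character vector of species; species without
#'   records appear with all-zero counts.
#' @param collapse `"species"` (default) or `"genome"`.
#' @return Data frame of class `species_repertoire` with columns
#'   `species`, `n_lc_cytoplasmic`, `n_lc_SPI`, `n_lc_SPII`, `n_lc`,
#'   `n_sc`.
#' @export
tally_repertoires <- function(records, roster = NULL,
                              collapse = c("species", "genome")) {
  collapse <- match.arg(collapse)
  if (nrow(records) > 0 && (is.null(records$species) ||
                            anyNA(records$species)))
    stop("records must carry a 'species' field", call. = FALSE)
  if (nrow(records) > 0) {
    stopifnot(!is.null(records$length_class), !is.null(records$localization))
    if (!is.null(records$genome_id) && !is.null(records$start)) {
      key <- paste(records$genome_id, records$strand, records$start,
                   records$end)
      records <- records[!duplicated(key), , drop = FALSE]
    }
    if (collapse == "species" && !is.null(records$protein)) {
      key <- paste(records$species, records$protein)
      records <- records[!duplicated(key), , drop = FALSE]
    }
  }
  unit <- if (collapse == "genome" && !is.null(records$genome_id))
    records$genome_id else records$species
  all_units <- unique(c(unit, roster))
  count <- function(cond) {
    t <- table(factor(unit[cond], levels = all_units))
    as.integer(t)
  }
  lc <- records$length_class == "long"
  out <- data.frame(
    species = all_units,
    n_lc_cytoplasmic = count(lc & records$localization == "cytoplasmic"),
    n_lc_SPI = count(lc & records$localization == "SPI"),
    n_lc_SPII = count(lc & records$localization == "SPII"),
    n_sc = count(records$length_class == "short"),
    stringsAsFactors = FALSE)
  out$n_lc <- out$n_lc_cytoplasmic + out$n_lc_SPI + out$n_lc_SPII
  class(out) <- c("species_repertoire", class(out))
  out
}

#' Histogram of long-chain repertoire combinations
#'
#' Counts how many species carry each (cytoplasmic, SPI, SPII)
#' long-chain combination, ordered by decreasing species count. The
#' modal combinations reveal the typical per-organism repertoire (most
#' species: none at all, then a single cytoplasmic enzyme).
#'
#' @param repertoires A [tally_repertoires()] result.
#' @return Data frame with `n_lc_cytoplasmic`, `n_lc_SPI`, `n_lc_SPII`,
#'   `n_species`; counts sum to the roster size.
#' @export
repertoire_histogram <- function(repertoires) {
  key <- paste(repertoires$n_lc_cytoplasmic, repertoires$n_lc_SPI,
               repertoires$n_lc_SPII, sep = ",")
  tab <- sort(table(key), decreasing = TRUE)
  parts <- strsplit(names(tab), ",", fixed = TRUE)
  data.frame(
    n_lc_cytoplasmic = as.integer(vapply(parts, `[`, "", 1L)),
    n_lc_SPI = as.integer(vapply(parts, `[`, "", 2L)),
    n_lc_SPII = as.integer(vapply(parts, `[`, "", 3L)),
    n_species = as.integer(tab), stringsAsFactors = FALSE)
}

#' Short-chain fraction stratified by long-chain count
#'
#' Groups species by their number of long-chain asparaginases (0, 1, or
#' more than one) and reports, per group, the fraction of species that
#' carry at least one short-chain enzyme. An empty group yields an
#' undefined (NA) fraction, never 0.
#'
#' @param repertoires A [tally_repertoires()] result.
#' @return Data frame with `lc_group` (`"0"`, `"1"`, `">1"`),
#'   `n_species`, `n_with_sc`, `fraction` (NA when `n_species` is 0) and
#'   `defined`.
#' @export
sc_fraction_by_lc_count <- function(repertoires) {
  grp <- cut(repertoires$n_lc, breaks = c(-0.5, 0.5, 1.5, Inf),
             labels = c("0", "1", ">1"))
  n <- as.integer(table(grp))
  with_sc <- vapply(levels(grp), function(g)
    sum(repertoires$n_sc[grp == g] >= 1L), integer(1))
  data.frame(lc_group = levels(grp), n_species = n,
             n_with_sc = as.integer(with_sc),
             fraction = ifelse(n > 0, with_sc / n, NA_real_),
             defined = n > 0, stringsAsFactors = FALSE)
}
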