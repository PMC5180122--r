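#' Read a species ledger table
#'
#' The ledger table has one row per secondary species (an unresolved
#' species complex counts as a single row, its clade letters recorded
#' in `clade_letters`). Columns: `primary_morphospecies`,
#' `secondary_species`, `mb_base` (`MB`, `MB1`, `MB2`, ...), `clade_letters`
#' (e.g. `"a-f"`, empty for ordinary species), `origin` (`retained`,
#' `cryptic_split`, `reassignment`), `cryptic` (logical: this row
#' carries cryptic-species evidence), and per-locus sequence counts
#' `n_coi`, `n_16s` (`NA` where a merged cell in the source survey made
#' per-species counts indeterminable).
#'
#' @param path Path to a TSV file.
#' @return A data frame.
#' @export
read_species_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "", na.strings = c("NA", ""))
  req <- c("primary_morphospecies", "secondary_species", "mb_base",
           "clade_letters", "origin", "cryptic")
  miss <- setdiff(req, names(tab))
  if (length(miss)) {
    stop("species table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tab$cryptic <- as.logical(tab$cryptic)
  tab$clade_letters[is.na(tab$clade_letters)] <- ""
  tab
}

#' The packaged Antarctic polychaete species table
#'
#' A desk-scale encoding of the worked survey this package models: 15
#' deep-sea Antarctic polychaete morphospecies whose secondary
#' (molecular + re-examined morphological) identifications yielded 35
#' species.
#'
#' @return A data frame in the [read_species_table()] layout.
#' @export
example_species_table <- function() {
  read_species_table(system.file("extdata", "antarctic_polychaete_species.tsv",
                                 package = "cryptgap", mustWork = TRUE))
}

#' Tally the before/after species ledger
#'
#' Each MB-numbered species contributes one secondary species; a
#' lettered species complex contributes one in total; each reassigned
#' morphospecies contributes one. A cryptic species that replaces its
#' parent morphospecies name one-for-one is a `retained` row carrying
#' the cryptic flag: it flags the morphospecies but adds nothing to the
#' counts.
#'
#' @param species_table A data frame as from [read_species_table()] or
#'   [ledger_from_results()].
#' @return Object of class `species_ledger`: list with `primary`,
#'   `total`, `cryptic_additions`, `reassignment_additions`,
#'   `retained`, `cryptic_morphospecies` (count and names) and the
#'   input table.
#' @export
tally <- function(species_table) {
  tab <- species_table
  origins <- c("retained", "cryptic_split", "reassignment")
  bad <- setdiff(unique(tab$origin), origins)
  if (length(bad)) {
    stop("unknown origin value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  # same MB integer must not appear both plain and lettered within a
  # morphospecies
  for (msp in unique(tab$primary_morphospecies)) {
    sub <- tab[tab$primary_morphospecies == msp, ]
    is_int <- grepl("^MB[0-9]+$", sub$mb_base)
    lettered <- unique(sub$mb_base[is_int & nzchar(sub$clade_letters)])
    plain <- unique(sub$mb_base[is_int & !nzchar(sub$clade_letters)])
    clash <- intersect(lettered, plain)
    if (length(clash)) {
      stop("inconsistent MB labels in ", msp, ": ",
           paste(clash, collapse = ", "),
           " used both plain and lettered", call. = FALSE)
    }
  }
  primaries <- unique(tab$primary_morphospecies)
  primary <- length(primaries)
  total <- nrow(tab)
  cryptic_additions <- sum(tab$origin == "cryptic_split")
  reassignment_additions <- sum(tab$origin == "reassignment")
  retained <- sum(tab$origin == "retained")
  if (retained != primary) {
    stop("ledger does not reconcile: ", retained,
         " retained rows for ", primary, " primary morphospecies ",
         "(each morphospecies must retain exactly one lineage)",
         call. = FALSE)
  }
  stopifnot(total == primary + cryptic_additions + reassignment_additions)
  flagged <- vapply(primaries, function(msp)
    any(tab$cryptic[tab$primary_morphospecies == msp]), logical(1))
  structure(list(primary = primary, primary_names = primaries,
                 total = total,
                 cryptic_additions = cryptic_additions,
                 reassignment_additions = reassignment_additions,
                 retained = retained,
                 cryptic_morphospecies = sum(flagged),
                 cryptic_morphospecies_names = primaries[flagged],
                 table = tab),
            class = "species_ledger")
}

#' @export
print.species_ledger <- function(x, ...) {
  cat("<species_ledger> ", x$primary, " primary morphospecies -> ",
      x$total, " secondary species (", x$cryptic_additions,
      " cryptic additions, ", x$reassignment_additions,
      " reassignments); cryptic evidence in ", x$cryptic_morphospecies,
      " of ", x$primary, "\n", sep = "")
  invisible(x)
}

#' Species-richness ratio (percent)
#'
#' Reported as `100 * total_after / primary`, rounded to the nearest
#' integer: the after/before ratio convention, so 15 -> 35 species
#' prints as 233 (not the 133% increase).
#'
#' @param ledger A [tally()] result.
#' @return Integer percentage.
#' @export
richness_percent <- function(ledger) {
  stopifnot(ledger$primary > 0)
  round(100 * ledger$total / ledger$primary)
}

#' Prevalence of cryptic diversity among morphospecies
#'
#' @param ledger A [tally()] result.
#' @return List with `count`, `primary`, `fraction` and `percent`.
#' @export
cryptic_prevalence <- function(ledger) {
  stopifnot(ledger$primary > 0)
  frac <- ledger$cryptic_morphospecies / ledger$primary
  list(count = ledger$cryptic_morphospecies, primary = ledger$primary,
       fraction = frac, percent = 100 * frac)
}

#' Build a species ledger table from pipeline results
#'
#' Converts per-morphospecies scenario results into ledger rows: the
#' first (largest) delimited species of each morphospecies is the
#' retained lineage, further MB-numbered species are cryptic additions,
#' and a lettered complex is one retained row. Morphological
#' reassignments are not inferable from sequences and enter as input
#' annotations.
#'
#' @param results List of [delimit_morphospecies()] results.
#' @param reassignments Optional data frame with columns
#'   `primary_morphospecies`, `secondary_species` (one row per
#'   reassigned morphospecies; `cryptic` column optional, default
#'   `FALSE`).
#' @return A data frame in the [read_species_table()] layout.
#' @export
ledger_from_results <- function(results, reassignments = NULL) {
  rows <- list()
  for (res in results) {
    sp <- res$labels$species
    for (i in seq_len(nrow(sp))) {
      lab <- sp$label[i]
      complex <- sp$complex[i]
      letters_part <- if (complex) sub("^MB[0-9]*", "", lab) else ""
      base <- if (complex) sub("^(MB[0-9]*).*$", "\\1", lab) else lab
      rows[[length(rows) + 1L]] <- data.frame(
        primary_morphospecies = res$morphospecies,
        secondary_species = paste0(res$morphospecies, " (", lab, ")"),
        mb_base = base, clade_letters = letters_part,
        origin = if (i == 1L) "retained" else "cryptic_split",
        cryptic = sp$cryptic[i] ||
          (i == 1L && any(sp$cryptic)),  # flag rides on the retained row too
        n_coi = NA_integer_, n_16s = NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  if (!is.null(reassignments) && nrow(reassignments)) {
    if (!"cryptic" %in% names(reassignments)) reassignments$cryptic <- FALSE
    extra <- data.frame(
      primary_morphospecies = reassignments$primary_morphospecies,
      secondary_species = reassignments$secondary_species,
      mb_base = "MB", clade_letters = "",
      origin = "reassignment", cryptic = reassignments$cryptic,
      n_coi = NA_integer_, n_16s = NA_integer_, stringsAsFactors = FALSE)
    tab <- rbind(tab, extra)
  }
  tab
}

#' Write ledger outputs
#'
#' Writes the ledger table as TSV and the headline statistics as JSON
#' (`primary`, `cryptic_additions`, `reassignment_additions`, `total`,
#' `richness_percent`, `cryptic_prevalence_percent`).
#'
#' @param ledger A [tally()] result.
#' @param dir Output directory.
#' @return Paths written, invisibly.
#' @export
write_ledger <- function(ledger, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- file.path(dir, "species_ledger.tsv")
  js <- file.path(dir, "ledger_summary.json")
  utils::write.table(ledger$table, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  prev <- cryptic_prevalence(ledger)
  summary <- sprintf(paste0(
    '{"primary": %d, "cryptic_additions": %d, "reassignment_additions": %d, ',
    '"total": %d, "richness_percent": %d, ',
    '"cryptic_morphospecies": %d, "cryptic_prevalence_percent": %.6g}'),
    ledger$primary, ledger$cryptic_additions, ledger$reassignment_additions,
    ledger$total, richness_percent(ledger), prev$count, prev$percent)
  writeLines(summary, js)
  invisible(c(tsv, js))
}
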