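#' Default analysis thresholds
#'
#' Clade-forming distance cuts per locus (COI 0.03, 16S 0.01 — inside
#' the observed separation between sub-1% intra-clade and multi-percent
#' inter-clade barcode divergences), the node-support cutoff for
#' imported trees (0.95) and the divergence-ratio fold requirement
#' (10).
#'
#' @return Named list: `COI`, `16S` (proportions), `min_support`,
#'   `ratio_k`, `linkage`.
#' @export
default_thresholds <- function() {
  list(COI = 0.03, "16S" = 0.01, min_support = 0.95, ratio_k = 10,
       linkage = "single")
}

#' Delimit one morphospecies across its available loci
#'
#' For each locus with at least two sequences of the morphospecies:
#' compute the K2P distance matrix, partition into candidate clades
#' (from a supplied support tree when available for that locus,
#' otherwise by threshold clustering), summarise intra-/inter-clade
#' variation and delimit. The per-locus verdicts are then reconciled
#' into an evidence scenario and MB labels are assigned.
#'
#' @param alignments Named list of [locus_alignment()]s (any subset of
#'   COI, 16S).
#' @param morphospecies The focal morphospecies name.
#' @param metadata Metadata data frame (see
#'   [read_specimen_metadata()]).
#' @param thresholds See [default_thresholds()].
#' @param trees Optional named list of [read_newick_tree()] trees per
#'   locus.
#' @param reference_distances Optional numeric vector of congeneric
#'   inter-species K2P distances (%) for this morphospecies.
#' @return Object of class `morphospecies_result`: list with
#'   `morphospecies`, `scenario`, `verdicts`, `labels`, `contingency`,
#'   `notes`.
#' @export
delimit_morphospecies <- function(alignments, morphospecies, metadata,
                                  thresholds = default_thresholds(),
                                  trees = NULL,
                                  reference_distances = NULL) {
  specimens <- metadata$specimen_id[metadata$morphospecies == morphospecies]
  verdicts <- list()
  for (lc in intersect(.LOCI, names(alignments))) {
    aln <- alignments[[lc]]
    ids <- intersect(aln$ids, specimens)
    if (length(ids) < 2L) next
    sub <- subset_alignment(aln, ids)
    dm <- distance_matrix(sub)
    part <- if (!is.null(trees) && !is.null(trees[[lc]])) {
      partition_from_tree(trees[[lc]], ids,
                          min_support = thresholds$min_support,
                          morphospecies = morphospecies, locus = lc)
    } else {
      cluster_by_threshold(dm, threshold = thresholds[[lc]],
                           linkage = thresholds$linkage,
                           morphospecies = morphospecies, locus = lc)
    }
    vs <- variation_summary(part, dm)
    verdicts[[lc]] <- delimit(part, vs,
                              reference_distances = reference_distances,
                              k = thresholds$ratio_k)
  }
  if (!length(verdicts)) {
    stop("morphospecies ", morphospecies,
         ": no locus with >= 2 sequences; nothing to delimit",
         call. = FALSE)
  }
  sc <- classify_scenario(coi = verdicts[["COI"]], s16 = verdicts[["16S"]])
  labels <- assign_mb_labels(sc)
  structure(list(morphospecies = morphospecies, scenario = sc$scenario,
                 verdicts = sc$verdicts, labels = labels,
                 contingency = sc$contingency, notes = sc$notes),
            class = "morphospecies_result")
}

#' @export
print.morphospecies_result <- function(x, ...) {
  cat("<morphospecies_result> ", x$morphospecies, ": scenario ",
      x$scenario, "; species: ",
      paste(x$labels$species$label, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Run the full delimitation pipeline
#'
#' Iterates every morphospecies in the metadata, delimits it across the
#' available loci, assembles the species ledger and (optionally) writes
#' the report tables, ledger and per-locus distance matrices.
#'
#' @param alignments Named list of [locus_alignment()]s.
#' @param metadata Metadata data frame.
#' @param thresholds See [default_thresholds()].
#' @param trees Optional named list of support trees per locus.
#' @param references Optional named list (by morphospecies) of
#'   congeneric reference distance vectors (%).
#' @param reassignments Optional reassignment annotations (see
#'   [ledger_from_results()]).
#' @param out_dir Optional output directory for the report files.
#' @return Object of class `cryptgap_run`: list with `results` (one
#'   `morphospecies_result` each), `ledger` and `scenarios` (named
#'   character vector).
#' @export
run_delimitation <- function(alignments, metadata,
                             thresholds = default_thresholds(),
                             trees = NULL, references = NULL,
                             reassignments = NULL, out_dir = NULL) {
  msps <- unique(metadata$morphospecies)
  results <- list()
  for (msp in msps) {
    refs <- if (!is.null(references)) references[[msp]] else NULL
    results[[msp]] <- delimit_morphospecies(
      alignments, msp, metadata, thresholds = thresholds, trees = trees,
      reference_distances = refs)
  }
  ledger <- tally(ledger_from_results(results, reassignments))
  scenarios <- vapply(results, `[[`, character(1), "scenario")
  run <- structure(list(results = results, ledger = ledger,
                        scenarios = scenarios),
                   class = "cryptgap_run")
  if (!is.null(out_dir)) {
    write_report_tables(results, out_dir)
    write_ledger(ledger, out_dir)
  }
  run
}

#' @export
print.cryptgap_run <- function(x, ...) {
  cat("<cryptgap_run> ", length(x$results), " morphospecies; scenarios: ",
      paste(sprintf("%s=%d", names(table(x$scenarios)), table(x$scenarios)),
            collapse = ", "), "\n", sep = "")
  print(x$ledger)
  invisible(x)
}
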