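#' Reconcile per-locus delimitation verdicts into an evidence scenario
#'
#' The four scenarios: S1 — cryptic species supported coherently by
#' every available locus (a single-locus dataset with a clean cryptic
#' signal is also S1); S2 — cryptic species in COI that 16S absorbs
#' (16S present but not itself establishing cryptic species); S3 —
#' unresolved species complex or otherwise undetermined, with no locus
#' establishing cryptic species, and the conservative bucket for
#' conflicting loci; S4 — a single clade at every locus.
#'
#' @param coi,s16 `delimitation_verdict`s for COI and 16S (either may
#'   be `NULL` when the locus was not sequenced, not both).
#' @param contingency Optional [map_partition_across_loci()] result for
#'   the two partitions; computed internally when both verdicts are
#'   present and it is omitted.
#' @return Object of class `scenario_result`: list with `scenario`
#'   (`"S1"`, `"S2"`, `"S3"`, `"S4"`), `loci_used`, `verdicts`,
#'   `contingency` and `notes`.
#' @export
classify_scenario <- function(coi = NULL, s16 = NULL, contingency = NULL) {
  if (is.null(coi) && is.null(s16)) {
    stop("at least one locus verdict is required", call. = FALSE)
  }
  verdicts <- list()
  if (!is.null(coi)) verdicts[["COI"]] <- coi
  if (!is.null(s16)) verdicts[["16S"]] <- s16
  statuses <- vapply(verdicts, `[[`, character(1), "status")
  notes <- character(0)
  both <- !is.null(coi) && !is.null(s16)
  if (both && is.null(contingency)) {
    contingency <- map_partition_across_loci(coi$partition, s16$partition)
  }
  if (all(statuses == "cryptic_species")) {
    if (!both) {
      scenario <- "S1"
      if (identical(names(verdicts), "COI")) {
        notes <- c(notes, "cryptic signal from COI only (16S not sequenced)")
      }
    } else if (isTRUE(contingency$coherent)) {
      scenario <- "S1"
    } else if (is.na(contingency$coherent)) {
      scenario <- "S3"
      notes <- c(notes,
                 "no specimens shared between loci; coherence undecidable")
    } else {
      scenario <- "S3"
      notes <- c(notes, "conflict: both loci cryptic but partitions cross")
    }
  } else if (!is.null(coi) && coi$status == "cryptic_species") {
    # 16S present but not cryptic: it absorbs the COI clades
    scenario <- "S2"
  } else if (!is.null(s16) && s16$status == "cryptic_species") {
    scenario <- "S3"
    notes <- c(notes,
               "conflict: 16S cryptic but COI does not support the split")
  } else if (any(statuses %in% c("species_complex", "undetermined"))) {
    scenario <- "S3"
  } else {
    scenario <- "S4"
  }
  structure(list(scenario = scenario, loci_used = names(verdicts),
                 verdicts = verdicts, contingency = contingency,
                 notes = notes),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("<scenario_result> ", x$scenario, " (loci: ",
      paste(x$loci_used, collapse = ", "), ")\n", sep = "")
  if (length(x$notes)) cat("  note: ", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Assign MB-style species labels
#'
#' Each delimited species receives a label built from the "MB" stem:
#' distinct cryptic species get distinct integers (`MB1`, `MB2`, ...);
#' the clades of an unresolved species complex share one integer with
#' clade letters (`MB1a`, `MB1b`, ...); a morphospecies with no split
#' keeps the bare `MB`. Specimens sequenced only at a locus that cannot
#' discriminate the clades are returned in an unassigned bucket
#' labelled `MB` unless the cross-locus contingency maps their block
#' unambiguously into one discriminating clade. Numbering follows the
#' canonical clade order (size descending, then smallest specimen id).
#'
#' @param scenario_result A [classify_scenario()] result.
#' @return Object of class `mb_labels`: list with `species` (data
#'   frame: `label`, `n_specimens`, `cryptic`, `complex`),
#'   `assignments` (specimen id -> label) and `unassigned` (specimen
#'   ids labelled bare `MB`).
#' @export
assign_mb_labels <- function(scenario_result) {
  verdicts <- scenario_result$verdicts
  scenario <- scenario_result$scenario
  # discriminating verdict: the one that motivates the split
  pick <- function() {
    if (length(verdicts) == 1L) return(verdicts[[1L]])
    if (scenario == "S2") return(verdicts[["COI"]])
    nb <- vapply(verdicts, `[[`, integer(1), "n_clades")
    st <- vapply(verdicts, `[[`, character(1), "status")
    if (scenario == "S1") {
      cand <- verdicts[st == "cryptic_species"]
    } else if (scenario == "S3") {
      cand <- verdicts[st %in% c("species_complex", "undetermined")]
      if (!length(cand)) cand <- verdicts
    } else {
      cand <- verdicts
    }
    nb <- vapply(cand, `[[`, integer(1), "n_clades")
    # most clades wins; prefer COI on ties (it is the faster marker)
    ord <- order(-nb, names(cand) != "COI")
    cand[[ord[1L]]]
  }
  v <- pick()
  part <- v$partition
  blocks <- part$blocks
  n_blocks <- length(blocks)
  status <- v$status

  if (status == "single_species" || n_blocks == 1L) {
    species <- data.frame(label = "MB", n_specimens = length(blocks[[1L]]),
                          cryptic = FALSE, complex = FALSE,
                          stringsAsFactors = FALSE)
    assignments <- stats::setNames(rep("MB", length(blocks[[1L]])),
                                   blocks[[1L]])
  } else if (status == "cryptic_species") {
    labels <- paste0("MB", seq_len(n_blocks))
    species <- data.frame(label = labels, n_specimens = lengths(blocks),
                          cryptic = TRUE, complex = FALSE,
                          stringsAsFactors = FALSE)
    assignments <- stats::setNames(rep(labels, lengths(blocks)),
                                   unlist(blocks, use.names = FALSE))
  } else {
    # species complex / undetermined: one species, lettered clades
    letters_used <- letters[seq_len(n_blocks)]
    labels <- paste0("MB1", letters_used)
    species <- data.frame(label = paste0("MB1", paste0(letters_used[1L], "-",
                            letters_used[n_blocks])),
                          n_specimens = sum(lengths(blocks)),
                          cryptic = FALSE, complex = TRUE,
                          stringsAsFactors = FALSE)
    if (n_blocks == 1L) species$label <- "MB1a"
    assignments <- stats::setNames(rep(labels, lengths(blocks)),
                                   unlist(blocks, use.names = FALSE))
  }

  # specimens only sequenced at the other locus
  unassigned <- character(0)
  others <- setdiff(names(verdicts), v$locus)
  if (length(others)) {
    other <- verdicts[[others[1L]]]
    mem_other <- partition_membership(other$partition)
    extra <- setdiff(names(mem_other), names(assignments))
    ctg <- scenario_result$contingency
    for (sp in extra) {
      lab <- "MB"
      if (!is.null(ctg) && !is.null(ctg$table)) {
        # orient the contingency: rows of table are blocks of COI verdict's
        # partition (partition_a); map only when the specimen's block at
        # the other locus co-occurs with exactly one discriminating block
        tab <- ctg$table
        if (identical(v$locus, "COI")) {
          col_block <- mem_other[[sp]]
          hits <- rownames(tab)[tab[, col_block] > 0]
        } else {
          row_block <- mem_other[[sp]]
          hits <- colnames(tab)[tab[row_block, ] > 0]
        }
        if (length(hits) == 1L && status != "single_species") {
          blk_idx <- match(hits, names(blocks))
          lab <- unname(assignments[blocks[[blk_idx]][1L]])
        }
      }
      if (identical(lab, "MB")) unassigned <- c(unassigned, sp)
      assignments[sp] <- lab
    }
  }
  structure(list(species = species, assignments = assignments,
                 unassigned = unassigned, discriminating_locus = v$locus),
            class = "mb_labels")
}

#' @export
print.mb_labels <- function(x, ...) {
  cat("<mb_labels> ", nrow(x$species), " species: ",
      paste(x$species$label, collapse = ", "), sep = "")
  if (length(x$unassigned)) {
    cat(" (+", length(x$unassigned), " unassigned 'MB')", sep = "")
  }
  cat("\n")
  invisible(x)
}
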