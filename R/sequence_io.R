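#' Read a specimen metadata table
#'
#' The metadata table links specimen identifiers to their primary
#' (morphological) species assignment and, optionally, a sampling site.
#' Comma- or tab-delimited files are accepted; the delimiter is sniffed
#' from the header line.
#'
#' @param path Path to a CSV/TSV file with columns `specimen_id`,
#'   `morphospecies` and optionally `site`.
#' @return A data frame with columns `specimen_id`, `morphospecies`, `site`.
#' @export
read_specimen_metadata <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  md <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  req <- c("specimen_id", "morphospecies")
  if (!all(req %in% names(md))) {
    stop("metadata must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (!"site" %in% names(md)) md$site <- NA_character_
  if (anyDuplicated(md$specimen_id)) {
    stop("duplicated specimen_id in metadata: ",
         paste(unique(md$specimen_id[duplicated(md$specimen_id)]),
               collapse = ", "), call. = FALSE)
  }
  md[, c("specimen_id", "morphospecies", "site")]
}

#' Construct a validated single-locus alignment
#'
#' @param ids Character vector of specimen identifiers.
#' @param sequences Character vector of aligned sequences (equal length,
#'   alphabet `A C G T -` plus IUPAC ambiguity codes; case-insensitive).
#' @param locus `"COI"` or `"16S"`.
#' @param morphospecies Optional character vector (parallel to `ids`) of
#'   primary species assignments.
#' @return An object of class `locus_alignment`: a list with elements
#'   `locus`, `ids`, `morphospecies`, and `seq` (a specimen-by-site
#'   character matrix, upper case).
#' @export
locus_alignment <- function(ids, sequences, locus = c("COI", "16S"),
                            morphospecies = NULL) {
  locus <- match.arg(locus)
  if (length(ids) != length(sequences)) {
    stop("ids and sequences differ in length", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicated specimen ids in alignment: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  sequences <- toupper(sequences)
  lens <- nchar(sequences)
  if (length(unique(lens)) > 1L) {
    stop("alignment error: sequences have unequal lengths (",
         paste(sort(unique(lens)), collapse = ", "), ")", call. = FALSE)
  }
  seq_mat <- NULL
  if (length(sequences)) {
    seq_mat <- do.call(rbind, strsplit(sequences, "", fixed = TRUE))
    rownames(seq_mat) <- ids
    ok <- seq_mat %in% c(.NT, .AMBIG, .GAP)
    if (!all(ok)) {
      stop("alphabet error: illegal character(s) ",
           paste(unique(seq_mat[!ok]), collapse = " "),
           " (gaps must be '-')", call. = FALSE)
    }
  }
  if (is.null(morphospecies)) morphospecies <- rep(NA_character_, length(ids))
  structure(list(locus = locus, ids = ids,
                 morphospecies = stats::setNames(morphospecies, ids),
                 seq = seq_mat),
            class = "locus_alignment")
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat("<locus_alignment> ", x$locus, ": ", length(x$ids), " sequences x ",
      if (is.null(x$seq)) 0L else ncol(x$seq), " sites\n", sep = "")
  invisible(x)
}

#' Subset an alignment to a set of specimens
#'
#' @param aln A `locus_alignment`.
#' @param ids Specimen identifiers to keep (order preserved as in `aln`).
#' @return A `locus_alignment` over the intersection.
#' @export
subset_alignment <- function(aln, ids) {
  keep <- aln$ids %in% ids
  locus_alignment(aln$ids[keep],
                  apply(aln$seq[keep, , drop = FALSE], 1L, paste, collapse = ""),
                  locus = aln$locus,
                  morphospecies = unname(aln$morphospecies[keep]))
}

#' Read an aligned multi-FASTA file for one locus
#'
#' Headers follow the dialect `specimen_id|morphospecies|locus`; the
#' second and third fields are optional when a metadata table is
#' supplied. Sequences are case-insensitive and normalised to upper
#' case; all records must be equal length (the file is an alignment).
#'
#' @param path Path to a FASTA file.
#' @param locus `"COI"` or `"16S"`.
#' @param metadata Optional metadata data frame (see
#'   [read_specimen_metadata()]); when supplied, every record must
#'   resolve to a known specimen and morphospecies labels are taken from
#'   it.
#' @return A [locus_alignment()].
#' @export
read_fasta_alignment <- function(path, locus = c("COI", "16S"),
                                 metadata = NULL) {
  locus <- match.arg(locus)
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  fields <- strsplit(headers, "|", fixed = TRUE)
  ids <- vapply(fields, function(f) trimws(f[[1L]]), character(1))
  msp <- vapply(fields, function(f)
    if (length(f) >= 2L) trimws(f[[2L]]) else NA_character_, character(1))
  msp[!is.na(msp) & msp == ""] <- NA_character_
  hdr_locus <- vapply(fields, function(f)
    if (length(f) >= 3L) trimws(f[[3L]]) else NA_character_, character(1))
  if (any(!is.na(hdr_locus) & hdr_locus != locus)) {
    stop("locus mismatch: header declares ",
         paste(unique(hdr_locus[!is.na(hdr_locus) & hdr_locus != locus]),
               collapse = ", "), " but reading as ", locus, call. = FALSE)
  }
  if (!is.null(metadata)) {
    unknown <- setdiff(ids, metadata$specimen_id)
    if (length(unknown)) {
      stop("unknown specimen(s) not in metadata: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    msp <- metadata$morphospecies[match(ids, metadata$specimen_id)]
  }
  locus_alignment(ids, as.character(set), locus = locus, morphospecies = msp)
}

#' Write a locus alignment as multi-FASTA
#'
#' Headers use the `specimen_id|morphospecies|locus` dialect (fields
#' omitted when the morphospecies is unknown).
#'
#' @param aln A `locus_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(aln$ids)) {
    msp <- aln$morphospecies[[i]]
    # always three fields; empty morphospecies keeps the layout unambiguous
    hdr <- paste(aln$ids[i], if (is.na(msp)) "" else msp, aln$locus,
                 sep = "|")
    writeLines(c(paste0(">", hdr),
                 paste(aln$seq[i, ], collapse = "")), con)
  }
  invisible(path)
}

#' Read a Newick tree with node-support values
#'
#' Internal-node labels are parsed as posterior probabilities in
#' \[0, 1\]; missing labels are recorded as `NA` (absent), never as
#' zero.
#'
#' @param path Path to a Newick file, or a Newick string.
#' @param outgroup Optional character vector of outgroup leaf names.
#' @return An object of class `support_tree`: list with `tree` (an
#'   [ape::read.tree()] phylo), `support` (numeric, one per internal
#'   node) and `outgroup`.
#' @export
read_newick_tree <- function(path, outgroup = NULL) {
  tr <- tryCatch(
    if (file.exists(path)) ape::read.tree(path) else ape::read.tree(text = path),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo")) {
    stop("Newick parse error: ", path, call. = FALSE)
  }
  if (anyDuplicated(tr$tip.label)) {
    stop("identity error: duplicate leaf name(s): ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]),
               collapse = ", "), call. = FALSE)
  }
  supp <- rep(NA_real_, tr$Nnode)
  if (!is.null(tr$node.label)) {
    lab <- tr$node.label
    lab[lab == ""] <- NA_character_
    supp <- suppressWarnings(as.numeric(lab))
    if (any(!is.na(lab) & is.na(supp))) {
      stop("support parse error: non-numeric node label(s): ",
           paste(unique(lab[!is.na(lab) & is.na(supp)]), collapse = ", "),
           call. = FALSE)
    }
  }
  if (any(supp < 0 | supp > 1, na.rm = TRUE)) {
    stop("node supports must be posterior probabilities in [0, 1]",
         call. = FALSE)
  }
  if (!is.null(outgroup)) {
    missing_og <- setdiff(outgroup, tr$tip.label)
    if (length(missing_og)) {
      stop("outgroup leaf/leaves not in tree: ",
           paste(missing_og, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(tree = tr, support = supp, outgroup = outgroup),
            class = "support_tree")
}

#' Serialize a support tree back to Newick
#'
#' @param x A `support_tree`.
#' @param path Optional output path; when `NULL` the Newick string is
#'   returned.
#' @return The Newick string (invisibly when written to file).
#' @export
write_newick_tree <- function(x, path = NULL) {
  tr <- x$tree
  tr$node.label <- ifelse(is.na(x$support), "",
                          format(x$support, trim = TRUE, digits = 15))
  if (is.null(path)) return(ape::write.tree(tr))
  ape::write.tree(tr, file = path)
  invisible(ape::write.tree(tr))
}

#' Write per-morphospecies report tables
#'
#' Emits two tab-delimited files: a per-species table (primary name,
#' secondary MB label, cryptic verdict, per-locus sequence counts) and a
#' divergence table of mean intra- and inter-clade K2P (%) per
#' morphospecies per locus.
#'
#' @param results A list of per-morphospecies results as returned by
#'   [delimit_morphospecies()] (possibly empty).
#' @param dir Output directory (created if needed).
#' @return Character vector of the two paths written, invisibly.
#' @export
write_report_tables <- function(results, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sp_path <- file.path(dir, "species_report.tsv")
  dv_path <- file.path(dir, "divergence_report.tsv")

  sp_cols <- c("primary_morphospecies", "secondary_label", "scenario",
               "cryptic", "n_specimens", "n_coi", "n_16s")
  dv_cols <- c("morphospecies", "locus", "n_clades", "mean_intra_pct",
               "mean_inter_pct", "max_intra_pct", "min_inter_pct",
               "gap_pct", "ratio", "status", "n_saturated_excluded")
  sp <- as.data.frame(stats::setNames(rep(list(character(0)), length(sp_cols)),
                                      sp_cols))
  dv <- as.data.frame(stats::setNames(rep(list(character(0)), length(dv_cols)),
                                      dv_cols))
  for (res in results) {
    n_by_locus <- vapply(.LOCI, function(lc) {
      v <- res$verdicts[[lc]]
      if (is.null(v)) 0L else length(unlist(v$partition$blocks))
    }, integer(1))
    lab <- res$labels
    for (i in seq_len(nrow(lab$species))) {
      sp <- rbind(sp, data.frame(
        primary_morphospecies = res$morphospecies,
        secondary_label = lab$species$label[i],
        scenario = res$scenario,
        cryptic = lab$species$cryptic[i],
        n_specimens = lab$species$n_specimens[i],
        n_coi = n_by_locus[["COI"]], n_16s = n_by_locus[["16S"]],
        stringsAsFactors = FALSE))
    }
    for (lc in names(res$verdicts)) {
      v <- res$verdicts[[lc]]
      s <- v$summary
      dv <- rbind(dv, data.frame(
        morphospecies = res$morphospecies, locus = lc,
        n_clades = v$n_clades,
        mean_intra_pct = s$mean_intra, mean_inter_pct = s$mean_inter,
        max_intra_pct = s$max_intra, min_inter_pct = s$min_inter,
        gap_pct = v$gap_pct, ratio = v$ratio, status = v$status,
        n_saturated_excluded = s$n_saturated_excluded,
        stringsAsFactors = FALSE))
    }
  }
  utils::write.table(sp, sp_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dv, dv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(sp_path, dv_path))
}
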