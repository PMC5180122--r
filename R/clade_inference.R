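#' Construct a clade partition
#'
#' A partition of one morphospecies' sequenced specimens (at one locus)
#' into disjoint non-empty candidate clades. Blocks are stored in a
#' canonical order — decreasing size, ties broken by the
#' lexicographically smallest specimen id — and named `C1`, `C2`, ...;
#' downstream MB numbering inherits this order.
#'
#' @param blocks List of non-empty, disjoint character vectors of
#'   specimen ids.
#' @param morphospecies,locus Labels carried along for reporting.
#' @param provenance Free-form description of how the partition was
#'   obtained (clustering parameters or tree support cutoff).
#' @return An object of class `clade_partition`.
#' @export
clade_partition <- function(blocks, morphospecies = NA_character_,
                            locus = NA_character_,
                            provenance = "manual") {
  if (!length(blocks) || any(lengths(blocks) == 0L)) {
    stop("blocks must be non-empty", call. = FALSE)
  }
  all_ids <- unlist(blocks, use.names = FALSE)
  if (anyDuplicated(all_ids)) {
    stop("blocks are not disjoint: ",
         paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "),
         call. = FALSE)
  }
  blocks <- lapply(blocks, function(b) sort(as.character(b)))
  ord <- order(-lengths(blocks),
               vapply(blocks, `[[`, character(1), 1L))
  blocks <- blocks[ord]
  names(blocks) <- paste0("C", seq_along(blocks))
  structure(list(morphospecies = morphospecies, locus = locus,
                 blocks = blocks, provenance = provenance),
            class = "clade_partition")
}

#' @export
print.clade_partition <- function(x, ...) {
  cat("<clade_partition> ", x$morphospecies, " / ", x$locus, ": ",
      length(x$blocks), " clade(s) over ",
      length(unlist(x$blocks)), " specimens [", x$provenance, "]\n",
      sep = "")
  invisible(x)
}

#' Block membership as a named vector
#' @param x A `clade_partition`.
#' @return Named character vector: specimen id -> block name.
#' @export
partition_membership <- function(x) {
  stats::setNames(rep(names(x$blocks), lengths(x$blocks)),
                  unlist(x$blocks, use.names = FALSE))
}

#' Infer clades by agglomerative clustering of the distance matrix
#'
#' Agglomerative clustering (single linkage by default, mirroring clade
#' connectivity; average linkage available for robustness checks) cut
#' at the given distance. Merging is strict: only joins at distance
#' `< threshold` are kept, so ties at exactly the threshold separate.
#' Saturated or insufficient pairs are treated as farther than any
#' threshold.
#'
#' @param distmat A `k2p_distmat` over one morphospecies' specimens.
#' @param threshold Distance cut (proportion scale; e.g. 0.03 for COI,
#'   0.01 for 16S).
#' @param linkage `"single"` (default) or `"average"`.
#' @param morphospecies,locus Labels for the partition.
#' @return A [clade_partition()].
#' @export
cluster_by_threshold <- function(distmat, threshold,
                                 linkage = c("single", "average"),
                                 morphospecies = NA_character_,
                                 locus = NA_character_) {
  linkage <- match.arg(linkage)
  n <- length(distmat$ids)
  if (n == 0L) stop("empty distance matrix", call. = FALSE)
  prov <- sprintf("threshold-clustering(linkage=%s, threshold=%g)",
                  linkage, threshold)
  if (n == 1L) {
    return(clade_partition(list(distmat$ids), morphospecies, locus, prov))
  }
  d <- distmat$d
  big <- max(d[is.finite(d)], 0) + threshold + 1
  d[!is.finite(d)] <- big
  d[distmat$flags != "ok"] <- big
  diag(d) <- 0
  hc <- stats::hclust(stats::as.dist(d), method = linkage)
  k <- n - sum(hc$height < threshold)
  grp <- stats::cutree(hc, k = k)
  blocks <- split(names(grp), grp)
  clade_partition(unname(blocks), morphospecies, locus, prov)
}

#' Extract supported clades from an imported tree
#'
#' Candidate clades are the maximal monophyletic groups consisting only
#' of the focal morphospecies' specimens whose defining node has
#' posterior support at or above `min_support`. Specimens falling in no
#' supported group become singletons.
#'
#' @param tree A [read_newick_tree()] `support_tree` whose leaves
#'   include all of `specimens`.
#' @param specimens Character vector: the morphospecies' sequenced
#'   specimens.
#' @param min_support Support cutoff (default 0.95, the conventional
#'   posterior-probability significance mark).
#' @param morphospecies,locus Labels for the partition.
#' @return A [clade_partition()].
#' @export
partition_from_tree <- function(tree, specimens, min_support = 0.95,
                                morphospecies = NA_character_,
                                locus = NA_character_) {
  tr <- tree$tree
  missing_ids <- setdiff(specimens, tr$tip.label)
  if (length(missing_ids)) {
    stop("specimen(s) absent from tree: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  ntip <- length(tr$tip.label)
  kids <- .tips_per_node(tr)
  candidates <- list()
  for (i in seq_len(tr$Nnode)) {
    tips <- tr$tip.label[kids[[i]]]
    supp <- tree$support[i]
    if (length(tips) >= 2L && all(tips %in% specimens) &&
        !is.na(supp) && supp >= min_support) {
      candidates[[length(candidates) + 1L]] <- tips
    }
  }
  # clades are laminar: keep only those not contained in a larger one
  keep <- rep(TRUE, length(candidates))
  for (i in seq_along(candidates)) {
    for (j in seq_along(candidates)) {
      if (i != j && keep[i] &&
          all(candidates[[i]] %in% candidates[[j]]) &&
          length(candidates[[i]]) < length(candidates[[j]])) {
        keep[i] <- FALSE
      }
    }
  }
  blocks <- candidates[keep]
  assigned <- unlist(blocks, use.names = FALSE)
  singletons <- setdiff(specimens, assigned)
  blocks <- c(blocks, as.list(singletons))
  clade_partition(blocks, morphospecies, locus,
                  provenance = sprintf("tree(min_support=%g)", min_support))
}

# tip indices descending from each internal node, in node order
# (internal node ntip + i  ->  element i)
.tips_per_node <- function(tr) {
  ntip <- length(tr$tip.label)
  res <- vector("list", tr$Nnode)
  # postorder so children are resolved before parents
  reord <- ape::reorder.phylo(tr, "postorder")
  tmp <- vector("list", ntip + tr$Nnode)
  for (i in seq_len(ntip)) tmp[[i]] <- i
  for (e in seq_len(nrow(reord$edge))) {
    par <- reord$edge[e, 1L]; child <- reord$edge[e, 2L]
    tmp[[par]] <- c(tmp[[par]], tmp[[child]])
  }
  for (i in seq_len(tr$Nnode)) res[[i]] <- tmp[[ntip + i]]
  res
}

#' Cross-locus contingency of two clade partitions
#'
#' Restricted to the specimens sequenced at both loci, counts how the
#' blocks of one partition distribute over the blocks of the other.
#' Specimens sequenced at only one locus are listed as unassigned at
#' the other. Coherence holds when no two blocks of one locus each
#' split across the same two blocks of the other (no 2x2 all-positive
#' submatrix) — the weakest formal reading of "the clade groupings
#' were consistent across the two genes".
#'
#' @param partition_a,partition_b `clade_partition`s for the same
#'   morphospecies at two loci.
#' @return Object of class `locus_contingency`: list with `table`
#'   (blocks of a x blocks of b), `shared`, `only_a`, `only_b`, and
#'   `coherent` (`TRUE`/`FALSE`, or `NA` when no shared specimens make
#'   coherence undecidable).
#' @export
map_partition_across_loci <- function(partition_a, partition_b) {
  ma <- partition_membership(partition_a)
  mb <- partition_membership(partition_b)
  shared <- intersect(names(ma), names(mb))
  only_a <- setdiff(names(ma), names(mb))
  only_b <- setdiff(names(mb), names(ma))
  if (!length(shared)) {
    return(structure(list(table = NULL, shared = character(0),
                          only_a = only_a, only_b = only_b,
                          coherent = NA),
                     class = "locus_contingency"))
  }
  tab <- table(factor(ma[shared], levels = names(partition_a$blocks)),
               factor(mb[shared], levels = names(partition_b$blocks)))
  coherent <- !.has_crossing(unclass(tab))
  structure(list(table = tab, shared = shared, only_a = only_a,
                 only_b = only_b, coherent = coherent),
            class = "locus_contingency")
}

# TRUE if some pair of rows and pair of columns are all positive
.has_crossing <- function(m) {
  pos <- m > 0
  nr <- nrow(pos)
  if (nr < 2L || ncol(pos) < 2L) return(FALSE)
  for (i in seq_len(nr - 1L)) {
    for (j in (i + 1L):nr) {
      if (sum(pos[i, ] & pos[j, ]) >= 2L) return(TRUE)
    }
  }
  FALSE
}

#' Write clade partitions as TSV
#'
#' @param partitions A `clade_partition` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partitions, path) {
  if (inherits(partitions, "clade_partition")) partitions <- list(partitions)
  rows <- do.call(rbind, lapply(partitions, function(p) {
    mem <- partition_membership(p)
    data.frame(specimen_id = names(mem), morphospecies = p$morphospecies,
               locus = p$locus, clade_label = unname(mem),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
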