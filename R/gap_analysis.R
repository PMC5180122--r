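#' Intra- and inter-clade divergence summary
#'
#' Computes, for one morphospecies at one locus, the per-clade
#' intra-clade and per-clade-pair inter-clade pairwise K2P statistics,
#' plus pooled overall means. All values are reported in percent (x100),
#' the scale used for barcoding divergences. Means are plain arithmetic
#' means of the pooled pairwise distances; saturated pairs are excluded
#' from every statistic and counted.
#'
#' @param partition A [clade_partition()].
#' @param distmat A `k2p_distmat` covering (at least) the partition's
#'   specimens.
#' @return Object of class `variation_summary`: list with `intra` and
#'   `inter` data frames (mean/min/max %, pair counts, saturated
#'   counts; `NA` where no pair exists, e.g. singleton clades), pooled
#'   `mean_intra`, `mean_inter`, `max_intra`, `min_inter` (%), pair
#'   totals and `n_saturated_excluded`.
#' @export
variation_summary <- function(partition, distmat) {
  ids <- unlist(partition$blocks, use.names = FALSE)
  missing_ids <- setdiff(ids, distmat$ids)
  if (length(missing_ids)) {
    stop("partition specimens absent from distance matrix: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  blocks <- partition$blocks
  bn <- names(blocks)
  stat_row <- function(v, n_sat) {
    v <- v[!is.na(v)]
    if (!length(v)) {
      data.frame(n_pairs = 0L, mean = NA_real_, min = NA_real_,
                 max = NA_real_, n_saturated = n_sat)
    } else {
      data.frame(n_pairs = length(v), mean = 100 * mean(v),
                 min = 100 * min(v), max = 100 * max(v),
                 n_saturated = n_sat)
    }
  }
  pair_vals <- function(a, b) {
    sub_d <- distmat$d[a, b, drop = FALSE]
    sub_f <- distmat$flags[a, b, drop = FALSE]
    if (identical(a, b)) {
      keep <- upper.tri(sub_d)
      list(v = sub_d[keep & sub_f == "ok"],
           sat = sum(keep & sub_f == "saturated"))
    } else {
      list(v = sub_d[sub_f == "ok"], sat = sum(sub_f == "saturated"))
    }
  }
  intra <- do.call(rbind, lapply(bn, function(cl) {
    pv <- pair_vals(blocks[[cl]], blocks[[cl]])
    cbind(data.frame(clade = cl, n = length(blocks[[cl]])),
          stat_row(pv$v, pv$sat))
  }))
  inter <- NULL
  if (length(bn) >= 2L) {
    combs <- utils::combn(bn, 2L)
    inter <- do.call(rbind, lapply(seq_len(ncol(combs)), function(k) {
      a <- combs[1L, k]; b <- combs[2L, k]
      pv <- pair_vals(blocks[[a]], blocks[[b]])
      cbind(data.frame(clade_a = a, clade_b = b), stat_row(pv$v, pv$sat))
    }))
  }
  pool <- function(which) {
    vals <- numeric(0); sat <- 0L
    for (cl in bn) {
      if (which == "intra") {
        pv <- pair_vals(blocks[[cl]], blocks[[cl]])
        vals <- c(vals, pv$v); sat <- sat + pv$sat
      }
    }
    if (which == "inter" && length(bn) >= 2L) {
      combs <- utils::combn(bn, 2L)
      for (k in seq_len(ncol(combs))) {
        pv <- pair_vals(blocks[[combs[1L, k]]], blocks[[combs[2L, k]]])
        vals <- c(vals, pv$v); sat <- sat + pv$sat
      }
    }
    list(vals = vals, sat = sat)
  }
  pi_ <- pool("intra"); pe <- pool("inter")
  structure(list(
    morphospecies = partition$morphospecies, locus = partition$locus,
    clades = stats::setNames(lengths(blocks), bn),
    intra = intra, inter = inter,
    mean_intra = if (length(pi_$vals)) 100 * mean(pi_$vals) else NA_real_,
    mean_inter = if (length(pe$vals)) 100 * mean(pe$vals) else NA_real_,
    max_intra = if (length(pi_$vals)) 100 * max(pi_$vals) else NA_real_,
    min_inter = if (length(pe$vals)) 100 * min(pe$vals) else NA_real_,
    n_intra_pairs = length(pi_$vals), n_inter_pairs = length(pe$vals),
    n_saturated_excluded = pi_$sat + pe$sat),
    class = "variation_summary")
}

#' @export
print.variation_summary <- function(x, ...) {
  cat("<variation_summary> ", x$morphospecies, " / ", x$locus, ": ",
      length(x$clades), " clade(s); mean intra ",
      formatC(x$mean_intra, digits = 3), "%, mean inter ",
      formatC(x$mean_inter, digits = 3), "%\n", sep = "")
  invisible(x)
}

#' Barcoding-gap statistic
#'
#' The gap is the minimum inter-clade pairwise distance minus the
#' maximum intra-clade pairwise distance (percent); a gap is present
#' when the two distributions do not overlap (`gap > 0`).
#'
#' @param summary A [variation_summary()].
#' @return List with `gap_pct`, `present`, and `status` (`"ok"`,
#'   `"undefined"` with fewer than 2 clades, `"undecidable"` when only
#'   singleton clades leave no intra-clade pair).
#' @export
barcoding_gap <- function(summary) {
  if (length(summary$clades) < 2L) {
    return(list(gap_pct = NA_real_, present = NA, status = "undefined"))
  }
  if (summary$n_intra_pairs == 0L || summary$n_inter_pairs == 0L) {
    return(list(gap_pct = NA_real_, present = NA, status = "undecidable"))
  }
  gap <- summary$min_inter - summary$max_intra
  list(gap_pct = gap, present = gap > 0, status = "ok")
}

#' Divergence-ratio rule of thumb
#'
#' Passes when the mean inter-clade divergence is at least `k` times
#' the mean intra-clade divergence (default `k = 10`, the conventional
#' rule of thumb for flagging cryptic species). Zero intra-clade
#' variation with positive inter-clade divergence passes; both zero
#' fails.
#'
#' @param summary A [variation_summary()].
#' @param k Required fold difference.
#' @return List with `ratio`, `pass` and `k`.
#' @export
ratio_rule <- function(summary, k = 10) {
  mi <- summary$mean_intra; me <- summary$mean_inter
  if (is.na(me)) return(list(ratio = NA_real_, pass = NA, k = k))
  if (is.na(mi)) return(list(ratio = NA_real_, pass = NA, k = k))
  if (mi == 0) {
    return(list(ratio = if (me > 0) Inf else NaN, pass = me > 0, k = k))
  }
  ratio <- me / mi
  list(ratio = ratio, pass = ratio >= k, k = k)
}

#' Delimit one morphospecies at one locus
#'
#' Decision rule: a single clade is a single species. With two or more
#' clades, a present barcoding gap together with a passing divergence
#' ratio gives cryptic species; failing that, an inter-clade divergence
#' at least as large as the smallest divergence among supplied
#' congeneric reference species still gives cryptic species (with a
#' note); otherwise the intra- and inter-clade variation overlap and
#' the morphospecies is an unresolved species complex. A partition of
#' only singletons (no intra-clade pair anywhere) is undetermined.
#'
#' @param partition A [clade_partition()].
#' @param summary The matching [variation_summary()].
#' @param reference_distances Optional numeric vector of inter-species
#'   K2P distances (%) among known congeners, used as external
#'   calibration when the gap/ratio evidence is weak.
#' @param k Ratio-rule fold requirement (default 10).
#' @return Object of class `delimitation_verdict`: list with `status`
#'   (`cryptic_species`, `species_complex`, `single_species`,
#'   `undetermined`), `gap_pct`, `gap_present`, `ratio`, `ratio_pass`,
#'   `n_clades`, `notes`, and the input `summary` and `partition`.
#' @export
delimit <- function(partition, summary, reference_distances = NULL, k = 10) {
  n_clades <- length(partition$blocks)
  gap <- barcoding_gap(summary)
  rr <- ratio_rule(summary, k = k)
  notes <- character(0)
  if (n_clades == 1L) {
    status <- "single_species"
  } else if (summary$n_intra_pairs == 0L || summary$n_inter_pairs == 0L) {
    status <- "undetermined"
    notes <- c(notes, "no defined intra- or inter-clade pairs (singletons)")
  } else if (isTRUE(gap$present) && isTRUE(rr$pass)) {
    status <- "cryptic_species"
  } else if (!is.null(reference_distances) &&
             length(reference_distances) &&
             summary$mean_inter >= min(reference_distances)) {
    status <- "cryptic_species"
    notes <- c(notes, sprintf(
      "no clear gap/ratio but mean inter-clade divergence %.2f%% is within the congeneric reference range (min %.2f%%)",
      summary$mean_inter, min(reference_distances)))
  } else {
    status <- "species_complex"
    notes <- c(notes,
               "intra- and inter-clade variation overlap; clades unresolved")
  }
  structure(list(status = status, gap_pct = gap$gap_pct,
                 gap_present = gap$present, ratio = rr$ratio,
                 ratio_pass = rr$pass, n_clades = n_clades,
                 morphospecies = partition$morphospecies,
                 locus = partition$locus, notes = notes,
                 summary = summary, partition = partition),
            class = "delimitation_verdict")
}

#' @export
print.delimitation_verdict <- function(x, ...) {
  cat("<delimitation_verdict> ", x$morphospecies, " / ", x$locus, ": ",
      x$status, " (", x$n_clades, " clade(s); gap ",
      formatC(x$gap_pct, digits = 3), "%, ratio ",
      formatC(x$ratio, digits = 3), ")\n", sep = "")
  if (length(x$notes)) cat("  note: ", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}
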