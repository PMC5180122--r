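# Shared fixture builders and independent oracles.

# small alignment from raw strings
aln_from <- function(ids, seqs, locus = "COI", msp = NULL) {
  locus_alignment(ids, seqs, locus = locus, morphospecies = msp)
}

# two-clade toy alignment: clade 1 all `base`, clade 2 with `k` fixed
# transversions relative to base
two_clade_alignment <- function(n_per = 3, L = 60, k = 12, locus = "COI") {
  base <- paste(rep(c("A", "C", "G", "T"), length.out = L), collapse = "")
  alt <- .subst_transversions(base, k)
  ids <- c(sprintf("A%02d", seq_len(n_per)), sprintf("B%02d", seq_len(n_per)))
  aln_from(ids, c(rep(base, n_per), rep(alt, n_per)), locus = locus,
           msp = rep("Msp01", 2 * n_per))
}

.subst_transversions <- function(s, k) {
  v <- strsplit(s, "")[[1]]
  swap <- c(A = "C", C = "A", G = "T", T = "G")
  v[seq_len(k)] <- swap[v[seq_len(k)]]
  paste(v, collapse = "")
}

# random symmetric "distance matrix" object with all-ok flags
random_distmat <- function(n, max_d = 0.2) {
  ids <- sprintf("S%02d", seq_len(n))
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  vals <- stats::runif(n * (n - 1) / 2, 0, max_d)
  d[upper.tri(d)] <- vals
  d <- d + t(d)
  structure(list(ids = ids, d = d,
                 L = matrix(100L, n, n, dimnames = dimnames(d)),
                 flags = matrix("ok", n, n, dimnames = dimnames(d)),
                 model = "k2p"),
            class = "k2p_distmat")
}

# oracle: connected components of the graph with edges d < threshold
components_oracle <- function(distmat, threshold) {
  n <- length(distmat$ids)
  adj <- distmat$d < threshold & distmat$flags == "ok"
  diag(adj) <- TRUE
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (adj[i, j] && comp[j] != comp[i]) {
          new <- min(comp[i], comp[j])
          comp[comp == comp[i] | comp == comp[j]] <- new
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  unname(split(distmat$ids, comp))
}

# canonical form of a partition (set of sorted blocks) for comparison
canon_blocks <- function(blocks) {
  blocks <- unname(lapply(blocks, function(b) sort(unname(b))))
  blocks[order(vapply(blocks, `[[`, character(1), 1L))]
}

# fabricate a delimitation verdict with a given clade structure; used
# to drive the scenario classifier without sequence data
fake_verdict <- function(blocks, status, locus,
                         morphospecies = "Msp01",
                         gap = NA_real_, ratio = NA_real_) {
  part <- clade_partition(blocks, morphospecies = morphospecies,
                          locus = locus, provenance = "fixture")
  structure(list(status = status, gap_pct = gap,
                 gap_present = if (is.na(gap)) NA else gap > 0,
                 ratio = ratio, ratio_pass = if (is.na(ratio)) NA else ratio >= 10,
                 n_clades = length(part$blocks),
                 morphospecies = morphospecies, locus = locus,
                 notes = character(0), summary = NULL, partition = part),
            class = "delimitation_verdict")
}

# random species-ledger table for reconciliation properties
random_species_table <- function(n_msp = 6) {
  rows <- list()
  for (m in seq_len(n_msp)) {
    msp <- sprintf("Rsp%02d", m)
    n_cryptic <- sample(0:3, 1)
    n_reass <- sample(0:2, 1)
    labels <- if (n_cryptic > 0) paste0("MB", seq_len(n_cryptic + 1)) else "MB"
    for (i in seq_along(labels)) {
      rows[[length(rows) + 1L]] <- data.frame(
        primary_morphospecies = msp,
        secondary_species = paste0(msp, " (", labels[i], ")"),
        mb_base = labels[i], clade_letters = "",
        origin = if (i == 1L) "retained" else "cryptic_split",
        cryptic = n_cryptic > 0, n_coi = NA_integer_, n_16s = NA_integer_,
        stringsAsFactors = FALSE)
    }
    for (r in seq_len(n_reass)) {
      rows[[length(rows) + 1L]] <- data.frame(
        primary_morphospecies = msp,
        secondary_species = sprintf("%s reassigned %d (MB)", msp, r),
        mb_base = "MB", clade_letters = "",
        origin = "reassignment", cryptic = FALSE,
        n_coi = NA_integer_, n_16s = NA_integer_, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
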