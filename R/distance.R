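#' Count comparable sites, transitions and transversions for one pair
#'
#' Sites where either sequence carries a gap or any ambiguity code are
#' excluded from the comparison (pairwise deletion). Transitions are
#' purine-purine (A/G) or pyrimidine-pyrimidine (C/T) differences;
#' every other difference is a transversion.
#'
#' @param seq_a,seq_b Aligned sequences of equal length: strings or
#'   character vectors of residues.
#' @return An object of class `pair_counts`: list with `L` (comparable
#'   sites), `ts`, `tv`, and the proportions `P = ts/L`, `Q = tv/L`
#'   (`NA` when `L == 0`).
#' @export
pair_counts <- function(seq_a, seq_b) {
  if (is.character(seq_a) && length(seq_a) == 1L) seq_a <- .chars(toupper(seq_a))
  if (is.character(seq_b) && length(seq_b) == 1L) seq_b <- .chars(toupper(seq_b))
  if (length(seq_a) != length(seq_b)) {
    stop("sequences differ in length", call. = FALSE)
  }
  a <- .encode_seq(seq_a)
  b <- .encode_seq(seq_b)
  .pair_counts_int(a, b)
}

# integer-coded fast path shared with distance_matrix() and the simulator
.pair_counts_int <- function(a, b) {
  cmp <- !is.na(a) & !is.na(b)
  L <- sum(cmp)
  a <- a[cmp]; b <- b[cmp]
  diff <- a != b
  # purines code 1 (A) and 3 (G): same parity <=> same chemical class
  ts <- sum(diff & (a %% 2L == b %% 2L))
  tv <- sum(diff) - ts
  structure(list(L = L, ts = ts, tv = tv,
                 P = if (L > 0) ts / L else NA_real_,
                 Q = if (L > 0) tv / L else NA_real_),
            class = "pair_counts")
}

#' Kimura two-parameter distance from pair counts
#'
#' Implements the two-parameter correction
#' \deqn{d = -\tfrac12 \ln\big[(1 - 2P - Q)\sqrt{1 - 2Q}\big]}
#' where `P` and `Q` are the observed transition and transversion
#' proportions. When the logarithm's argument is not positive the pair
#' is saturated and no finite distance exists; such pairs are flagged
#' and later excluded from summary means rather than clamped.
#'
#' @param counts A [pair_counts()] object.
#' @return List with `distance` (proportion scale; `NA` unless status
#'   is `"ok"`) and `status` in `ok`, `saturated`, `insufficient`.
#' @export
k2p <- function(counts) {
  if (counts$L == 0L) {
    return(list(distance = NA_real_, status = "insufficient"))
  }
  d <- k2p_pq(counts$P, counts$Q)
  if (!is.finite(d)) {
    return(list(distance = NA_real_, status = "saturated"))
  }
  list(distance = d, status = "ok")
}

#' K2P distance directly from transition/transversion proportions
#'
#' Vectorised over `P` and `Q`; returns `NaN` outside the formula's
#' domain (saturation).
#'
#' @param P,Q Observed transition and transversion proportions.
#' @return Numeric distances (substitutions per site).
#' @export
k2p_pq <- function(P, Q) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  out <- rep(NaN, length(w1))
  ok <- w1 > 0 & w2 > 0
  out[ok] <- -0.5 * log(w1[ok]) - 0.25 * log(w2[ok])
  out
}

#' Uncorrected p-distance from pair counts
#'
#' @param counts A [pair_counts()] object.
#' @return List with `distance` (`(ts + tv) / L`) and `status`.
#' @export
p_distance <- function(counts) {
  if (counts$L == 0L) {
    return(list(distance = NA_real_, status = "insufficient"))
  }
  list(distance = (counts$ts + counts$tv) / counts$L, status = "ok")
}

#' Pairwise distance matrix for an alignment
#'
#' Computes all unordered specimen pairs under pairwise deletion. The
#' result is symmetric and independent of row order (up to the induced
#' permutation).
#'
#' @param alignment A [locus_alignment()] with at least 2 rows.
#' @param model `"k2p"` (default) or `"p"`.
#' @return An object of class `k2p_distmat`: list with `ids`, `d`
#'   (symmetric matrix of proportions; `NA` where not `ok`), `L`
#'   (comparable-site counts) and `flags` (`ok`, `saturated`,
#'   `insufficient`; the diagonal is `ok` with distance 0).
#' @export
distance_matrix <- function(alignment, model = c("k2p", "p")) {
  model <- match.arg(model)
  if (length(alignment$ids) < 2L) {
    stop("need at least 2 sequences for a distance matrix", call. = FALSE)
  }
  ids <- alignment$ids
  n <- length(ids)
  enc <- apply(alignment$seq, 1L, .encode_seq)   # sites x specimens
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  L <- matrix(0L, n, n, dimnames = list(ids, ids))
  flags <- matrix("ok", n, n, dimnames = list(ids, ids))
  diag(L) <- colSums(!is.na(enc))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      pc <- .pair_counts_int(enc[, i], enc[, j])
      res <- if (model == "k2p") k2p(pc) else p_distance(pc)
      d[i, j] <- d[j, i] <- res$distance
      L[i, j] <- L[j, i] <- pc$L
      flags[i, j] <- flags[j, i] <- res$status
    }
  }
  structure(list(ids = ids, d = d, L = L, flags = flags, model = model),
            class = "k2p_distmat")
}

#' @export
print.k2p_distmat <- function(x, ...) {
  n <- length(x$ids)
  off <- x$flags[upper.tri(x$flags)]
  cat("<k2p_distmat> ", n, " specimens (", x$model, "); pairs: ",
      sum(off == "ok"), " ok, ", sum(off == "saturated"), " saturated, ",
      sum(off == "insufficient"), " insufficient\n", sep = "")
  invisible(x)
}

#' @export
as.matrix.k2p_distmat <- function(x, ...) x$d

#' Write a distance matrix as square TSV
#'
#' Distances are written on the proportion scale with flags in a
#' companion column-free layout (square numeric matrix; non-`ok` cells
#' are `NA`).
#'
#' @param dm A `k2p_distmat`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dm, path) {
  out <- as.data.frame(dm$d)
  out <- cbind(specimen_id = dm$ids, out)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a distance matrix from TSV (square or lower-triangle)
#'
#' Accepts the square layout written by [write_distance_matrix()] or a
#' PHYLIP-style lower-triangle file (first column specimen ids, ragged
#' rows).
#'
#' @param path Input path.
#' @return A `k2p_distmat` (flags reconstructed: `NA` cells off the
#'   diagonal are `saturated`; `L` is unknown and set to `NA`).
#' @export
read_distance_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (length(unique(nf)) == 1L) {
    # square with header row: every line has the same field count
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, check.names = FALSE)
    ids <- as.character(tab[[1L]])
    d <- as.matrix(tab[, -1L, drop = FALSE])
  } else {
    # ragged lower triangle: id, then i-1 distances
    ids <- vapply(fields, `[[`, character(1), 1L)
    n <- length(ids)
    d <- matrix(0, n, n)
    for (i in seq_len(n)) {
      vals <- suppressWarnings(as.numeric(fields[[i]][-1L]))
      if (length(vals) != i - 1L) {
        stop("malformed lower-triangle row for ", ids[i], call. = FALSE)
      }
      if (i > 1L) d[i, seq_len(i - 1L)] <- vals
    }
    d <- d + t(d)
  }
  dimnames(d) <- list(ids, ids)
  mode(d) <- "numeric"
  flags <- matrix("ok", nrow(d), ncol(d), dimnames = dimnames(d))
  flags[is.na(d)] <- "saturated"
  diag(flags) <- "ok"
  structure(list(ids = ids, d = d,
                 L = matrix(NA_integer_, nrow(d), ncol(d),
                            dimnames = dimnames(d)),
                 flags = flags, model = "k2p"),
            class = "k2p_distmat")
}
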