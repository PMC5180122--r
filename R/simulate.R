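#' Configuration for the two-locus barcode simulator
#'
#' The simulator plants cryptic structure: each morphospecies contains
#' 1-3 genetically divergent clades, sequences evolve under the
#' continuous-time K2P substitution process, the 16S locus evolves
#' slower than COI, and specimens may be sequenced at one or both loci.
#' Planted divergences are expressed as expected pairwise K2P in
#' percent; per-locus values default to the COI-scale value times the
#' locus rate multiplier, and can be overridden per locus with a named
#' vector.
#'
#' @param n_morphospecies Number of morphospecies (default 15, a survey
#'   of the size this package models).
#' @param clades Clade count per morphospecies: single value, vector of
#'   length `n_morphospecies`, or `NULL` to draw uniformly from 1-3.
#' @param specimens_per_clade Specimens per clade (default 5).
#' @param locus_length Named sites per locus (default COI 660, the
#'   Folmer fragment; 16S 500).
#' @param rate_multiplier Named per-locus rate scaling (default COI 1,
#'   16S 1/3: COI evolves about three times faster).
#' @param kappa Transition/transversion rate ratio (default 2).
#' @param inter_pct Planted expected inter-clade K2P (%), COI scale or
#'   named per locus (default 10).
#' @param intra_pct Planted expected intra-clade K2P (%), COI scale or
#'   named per locus (default 0.5; well under 1%, the regime of low
#'   within-clade barcode variation).
#' @param locus_fraction Named probability that a specimen is
#'   sequenced at each locus (default COI 0.6, 16S 0.95: COI
#'   amplification succeeds less often). Specimens drawn with neither
#'   locus are assigned the more available one.
#' @param seed Optional integer seed; the dataset is then fully
#'   reproducible.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_morphospecies = 15, clades = NULL,
                              specimens_per_clade = 5,
                              locus_length = c(COI = 660, "16S" = 500),
                              rate_multiplier = c(COI = 1, "16S" = 1 / 3),
                              kappa = 2,
                              inter_pct = 10, intra_pct = 0.5,
                              locus_fraction = c(COI = 0.6, "16S" = 0.95),
                              seed = NULL) {
  stopifnot(n_morphospecies >= 1, specimens_per_clade >= 1, kappa > 0)
  if (!is.null(clades)) {
    stopifnot(all(clades >= 1))
    if (length(clades) == 1L) clades <- rep(clades, n_morphospecies)
    stopifnot(length(clades) == n_morphospecies)
  }
  if (any(locus_fraction < 0 | locus_fraction > 1)) {
    stop("locus_fraction must be probabilities in [0, 1]", call. = FALSE)
  }
  per_locus <- function(x, what) {
    out <- vapply(.LOCI, function(lc) {
      if (!is.null(names(x)) && lc %in% names(x)) {
        unname(x[[lc]])
      } else if (is.null(names(x)) && length(x) == 1L) {
        unname(x) * rate_multiplier[[lc]]
      } else {
        NA_real_
      }
    }, numeric(1))
    if (any(is.na(out))) {
      stop(what, " must be a single COI-scale value or a fully named ",
           "per-locus vector", call. = FALSE)
    }
    out
  }
  inter <- per_locus(inter_pct, "inter_pct")
  intra <- per_locus(intra_pct, "intra_pct")
  if (any(inter < intra)) {
    stop("planted inter-clade divergence must be >= intra-clade divergence",
         call. = FALSE)
  }
  # saturation guard: the estimator must stay inside the K2P domain at
  # the planted expectation with comfortable margin
  for (lc in .LOCI) {
    pq <- k2p_expected_pq(inter[[lc]] / 100, kappa)
    if (1 - 2 * pq$P - pq$Q <= 0.05) {
      stop("config error: planted distance ", inter[[lc]],
           "% at locus ", lc, " is too close to saturation", call. = FALSE)
    }
  }
  structure(list(n_morphospecies = n_morphospecies, clades = clades,
                 specimens_per_clade = specimens_per_clade,
                 locus_length = locus_length,
                 rate_multiplier = rate_multiplier, kappa = kappa,
                 inter_pct = stats::setNames(inter, .LOCI),
                 intra_pct = stats::setNames(intra, .LOCI),
                 locus_fraction = locus_fraction, seed = seed),
            class = "simulation_config")
}

#' Expected transition/transversion proportions under the K2P process
#'
#' Closed-form expectations at divergence `t` (expected substitutions
#' per site) with transition/transversion rate ratio `kappa`, under the
#' normalisation alpha + 2 beta = 1 so that `t` equals the K2P distance.
#'
#' @param t Expected substitutions per site.
#' @param kappa Transition/transversion rate ratio.
#' @return List with `P` and `Q`.
#' @export
k2p_expected_pq <- function(t, kappa = 2) {
  beta <- 1 / (kappa + 2)
  alpha <- kappa / (kappa + 2)
  Q <- 0.5 - 0.5 * exp(-4 * beta * t)
  P <- 0.25 + 0.25 * exp(-4 * beta * t) - 0.5 * exp(-2 * (alpha + beta) * t)
  list(P = P, Q = Q)
}

# one exact CTMC step set: evolve integer-coded sequences over branch
# length t (expected substitutions per site). The total substitution
# rate out of every state is constant (alpha + 2 beta = 1), so the
# number of events per site is Poisson(t) and each event picks a
# transition with probability kappa/(kappa+2) or one of the two
# transversions with probability 1/(kappa+2) each.
.evolve_seq <- function(x, t, kappa) {
  L <- length(x)
  if (t <= 0) return(x)
  n_events <- stats::rpois(L, t)
  p_ts <- kappa / (kappa + 2)
  ts_target <- c(3L, 4L, 1L, 2L)          # A<->G, C<->T
  tv1 <- c(2L, 1L, 2L, 1L)                # first transversion target
  tv2 <- c(4L, 3L, 4L, 3L)                # second transversion target
  active <- which(n_events > 0L)
  if (!length(active)) return(x)
  max_ev <- max(n_events)
  for (round in seq_len(max_ev)) {
    idx <- active[n_events[active] >= round]
    u <- stats::runif(length(idx))
    cur <- x[idx]
    new <- ifelse(u < p_ts, ts_target[cur],
                  ifelse(u < p_ts + (1 - p_ts) / 2, tv1[cur], tv2[cur]))
    x[idx] <- new
  }
  x
}

.int_to_string <- function(x) paste(.NT[x], collapse = "")

#' Simulate a two-locus barcoding dataset with planted cryptic clades
#'
#' For each morphospecies, a random root sequence is evolved into one
#' ancestor per clade and each specimen evolves from its clade
#' ancestor; branch lengths are calibrated by inverting the K2P
#' expected-distance relation so that expected pairwise K2P between
#' clades equals the planted inter value and within clades the planted
#' intra value. Per-locus branch lengths carry the locus rate
#' multiplier (already folded into the per-locus planted values).
#' Specimens drop loci at random per the availability fractions but
#' never lose both. Identical seeds give identical datasets.
#'
#' @param config A [simulation_config()].
#' @return List with `alignments` (named list of [locus_alignment()]s),
#'   `metadata` (specimen table), `truth` (per-specimen true clade plus
#'   the planted divergences and intended per-morphospecies scenario
#'   ingredients) and `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
    }
    set.seed(config$seed)
  }
  n_msp <- config$n_morphospecies
  clades <- config$clades
  if (is.null(clades)) clades <- sample(1:3, n_msp, replace = TRUE)
  rows <- list(COI = list(), "16S" = list())
  meta <- list()
  truth <- list()
  for (m in seq_len(n_msp)) {
    msp <- sprintf("Msp%02d", m)
    n_clades <- clades[m]
    n_spec <- n_clades * config$specimens_per_clade
    spec_ids <- sprintf("%sC%dS%02d",
                        msp,
                        rep(seq_len(n_clades), each = config$specimens_per_clade),
                        rep(seq_len(config$specimens_per_clade), n_clades))
    clade_of <- rep(seq_len(n_clades), each = config$specimens_per_clade)
    # locus availability, never empty
    has <- cbind(COI = stats::runif(n_spec) < config$locus_fraction[["COI"]],
                 "16S" = stats::runif(n_spec) < config$locus_fraction[["16S"]])
    none <- !has[, 1L] & !has[, 2L]
    fallback <- names(which.max(config$locus_fraction))
    has[none, fallback] <- TRUE
    for (lc in .LOCI) {
      L <- config$locus_length[[lc]]
      d_inter <- config$inter_pct[[lc]] / 100
      d_intra <- config$intra_pct[[lc]] / 100
      t_anc <- max(0, (d_inter - d_intra) / 2)
      t_tip <- d_intra / 2
      root <- sample.int(4L, L, replace = TRUE)
      ancestors <- lapply(seq_len(n_clades), function(cl)
        .evolve_seq(root, t_anc, config$kappa))
      for (i in seq_len(n_spec)) {
        if (!has[i, lc]) next
        s <- .evolve_seq(ancestors[[clade_of[i]]], t_tip, config$kappa)
        rows[[lc]][[length(rows[[lc]]) + 1L]] <-
          list(id = spec_ids[i], msp = msp, seq = .int_to_string(s))
      }
    }
    meta[[m]] <- data.frame(specimen_id = spec_ids, morphospecies = msp,
                            site = NA_character_,
                            has_coi = has[, "COI"], has_16s = has[, "16S"],
                            stringsAsFactors = FALSE)
    truth[[m]] <- data.frame(specimen_id = spec_ids, morphospecies = msp,
                             true_clade = clade_of, stringsAsFactors = FALSE)
  }
  alignments <- list()
  for (lc in .LOCI) {
    rl <- rows[[lc]]
    if (!length(rl)) next
    alignments[[lc]] <- locus_alignment(
      vapply(rl, `[[`, character(1), "id"),
      vapply(rl, `[[`, character(1), "seq"),
      locus = lc,
      morphospecies = vapply(rl, `[[`, character(1), "msp"))
  }
  list(alignments = alignments,
       metadata = do.call(rbind, meta),
       truth = list(specimens = do.call(rbind, truth),
                    clades = stats::setNames(clades, sprintf("Msp%02d",
                                                             seq_len(n_msp))),
                    inter_pct = config$inter_pct,
                    intra_pct = config$intra_pct),
       config = config)
}

#' Monte-Carlo consistency experiment for the K2P estimator
#'
#' Simulates independent sequence pairs diverged by an expected `t`
#' substitutions per site under the continuous-time K2P process (each
#' tip evolves `t/2` from a common random ancestor) and returns the
#' estimated K2P distance of each pair. The mean estimate converges to
#' `t` as `L` grows, which is the calibration contract of the planted
#' divergences.
#'
#' @param n_pairs Number of independent pairs.
#' @param t Expected substitutions per site between the pair.
#' @param kappa Transition/transversion rate ratio.
#' @param L Sequence length (sites).
#' @param seed Optional integer seed.
#' @return Numeric vector of `n_pairs` K2P estimates (`NaN` for
#'   saturated pairs).
#' @export
simulate_pair_distances <- function(n_pairs, t, kappa = 2, L = 10000,
                                    seed = NULL) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
    }
    set.seed(seed)
  }
  vapply(seq_len(n_pairs), function(i) {
    root <- sample.int(4L, L, replace = TRUE)
    a <- .evolve_seq(root, t / 2, kappa)
    b <- .evolve_seq(root, t / 2, kappa)
    pc <- .pair_counts_int(a, b)
    k2p_pq(pc$P, pc$Q)
  }, numeric(1))
}

#' Simulate the four-scenario validation suite
#'
#' Emits one dataset per evidence scenario, each a single morphospecies
#' with both loci fully sequenced (except S3, which is 16S-only by
#' design): S1 — three clades well separated at both loci; S2 — two
#' clades separated in COI while the planted 16S inter-clade divergence
#' equals the intra-clade divergence (16S absorbs the clades); S3 —
#' three 16S clades whose inter-clade divergence is too close to the
#' intra-clade variation for the ratio rule (an unresolved complex);
#' S4 — one clade.
#'
#' @param seed Integer seed; each bundle derives its own sub-seed.
#' @param specimens_per_clade Specimens per clade (default 5).
#' @return Named list `S1`..`S4`; each element has the
#'   [simulate_dataset()] fields plus `intended_scenario`.
#' @export
simulate_scenario_suite <- function(seed, specimens_per_clade = 5) {
  cfgs <- list(
    S1 = simulation_config(
      n_morphospecies = 1, clades = 3,
      specimens_per_clade = specimens_per_clade,
      inter_pct = 10, intra_pct = 0.4,
      locus_fraction = c(COI = 1, "16S" = 1), seed = seed * 10L + 1L),
    S2 = simulation_config(
      n_morphospecies = 1, clades = 2,
      specimens_per_clade = specimens_per_clade,
      inter_pct = c(COI = 8, "16S" = 0.4 / 3),
      intra_pct = c(COI = 0.4, "16S" = 0.4 / 3),
      locus_fraction = c(COI = 1, "16S" = 1), seed = seed * 10L + 2L),
    S3 = simulation_config(
      n_morphospecies = 1, clades = 3,
      specimens_per_clade = specimens_per_clade,
      inter_pct = c(COI = 6, "16S" = 2.5),
      intra_pct = c(COI = 0.5, "16S" = 0.5),
      locus_fraction = c(COI = 0, "16S" = 1), seed = seed * 10L + 3L),
    S4 = simulation_config(
      n_morphospecies = 1, clades = 1,
      specimens_per_clade = 2 * specimens_per_clade,
      inter_pct = 10, intra_pct = 0.4,
      locus_fraction = c(COI = 1, "16S" = 1), seed = seed * 10L + 4L))
  out <- lapply(names(cfgs), function(sc) {
    ds <- simulate_dataset(cfgs[[sc]])
    ds$intended_scenario <- sc
    ds
  })
  stats::setNames(out, names(cfgs))
}

#' Write a simulated dataset to disk
#'
#' Emits one FASTA per locus (the [read_fasta_alignment()] header
#' dialect), the specimen metadata as CSV, the simulation truth as CSV
#' and a small manifest echoing the seed.
#'
#' @param dataset A [simulate_dataset()] result.
#' @param dir Output directory.
#' @return Character vector of written paths, invisibly.
#' @export
write_simulated_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (lc in names(dataset$alignments)) {
    p <- file.path(dir, paste0("locus_", lc, ".fasta"))
    write_fasta_alignment(dataset$alignments[[lc]], p)
    paths <- c(paths, p)
  }
  mp <- file.path(dir, "metadata.csv")
  utils::write.csv(dataset$metadata, mp, row.names = FALSE)
  tp <- file.path(dir, "truth.csv")
  utils::write.csv(dataset$truth$specimens, tp, row.names = FALSE)
  mf <- file.path(dir, "manifest.txt")
  writeLines(c(sprintf("seed: %s",
                       if (is.null(dataset$config$seed)) "none"
                       else dataset$config$seed),
               sprintf("n_morphospecies: %d",
                       dataset$config$n_morphospecies),
               sprintf("inter_pct: COI=%g 16S=%g",
                       dataset$config$inter_pct[["COI"]],
                       dataset$config$inter_pct[["16S"]]),
               sprintf("intra_pct: COI=%g 16S=%g",
                       dataset$config$intra_pct[["COI"]],
                       dataset$config$intra_pct[["16S"]])), mf)
  invisible(c(paths, mp, tp, mf))
}
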