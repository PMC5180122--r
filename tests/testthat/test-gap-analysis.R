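# minimal hand-built summary for the ratio/gap arithmetic tests
fake_summary <- function(mean_intra, mean_inter, max_intra = mean_intra,
                         min_inter = mean_inter, n_clades = 2,
                         n_intra = 10L, n_inter = 10L) {
  structure(list(morphospecies = "M", locus = "COI",
                 clades = stats::setNames(rep(2L, n_clades),
                                          paste0("C", seq_len(n_clades))),
                 intra = NULL, inter = NULL,
                 mean_intra = mean_intra, mean_inter = mean_inter,
                 max_intra = max_intra, min_inter = min_inter,
                 n_intra_pairs = n_intra, n_inter_pairs = n_inter,
                 n_saturated_excluded = 0L),
            class = "variation_summary")
}

test_that("variation summary separates intra and inter pools", {
  # two clades of identical sequences at a fixed inter distance
  aln <- two_clade_alignment(n_per = 3, L = 100, k = 10)
  dm <- distance_matrix(aln)
  part <- cluster_by_threshold(dm, 0.05, morphospecies = "M", locus = "COI")
  vs <- variation_summary(part, dm)
  expect_equal(vs$mean_intra, 0)
  expect_gt(vs$mean_inter, 0)
  expect_equal(vs$n_intra_pairs, 6L)   # 2 clades x choose(3,2)
  expect_equal(vs$n_inter_pairs, 9L)
  expect_equal(vs$min_inter, vs$mean_inter)  # every inter pair is identical

  # all singletons: every intra cell undefined
  p_single <- clade_partition(as.list(aln$ids), morphospecies = "M",
                              locus = "COI")
  vs2 <- variation_summary(p_single, dm)
  expect_true(all(is.na(vs2$intra$mean)))
  expect_equal(vs2$n_intra_pairs, 0L)
})

test_that("variation summary equals brute-force recomputation over labelled pairs", {
  withr::local_seed(51)
  cfg <- simulation_config(n_morphospecies = 1, clades = 3,
                           specimens_per_clade = 4, inter_pct = 6,
                           intra_pct = 1,
                           locus_fraction = c(COI = 1, "16S" = 1), seed = 51)
  ds <- simulate_dataset(cfg)
  aln <- ds$alignments$COI
  dm <- distance_matrix(aln)
  # random (not planted) partition stresses the bookkeeping
  ids <- aln$ids
  grp <- sample(1:3, length(ids), replace = TRUE)
  grp[1:3] <- 1:3                        # keep all groups non-empty
  part <- clade_partition(split(ids, grp), morphospecies = "M",
                          locus = "COI")
  vs <- variation_summary(part, dm)
  mem <- partition_membership(part)
  intra_vals <- c(); inter_vals <- c()
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i < j && dm$flags[i, j] == "ok") {
        if (mem[[ids[i]]] == mem[[ids[j]]]) {
          intra_vals <- c(intra_vals, dm$d[i, j])
        } else {
          inter_vals <- c(inter_vals, dm$d[i, j])
        }
      }
    }
  }
  expect_equal(vs$mean_intra, 100 * mean(intra_vals))
  expect_equal(vs$mean_inter, 100 * mean(inter_vals))
  expect_equal(vs$max_intra, 100 * max(intra_vals))
  expect_equal(vs$min_inter, 100 * min(inter_vals))
  expect_equal(vs$n_intra_pairs, length(intra_vals))
  expect_equal(vs$n_inter_pairs, length(inter_vals))
})

test_that("barcoding gap is min-inter minus max-intra", {
  g <- barcoding_gap(fake_summary(0.3, 6, max_intra = 0.5, min_inter = 5))
  expect_equal(g$gap_pct, 4.5)
  expect_true(g$present)
  # overlapping ranges: gap absent
  g2 <- barcoding_gap(fake_summary(1, 2, max_intra = 2.5, min_inter = 1.8))
  expect_false(g2$present)
  # one clade: undefined
  g3 <- barcoding_gap(fake_summary(0.5, NA, n_clades = 1))
  expect_equal(g3$status, "undefined")
  # singletons only: no intra pair, undecidable
  g4 <- barcoding_gap(fake_summary(NA, 5, n_intra = 0L))
  expect_equal(g4$status, "undecidable")
})

test_that("divergence-ratio rule matches the benchmark arithmetic", {
  # classic polychaete benchmark: 16.5% between vs 0.68% within
  rr <- ratio_rule(fake_summary(0.68, 16.5))
  expect_true(rr$pass)
  expect_equal(rr$ratio, 16.5 / 0.68, tolerance = 1e-12)
  expect_gt(rr$ratio, 24)
  # 2.28% vs 0.25% fails the 10x rule (ratio ~9.1)
  rr2 <- ratio_rule(fake_summary(0.25, 2.28))
  expect_false(rr2$pass)
  expect_equal(rr2$ratio, 9.12, tolerance = 1e-12)
  # zero intra with positive inter passes; both zero fails
  expect_true(ratio_rule(fake_summary(0, 3))$pass)
  expect_false(ratio_rule(fake_summary(0, 0))$pass)
})

test_that("delimitation decision rule covers the four statuses", {
  # planted well-separated clades recover cryptic_species
  aln <- two_clade_alignment(n_per = 4, L = 400, k = 40)
  dm <- distance_matrix(aln)
  part <- cluster_by_threshold(dm, 0.03, morphospecies = "M", locus = "COI")
  v <- delimit(part, variation_summary(part, dm))
  expect_equal(v$status, "cryptic_species")

  # single clade
  p1 <- clade_partition(list(aln$ids), morphospecies = "M", locus = "COI")
  expect_equal(delimit(p1, variation_summary(p1, dm))$status,
               "single_species")

  # all singletons: undetermined
  ps <- clade_partition(as.list(aln$ids), morphospecies = "M", locus = "COI")
  expect_equal(delimit(ps, variation_summary(ps, dm))$status,
               "undetermined")
})

test_that("weak separation is a species complex unless references rescue it", {
  ids <- c("a", "b", "c", "d")
  # two clades at inter ~2.3%, intra ~0.9%: ratio < 10
  d <- matrix(0.023, 4, 4, dimnames = list(ids, ids))
  d["a", "b"] <- d["b", "a"] <- 0.009
  d["c", "d"] <- d["d", "c"] <- 0.009
  diag(d) <- 0
  dm <- structure(list(ids = ids, d = d,
                       L = matrix(500L, 4, 4, dimnames = dimnames(d)),
                       flags = matrix("ok", 4, 4, dimnames = dimnames(d)),
                       model = "k2p"),
                  class = "k2p_distmat")
  part <- clade_partition(list(c("a", "b"), c("c", "d")),
                          morphospecies = "M", locus = "16S")
  vs <- variation_summary(part, dm)
  expect_equal(delimit(part, vs)$status, "species_complex")
  # congeneric reference species only ~2% apart: the same divergence is
  # credible inter-species signal
  v_ref <- delimit(part, vs, reference_distances = c(2.0, 3.5))
  expect_equal(v_ref$status, "cryptic_species")
  expect_true(any(grepl("reference", v_ref$notes)))
  # references larger than the observed divergence do not rescue
  expect_equal(delimit(part, vs, reference_distances = c(8, 12))$status,
               "species_complex")
})

test_that("merging clades moves the statistics toward single-species", {
  withr::local_seed(52)
  for (rep in 1:10) {
    dm <- random_distmat(9)
    grp <- sample(1:3, 9, replace = TRUE)
    grp[1:3] <- 1:3
    part3 <- clade_partition(split(dm$ids, grp))
    vs3 <- variation_summary(part3, dm)
    # merge blocks 1 and 2
    b <- part3$blocks
    part2 <- clade_partition(c(list(c(b[[1]], b[[2]])), b[-(1:2)]))
    vs2 <- variation_summary(part2, dm)
    # the intra pool only grows and the inter pool only shrinks, so the
    # extreme statistics that drive the gap are monotone under merging
    expect_gte(round(vs2$max_intra, 10), round(vs3$max_intra, 10))
    if (!is.na(vs2$min_inter)) {
      expect_gte(round(vs2$min_inter, 10), round(vs3$min_inter, 10))
    }
    expect_lte(vs2$n_inter_pairs, vs3$n_inter_pairs)
    expect_gte(vs2$n_intra_pairs, vs3$n_intra_pairs)
    # full coarsening always lands on single_species
    part1 <- clade_partition(list(dm$ids))
    expect_equal(delimit(part1, variation_summary(part1, dm))$status,
                 "single_species")
  }
})
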