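test_that("threshold clustering separates planted blocks and honours the cut", {
  aln <- two_clade_alignment(n_per = 3, L = 100, k = 15)   # inter ~ 0.17
  dm <- distance_matrix(aln)
  part <- cluster_by_threshold(dm, 0.05, morphospecies = "M", locus = "COI")
  expect_length(part$blocks, 2L)
  expect_setequal(part$blocks[[1]], c("A01", "A02", "A03"))
  # threshold above the largest distance: single clade
  p1 <- cluster_by_threshold(dm, 1)
  expect_length(p1$blocks, 1L)
  # tiny threshold: only identical sequences co-cluster
  p2 <- cluster_by_threshold(dm, 1e-9)
  expect_length(p2$blocks, 2L)   # each clade is internally identical
  expect_error(cluster_by_threshold(
    structure(list(ids = character(0)), class = "k2p_distmat"), 0.03),
    "empty")
})

test_that("merging at exactly the threshold is excluded (strict less-than)", {
  ids <- c("a", "b")
  d <- matrix(c(0, 0.03, 0.03, 0), 2, dimnames = list(ids, ids))
  dm <- structure(list(ids = ids, d = d,
                       L = matrix(10L, 2, 2), model = "k2p",
                       flags = matrix("ok", 2, 2, dimnames = dimnames(d))),
                  class = "k2p_distmat")
  expect_length(cluster_by_threshold(dm, 0.03)$blocks, 2L)
  expect_length(cluster_by_threshold(dm, 0.0300001)$blocks, 1L)
})

test_that("single linkage equals graph connected components on random matrices", {
  withr::local_seed(41)
  for (rep in 1:40) {
    n <- sample(3:12, 1)
    dm <- random_distmat(n)
    thr <- runif(1, 0.01, 0.15)
    got <- cluster_by_threshold(dm, thr, linkage = "single")
    expect_identical(canon_blocks(got$blocks),
                     canon_blocks(components_oracle(dm, thr)))
  }
})

test_that("increasing the threshold never increases the block count", {
  withr::local_seed(42)
  for (rep in 1:10) {
    dm <- random_distmat(10)
    ths <- sort(runif(6, 0.005, 0.2))
    counts <- vapply(ths, function(t)
      length(cluster_by_threshold(dm, t)$blocks), integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("saturated pairs never link specimens", {
  ids <- c("a", "b", "c")
  d <- matrix(0.001, 3, 3, dimnames = list(ids, ids)); diag(d) <- 0
  flags <- matrix("ok", 3, 3, dimnames = list(ids, ids))
  d["a", "c"] <- d["c", "a"] <- NA
  flags["a", "c"] <- flags["c", "a"] <- "saturated"
  # a-c saturated but both link through b: still one clade (single linkage)
  dm <- structure(list(ids = ids, d = d, L = matrix(10L, 3, 3),
                       flags = flags, model = "k2p"),
                  class = "k2p_distmat")
  expect_length(cluster_by_threshold(dm, 0.01)$blocks, 1L)
  # sever b: a and c cannot join directly
  d["a", "b"] <- d["b", "a"] <- 0.5
  d["c", "b"] <- d["b", "c"] <- 0.5
  dm$d <- d
  expect_length(cluster_by_threshold(dm, 0.01)$blocks, 3L)
})

test_that("supported clades are read off an imported tree", {
  specimens <- c("A", "B", "C", "D")
  tr <- read_newick_tree("((A,B)0.99,(C,D)0.97);")
  part <- partition_from_tree(tr, specimens, min_support = 0.95)
  expect_identical(canon_blocks(part$blocks),
                   canon_blocks(list(c("A", "B"), c("C", "D"))))
  # support below the cutoff dissolves the clade into singletons
  tr2 <- read_newick_tree("((A,B)0.80,(C,D)0.97);")
  part2 <- partition_from_tree(tr2, specimens, min_support = 0.95)
  expect_identical(canon_blocks(part2$blocks),
                   canon_blocks(list("A", "B", c("C", "D"))))
  expect_error(partition_from_tree(tr, c(specimens, "Zmissing")),
               "Zmissing")
})

test_that("only maximal supported morphospecies clades are kept", {
  # E is another morphospecies: the 0.99 node spans it, so the deepest
  # usable clade for {A,B,C} is the 0.98 node
  tr <- read_newick_tree("(((A,B)0.97,C)0.98,E)0.99;")
  part <- partition_from_tree(tr, c("A", "B", "C"), min_support = 0.95)
  expect_identical(canon_blocks(part$blocks),
                   canon_blocks(list(c("A", "B", "C"))))
})

test_that("tree partition matches an exhaustive supported-node scan", {
  withr::local_seed(43)
  for (rep in 1:20) {
    n <- 12
    tr <- ape::rtree(n, tip.label = sprintf("t%02d", 1:n))
    tr$edge.length <- NULL
    supp <- round(runif(tr$Nnode), 2)
    supp[sample(tr$Nnode, 2)] <- NA
    tr$node.label <- ifelse(is.na(supp), "", sprintf("%.2f", supp))
    stree <- read_newick_tree(ape::write.tree(tr))
    specimens <- sort(sample(tr$tip.label, 8))
    got <- partition_from_tree(stree, specimens, min_support = 0.7)
    # oracle: enumerate every internal node through ape's clade extractor
    ntip <- length(stree$tree$tip.label)
    cand <- list()
    for (nd in (ntip + 1):(ntip + stree$tree$Nnode)) {
      tips <- ape::extract.clade(stree$tree, nd)$tip.label
      sp <- stree$support[nd - ntip]
      if (length(tips) >= 2 && all(tips %in% specimens) &&
          !is.na(sp) && sp >= 0.7) {
        cand[[length(cand) + 1L]] <- tips
      }
    }
    keep <- vapply(seq_along(cand), function(i)
      !any(vapply(seq_along(cand), function(j)
        i != j && length(cand[[i]]) < length(cand[[j]]) &&
          all(cand[[i]] %in% cand[[j]]), logical(1))), logical(1))
    blocks <- cand[keep]
    blocks <- c(blocks, as.list(setdiff(specimens, unlist(blocks))))
    expect_identical(canon_blocks(got$blocks), canon_blocks(blocks))
  }
})

test_that("tree partition is invariant to rotation and outgroup placement", {
  forms <- c("(((A,B)0.99,(C,D)0.97)0.9,OG);",
             "(OG,((C,D)0.97,(A,B)0.99)0.9);",
             "((B,A)0.99,(D,C)0.97,OG);")
  parts <- lapply(forms, function(f)
    partition_from_tree(read_newick_tree(f), c("A", "B", "C", "D")))
  for (p in parts[-1]) {
    expect_identical(canon_blocks(p$blocks), canon_blocks(parts[[1]]$blocks))
  }
})

test_that("cross-locus contingency detects refinement, crossing and disjointness", {
  pa <- clade_partition(list(c("A", "B"), c("C", "D")), locus = "COI")
  pb_same <- clade_partition(list(c("A", "B"), c("C", "D")), locus = "16S")
  ctg <- map_partition_across_loci(pa, pb_same)
  expect_true(ctg$coherent)
  expect_equal(sum(diag(ctg$table) > 0), 2L)

  # 16S coarsens the two COI clades into one: still coherent
  pb_coarse <- clade_partition(list(c("A", "B", "C", "D")), locus = "16S")
  expect_true(map_partition_across_loci(pa, pb_coarse)$coherent)

  # crossing pairs break coherence
  pb_cross <- clade_partition(list(c("A", "C"), c("B", "D")), locus = "16S")
  expect_false(map_partition_across_loci(pa, pb_cross)$coherent)

  # disjoint specimen sets: undecidable
  pb_disj <- clade_partition(list(c("E", "F")), locus = "16S")
  ctg2 <- map_partition_across_loci(pa, pb_disj)
  expect_true(is.na(ctg2$coherent))
  expect_setequal(ctg2$only_b, c("E", "F"))
})

test_that("partition serialization writes one row per specimen", {
  p <- clade_partition(list(c("A", "B"), "C"), morphospecies = "M",
                       locus = "COI")
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_partition(p, tmp)
  tab <- read.delim(tmp)
  expect_equal(nrow(tab), 3L)
  expect_setequal(tab$clade_label[tab$specimen_id %in% c("A", "B")], "C1")
})
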