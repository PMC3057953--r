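test_that("Newick parsing honours support, lengths, and error cases", {
  tr <- parse_newick("((A:1,B:2)90:0.5,C:3);")
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  expect_equal(clade_support(tr, c("A", "B"))$support, 90)

  expect_warning(t0 <- parse_newick("((A,B),(C,D));"), "branch length")
  expect_true(all(t0$edge.length == 0))
  bp <- bipartitions(t0)
  expect_equal(nrow(bp), 1L)
  expect_equal(bp$split, "A,B")

  expect_error(parse_newick("((A:1,B:1):1,A:1);"), "duplicate")
  expect_error(parse_newick("((A:1,B:-0.5):1,C:1);"), "negative")
  expect_warning(ts <- parse_newick("((A:1,B:1)0.97:1,C:1,D:1);"), "rescaled")
  expect_equal(clade_support(ts, c("A", "B"))$support, 97)
})

test_that("Newick write -> parse round-trips topology and lengths", {
  for (seed in 1:5) {
    tr <- random_additive_tree(7, seed)
    tr2 <- parse_newick(write_newick(tr))
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(tr2)), 0,
                 ignore_attr = TRUE)
    d1 <- patristic_matrix(tr); d2 <- patristic_matrix(tr2)
    expect_lt(max(abs(d1 - d2)), 1e-12)
  }
})

test_that("bipartition sets match an independent split enumeration", {
  expect_equal(bipartitions(parse_newick("((A:1,B:1):1,(C:1,D:1):1);"))$split,
               "A,B")
  star <- parse_newick("(A:1,B:1,C:1,D:1,E:1);")
  expect_equal(nrow(bipartitions(star)), 0L)
  for (seed in 1:10) {
    n <- sample(5:9, 1)
    tr <- random_additive_tree(n, 300 + seed)
    mine <- sort(bipartitions(tr)$split)
    expect_equal(length(mine), n - 3L)          # binary unrooted: n-3 splits
    expect_equal(mine, sort(phangorn_splits(tr)))
  }
})

test_that("bipartitions are invariant under rerooting and leaf order", {
  tr <- random_additive_tree(8, 17)
  base <- sort(bipartitions(tr)$split)
  for (tip in c("t1", "t4")) {
    rr <- ape::root(tr, outgroup = tip, resolve.root = TRUE)
    expect_equal(sort(bipartitions(rr)$split), base)
  }
  perm <- ape::rotateConstr(tr, sample(tr$tip.label))
  expect_equal(sort(bipartitions(perm)$split), base)
})

test_that("patristic distances equal brute-force path sums and are four-point", {
  tr <- parse_newick("((A:1,B:2):0.5,(C:1,D:1):0.5);")
  d <- patristic_matrix(tr)
  expect_equal(d["A", "B"], 3)
  expect_equal(d["A", "C"], 3)
  for (seed in 1:5) {
    tr <- random_additive_tree(8, 40 + seed)
    d <- patristic_matrix(tr)
    expect_lt(max(abs(d - brute_patristic(tr))), 1e-12)
    taxa <- rownames(d)
    quads <- utils::combn(taxa, 4)
    for (q in seq_len(ncol(quads))) {
      ij <- quads[, q]
      s1 <- d[ij[1], ij[2]] + d[ij[3], ij[4]]
      s2 <- d[ij[1], ij[3]] + d[ij[2], ij[4]]
      s3 <- d[ij[1], ij[4]] + d[ij[2], ij[3]]
      two <- sort(c(s1, s2, s3), decreasing = TRUE)[1:2]
      expect_lt(abs(two[1] - two[2]), 1e-9)
    }
  }
})

test_that("restriction preserves patristic distances and merges supports by max", {
  tr <- parse_newick("((A:1,B:1)95:0.5,((C:1,D:1)80:0.25,E:1)60:0.25,F:2);")
  sub <- restrict_tree(tr, c("A", "B", "C", "D", "F"))
  expect_equal(sort(sub$tip.label), c("A", "B", "C", "D", "F"))
  # the (C,D,E)=60 edge merges into the (C,D)=80 edge: max wins
  expect_equal(clade_support(sub, c("C", "D"))$support, 80)
  expect_equal(clade_support(sub, c("A", "B"))$support, 95)
  d0 <- patristic_matrix(tr)
  d1 <- patristic_matrix(sub)
  keep <- rownames(d1)
  expect_lt(max(abs(d0[keep, keep] - d1)), 1e-12)

  for (seed in 1:5) {
    tr <- random_additive_tree(9, 70 + seed)
    keep <- sort(sample(tr$tip.label, 5))
    sub <- restrict_tree(tr, keep)
    expect_lt(max(abs(patristic_matrix(tr)[keep, keep] -
                      patristic_matrix(sub)[keep, keep])), 1e-12)
  }
  expect_identical(restrict_tree(tr, tr$tip.label), tr)
  expect_error(restrict_tree(tr, c("t1", "zz")), "zz")
})

test_that("split compatibility agrees with coexistence in some tree", {
  taxa <- sort(c("A", "B", "C", "D", "E", "F"))
  expect_false(compatible("A,B", "A,C", taxa = c("A", "B", "C", "D")))
  expect_true(compatible("A", c("A,C", "A,B"), taxa = c("A", "B", "C", "D")))

  # enumerate all non-trivial splits of 6 taxa and all unrooted topologies
  all_splits <- character(0)
  for (k in 2:4) {
    cmb <- utils::combn(taxa, k)
    for (i in seq_len(ncol(cmb))) {
      side <- cmb[, i]
      if (!("A" %in% side)) side <- sort(setdiff(taxa, side))
      all_splits <- c(all_splits, paste(sort(side), collapse = ","))
    }
  }
  all_splits <- unique(all_splits)
  trees <- phangorn::allTrees(6, tip.label = taxa)
  tree_splits <- lapply(trees, phangorn_splits)
  set.seed(5)
  pairs <- cbind(sample(all_splits, 40, replace = TRUE),
                 sample(all_splits, 40, replace = TRUE))
  for (i in seq_len(nrow(pairs))) {
    s1 <- pairs[i, 1]; s2 <- pairs[i, 2]
    coexist <- any(vapply(tree_splits, function(ts) {
      all(c(s1, s2) %in% ts)
    }, TRUE)) || s1 == s2
    expect_equal(compatible(s1, s2, taxa), coexist,
                 label = paste(s1, "vs", s2))
  }
})

test_that("clade support is invariant under rerooting", {
  tr <- parse_newick("((A:1,B:1)96:0.5,((C:1,D:1)88:0.25,E:1)70:0.25,F:2);")
  expect_equal(clade_support(tr, c("A", "B"))$support, 96)
  expect_false(clade_support(tr, c("A", "C"))$present)
  for (tip in c("A", "E", "F")) {
    rr <- ape::root(tr, outgroup = tip, resolve.root = TRUE)
    expect_equal(clade_support(rr, c("C", "D"))$support, 88)
  }
})
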