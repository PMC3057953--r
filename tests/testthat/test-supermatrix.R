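toy_genes <- function() {
  list(G1 = msa(c(a = "ACGT", b = "ACGA", c = "ACCA"), "nt"),
       G2 = msa(c(a = "GGGTTT", b = "GGGTTA"), "nt"))
}

test_that("concatenation fills absent blocks with ? and keeps one partition per gene", {
  sm <- concatenate(toy_genes())
  expect_equal(n_taxa(sm$aln), 3L)
  expect_equal(n_sites(sm$aln), 10L)
  expect_equal(sm$partitions$name, c("G1", "G2"))
  expect_equal(sm$partitions$start, c(1L, 5L))
  expect_equal(sm$partitions$end, c(4L, 10L))
  expect_equal(paste(unclass(sm$aln)["c", 5:10], collapse = ""), "??????")

  single <- concatenate(toy_genes()[1])
  expect_identical(unclass(single$aln), unclass(toy_genes()$G1))
  expect_equal(nrow(single$partitions), 1L)
})

test_that("extracting a partition and dropping all-missing taxa round-trips", {
  sm <- concatenate(toy_genes())
  g2 <- extract_partition(sm, "G2", drop_all_missing = TRUE)
  expect_identical(as_strings(g2), as_strings(toy_genes()$G2))
  # re-concatenating every partition reproduces the alignment exactly
  parts <- lapply(sm$partitions$name, extract_partition, sm = sm)
  names(parts) <- sm$partitions$name
  expect_identical(unclass(concatenate(parts)$aln), unclass(sm$aln))
})

test_that("missing_fraction counts every missing symbol", {
  full <- msa(c(a = "ACGT", b = "ACGA", c = "TTTT", d = "GGGG"), "nt")
  expect_equal(missing_fraction(concatenate(list(g = full))), 0)
  onegone <- msa(c(a = "ACGT", b = "ACGA", c = "TTTT", d = "????"), "nt")
  expect_equal(missing_fraction(concatenate(list(g = onegone))), 0.25)
  expect_equal(missing_fraction(concatenate(toy_genes())), 6 / 30)
  # '-' and N count as missing too
  gapn <- msa(c(a = "AC-T", b = "ACGN"), "nt")
  expect_equal(missing_fraction(concatenate(list(g = gapn))), 2 / 8)
})

test_that("per-taxon missing profile matches direct counts", {
  sm <- concatenate(toy_genes())
  tab <- per_taxon_missing(sm)
  expect_equal(tab$frac_missing[tab$taxon == "a"], 0)
  expect_equal(tab$n_partitions_missing[tab$taxon == "a"], 0L)
  expect_equal(tab$frac_missing[tab$taxon == "c"], 0.6)
  expect_equal(tab$n_partitions_missing[tab$taxon == "c"], 1L)
})

test_that("subset_taxa preserves rows, columns and partitions", {
  sm <- concatenate(toy_genes())
  expect_identical(unclass(subset_taxa(sm, c("a", "b", "c"))$aln),
                   unclass(sm$aln))
  two <- subset_taxa(sm, c("a", "c"))
  expect_equal(taxa_names(two), c("a", "c"))
  expect_equal(n_sites(two$aln), 10L)
  expect_identical(two$partitions, sm$partitions)
  expect_equal(missing_fraction(two), mean(unclass(two$aln) %in% c("-", "?", "N")))
  expect_error(subset_taxa(sm, c("a", "zz")), "zz")
})

test_that("concatenation is order-independent in content and validates input", {
  set.seed(11)
  genes <- lapply(1:4, function(i) {
    random_msa(sample(3:5, 1), sample(5:9, 1), seed = i)
  })
  names(genes) <- paste0("g", 1:4)
  sm1 <- concatenate(genes)
  sm2 <- concatenate(rev(genes))
  for (g in names(genes)) {
    expect_identical(as_strings(extract_partition(sm1, g)),
                     as_strings(extract_partition(sm2, g))[taxa_names(extract_partition(sm1, g))])
  }
  # overall missing fraction equals the direct weighted count
  expect_equal(missing_fraction(sm1), missing_fraction(sm2))
  expect_error(concatenate(stats::setNames(genes, c("g1", "g1", "g3", "g4"))),
               "duplicate")
  aa <- random_msa(3, 5, seed = 9, alphabet = "aa")
  expect_error(concatenate(c(genes, list(g5 = aa))), "alphabet")
})

test_that("partition tables round-trip through plain text", {
  sm <- concatenate(toy_genes())
  f <- withr::local_tempfile(fileext = ".txt")
  write_partitions(sm$partitions, f)
  p <- read_partitions(f)
  expect_equal(p$name, sm$partitions$name)
  expect_equal(p$start, sm$partitions$start)
  expect_equal(p$end, sm$partitions$end)
  sm2 <- supermatrix(sm$aln, p)
  expect_identical(sm2$partitions$name, sm$partitions$name)
  bad <- withr::local_tempfile()
  writeLines("G1 = banana", bad)
  expect_error(read_partitions(bad), "malformed")
})
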