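test_that("zero branch lengths copy the root draw to every taxon", {
  tr <- parse_newick("((A:0,B:0):0,C:0,D:0);")
  spec <- simulation_spec(tr, substitution_model(s = 4),
                          sites_per_gene = 50, n_genes = 1, seed = 3)
  sim <- simulate_supermatrix(spec)
  s <- as_strings(sim$supermatrix$aln)
  expect_true(all(s == s[[1]]))
})

test_that("single-branch divergence matches the closed-form probability", {
  # uniform 4-state model, one branch of length 0.75:
  # P(diff) = (3/4) (1 - exp(-4 L / 3))
  L <- 0.75
  tr <- parse_newick(sprintf("(A:%g,B:0);", L))
  spec <- simulation_spec(tr, substitution_model(s = 4),
                          sites_per_gene = 50000, n_genes = 1, seed = 11)
  sim <- simulate_supermatrix(spec)
  p_obs <- p_distance(sim$supermatrix$aln)["A", "B"]
  p_exp <- (3 / 4) * (1 - exp(-4 * L / 3))
  mc_se <- sqrt(p_exp * (1 - p_exp) / 50000)
  expect_lt(abs(p_obs - p_exp), 3 * mc_se)
})

test_that("a degenerate profile freezes its sites across all taxa", {
  prof <- rbind(c(1, rep(0, 19)))
  mod <- substitution_model(s = 20, mode = "profile_mixture", profiles = prof)
  tr <- random_additive_tree(5, 12, min_len = 0.5, max_len = 2)
  spec <- simulation_spec(tr, mod, sites_per_gene = 40, n_genes = 1, seed = 5)
  sim <- simulate_supermatrix(spec)
  s <- as_strings(sim$supermatrix$aln)
  expect_true(all(s == strrep("A", 40)))
})

test_that("the same spec and seed give a byte-identical supermatrix", {
  tr <- random_additive_tree(6, 8)
  mod <- substitution_model(s = 20, mode = "profile_mixture",
                            profiles = cat_profiles(5, 20, seed = 2),
                            gamma_shape = 0.8)
  spec <- simulation_spec(tr, mod, sites_per_gene = 100, n_genes = 2, seed = 99)
  s1 <- simulate_supermatrix(spec)
  s2 <- simulate_supermatrix(spec)
  expect_identical(unclass(s1$supermatrix$aln), unclass(s2$supermatrix$aln))
  expect_identical(s1$truth, s2$truth)
})

test_that("adding genes never perturbs earlier genes", {
  tr <- random_additive_tree(6, 8)
  mod <- substitution_model(s = 4, gamma_shape = 1)
  one <- simulate_supermatrix(simulation_spec(tr, mod, 80, n_genes = 1, seed = 7))
  three <- simulate_supermatrix(simulation_spec(tr, mod, 80, n_genes = 3, seed = 7))
  expect_identical(as_strings(extract_partition(one$supermatrix, "gene01")),
                   as_strings(extract_partition(three$supermatrix, "gene01")))
})

test_that("the truth table records profiles, rates, and gene multipliers", {
  prof <- cat_profiles(4, 20, seed = 3)
  mod <- substitution_model(s = 20, mode = "profile_mixture", profiles = prof,
                            gamma_shape = 0.5, gene_rates = c(1, 10))
  tr <- random_additive_tree(5, 14)
  sim <- simulate_supermatrix(simulation_spec(tr, mod, 60, n_genes = 2, seed = 31))
  tt <- sim$truth
  expect_equal(nrow(tt), 120L)
  expect_true(all(tt$profile %in% 1:4))
  cats <- phangorn::discrete.gamma(0.5, 4)
  expect_true(all(tt$rate[tt$gene == "gene01"] %in% cats))
  expect_true(all(tt$rate[tt$gene == "gene02"] %in% (10 * cats)))
})

test_that("gene-rate multipliers raise observed divergence", {
  tr <- balanced8(0.3)
  mod <- substitution_model(s = 4, gene_rates = c(1, 10))
  sim <- simulate_supermatrix(simulation_spec(tr, mod, 1500, n_genes = 2, seed = 13))
  p1 <- mean(p_distance(extract_partition(sim$supermatrix, "gene01"))[upper.tri(diag(8))])
  p2 <- mean(p_distance(extract_partition(sim$supermatrix, "gene02"))[upper.tri(diag(8))])
  expect_gt(p2, p1)
})

test_that("model constructors validate their invariants", {
  expect_error(substitution_model(s = 7), "4 or 20")
  expect_error(substitution_model(s = 4, freqs = c(0.5, 0.5, 0.1, 0)), "sum to 1")
  expect_error(substitution_model(s = 4, mode = "profile_mixture"), "profiles")
  expect_error(substitution_model(s = 4, gamma_shape = -1), "positive")
  p <- cat_profiles(3, 20, seed = 1)
  expect_error(substitution_model(s = 20, mode = "profile_mixture",
                                  profiles = p, weights = c(1, 1, 1)), "sum to 1")
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-12)
  tr <- random_additive_tree(4, 2)
  expect_error(simulation_spec(tr, substitution_model(s = 4), 100, 1),
               "seed")
})
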