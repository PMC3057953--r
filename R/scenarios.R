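# Benchmark scenarios: fully scripted study conditions that exercise
# the whole pipeline against known ground truth. They back both the
# acceptance script and the end-to-end tests.

random_binary_tree <- function(n, seed, min_len = 0.05, max_len = 0.5) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- stats::runif(nrow(tr$edge), min_len, max_len)
  tr
}

# balanced 8-taxon tree; `diameter` = maximum tip-to-tip path length
balanced_eight <- function(diameter = 0.05) {
  e <- diameter / 6
  nwk <- "(((A:e,B:e):e,(C:e,D:e):e):e,((E:e,F:e):e,(G:e,H:e):e):e);"
  ape::read.tree(text = gsub(":e", sprintf(":%.10g", e), nwk, fixed = TRUE))
}

# 10-taxon reference with sturdy (0.1) internal edges
reference_ten <- function() {
  ape::read.tree(text = paste0(
    "(((t1:0.1,t2:0.1):0.1,(t3:0.1,t4:0.1):0.1):0.1,",
    "((t5:0.1,t6:0.1):0.1,(t7:0.1,t8:0.1):0.1):0.1,",
    "(t9:0.1,t10:0.1):0.1);"))
}

#' Oracle check: NJ on additive matrices and four-point condition
#'
#' Draws random binary trees (6-10 leaves, branch lengths uniform on
#' \[0.05, 0.5\]), converts each to its patristic matrix, re-infers by
#' [neighbor_joining()], and measures topology recovery, the worst
#' branch-length reconstruction error, and the worst violation of the
#' four-point condition over all leaf quadruples of every matrix.
#'
#' @param n_trees number of random trees.
#' @param seed integer seed.
#' @return list: `recovery_rate`, `max_length_error`,
#'   `max_four_point_violation`, `n_trees`.
#' @export
nj_additive_check <- function(n_trees = 200, seed = 1) {
  worst_len <- 0
  worst_fp <- 0
  hits <- 0L
  for (i in seq_len(n_trees)) {
    set.seed(seed * 100000 + i)
    n <- sample(6:10, 1)
    tr <- random_binary_tree(n, seed * 100000 + i)
    D <- patristic_matrix(tr)
    nj <- neighbor_joining(D)
    rf <- as.numeric(ape::dist.topo(ape::unroot(tr), nj))
    if (rf == 0) hits <- hits + 1L
    Dn <- patristic_matrix(nj)
    worst_len <- max(worst_len, max(abs(Dn[rownames(D), colnames(D)] - D)))
    quads <- utils::combn(rownames(D), 4)
    for (q in seq_len(ncol(quads))) {
      ij <- quads[, q]
      sums <- sort(c(D[ij[1], ij[2]] + D[ij[3], ij[4]],
                     D[ij[1], ij[3]] + D[ij[2], ij[4]],
                     D[ij[1], ij[4]] + D[ij[2], ij[3]]), decreasing = TRUE)
      worst_fp <- max(worst_fp, sums[1] - sums[2])
    }
  }
  list(recovery_rate = hits / n_trees, max_length_error = worst_len,
       max_four_point_violation = worst_fp, n_trees = n_trees)
}

#' Saturation semantics under branch-length scaling
#'
#' Simulates homogeneous uniform 4-state data (10,000 sites) on a fixed
#' balanced 8-taxon tree whose maximum tip-to-tip path is 0.05
#' substitutions/site, then rescales all branch lengths by 1, 5 and 20.
#' For each multiplier the data are re-analyzed exactly as a user
#' would: Poisson-corrected distances, [neighbor_joining()], and
#' [saturation_slope()] of the data against that inferred tree. Slopes
#' are averaged over seeds.
#'
#' @param seeds integer vector of simulation seeds.
#' @param sites sites per simulation.
#' @return list `slope_x1`, `slope_x5`, `slope_x20`, `sites`, `n_seeds`.
#' @export
saturation_scaling_check <- function(seeds = 1:3, sites = 10000) {
  base <- balanced_eight(0.05)
  model <- substitution_model(s = 4)
  mean_slope <- function(mult) {
    tr <- base
    tr$edge.length <- tr$edge.length * mult
    mean(vapply(seeds, function(sd) {
      sim <- simulate_supermatrix(simulation_spec(tr, model, sites, 1,
                                                  seed = sd * 1000 + mult))
      nj <- neighbor_joining(corrected_distance_matrix(
        sim$supermatrix$aln, distance_model("poisson")))
      saturation_slope(sim$supermatrix, nj)$slope
    }, 1))
  }
  list(slope_x1 = mean_slope(1), slope_x5 = mean_slope(5),
       slope_x20 = mean_slope(20), sites = sites, n_seeds = length(seeds))
}

#' Ground-truth check of the supported-branch congruence screen
#'
#' Simulates 20 genes (1,000 sites each) on a fixed 10-taxon reference
#' tree, implants contaminations into two genes (the recipient's block
#' is overwritten by a distant donor's), infers every gene tree with
#' the internal bootstrap engine (B = 100, Poisson correction), and
#' runs [congruence_screen()] at threshold 70 — once on all 20 genes
#' and once on the 18 clean ones.
#'
#' @param seed integer seed.
#' @param n_genes,sites,B scenario size.
#' @return list: `flagged_genes`, `implanted_genes`, `conflicts`
#'   (data.frame), `conflict_rate_all`, `clean_conflict_rate`,
#'   `n_supported`.
#' @export
congruence_screen_check <- function(seed = 1, n_genes = 20, sites = 1000,
                                    B = 100) {
  ref <- reference_ten()
  sim <- simulate_supermatrix(simulation_spec(ref, substitution_model(s = 4),
                                              sites, n_genes, seed = seed))
  sm <- sim$supermatrix
  implants <- list(c("gene05", "t1", "t8"), c("gene13", "t2", "t9"))
  for (ev in implants) {
    sm <- implant_transfer(sm, ev[1], donor = ev[2], recipient = ev[3])
  }
  implanted <- vapply(implants, `[`, "", 1L)
  genes <- lapply(seq_len(nrow(sm$partitions)), function(i) {
    g <- sm$partitions$name[i]
    bootstrap_support(extract_partition(sm, g), B = B,
                      seed = seed * 1000 + i,
                      model = distance_model("poisson"))
  })
  names(genes) <- sm$partitions$name
  all_rep <- congruence_screen(genes, ref, threshold = 70)
  clean_rep <- congruence_screen(genes[setdiff(names(genes), implanted)],
                                 ref, threshold = 70)
  flagged <- all_rep$per_gene$gene[all_rep$per_gene$n_conflicting > 0L]
  list(flagged_genes = flagged, implanted_genes = implanted,
       conflicts = all_rep$conflicts,
       conflict_rate_all = all_rep$conflict_rate,
       clean_conflict_rate = clean_rep$conflict_rate,
       n_supported = all_rep$n_supported)
}

#' Long-branch attraction under uncorrected distances
#'
#' For each long-branch length, simulates amino-acid data (5,000 sites)
#' under a 10-profile CAT-like mixture on the two-long/two-short
#' quartet (short terminals 0.05, central edge 0.05), infers a tree
#' from uncorrected p-distances with [neighbor_joining()], and counts
#' how often the two long branches are (wrongly) placed together.
#'
#' @param n_seeds replicate simulations per condition.
#' @param seed master seed.
#' @param long_lens long-branch lengths to scan.
#' @param sites sites per simulation.
#' @return list: `wrong_freq` (named by long-branch length), `n_seeds`,
#'   `sites`.
#' @export
lba_check <- function(n_seeds = 50, seed = 1, long_lens = c(0.5, 1, 2),
                      sites = 5000) {
  profiles <- cat_profiles(K = 10, s = 20, concentration = 0.2,
                           seed = seed + 7777)
  model <- substitution_model(s = 20, mode = "profile_mixture",
                              profiles = profiles)
  wrong <- vapply(long_lens, function(L) {
    tr <- make_lba_tree(long_len = L, short_len = 0.05, internal_len = 0.05)
    mean(vapply(seq_len(n_seeds), function(r) {
      sim <- simulate_supermatrix(simulation_spec(
        tr, model, sites, 1, seed = seed * 100000 + round(L * 1000) + r))
      nj <- neighbor_joining(p_distance(sim$supermatrix$aln))
      bipartitions(nj)$split == "L1,L2"
    }, TRUE))
  }, 1)
  names(wrong) <- as.character(long_lens)
  list(wrong_freq = wrong, n_seeds = n_seeds, sites = sites)
}
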