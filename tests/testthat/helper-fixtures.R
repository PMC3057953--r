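# Fixture builders shared across test files. Everything is generated in
# code under fixed seeds; nothing is read from disk.

# random unrooted-style binary tree with strictly positive branch lengths
random_additive_tree <- function(n, seed, min_len = 0.05, max_len = 0.5) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- stats::runif(nrow(tr$edge), min_len, max_len)
  tr
}

# random nucleotide msa with iid uniform columns (signal-free)
random_msa <- function(n_taxa, n_sites, seed, alphabet = "nt") {
  set.seed(seed)
  states <- phyloqc:::residue_states(alphabet)
  m <- matrix(sample(states, n_taxa * n_sites, replace = TRUE),
              nrow = n_taxa,
              dimnames = list(paste0("t", seq_len(n_taxa)), NULL))
  msa(m, alphabet = alphabet)
}

# star-metric alignment: each taxon mutates its own private block of
# sites, so p-distances are exactly additive on a star tree
star_alignment <- function() {
  base <- strrep("A", 20)
  mut <- function(s, pos) {
    v <- strsplit(s, "")[[1]]
    v[pos] <- "C"
    paste(v, collapse = "")
  }
  msa(c(A = mut(base, 1:2), B = mut(base, 3:4),
        C = mut(base, 5:8), D = mut(base, 9:12)), "nt")
}

star_tree <- function(scale = 1) {
  parse_newick(sprintf("(A:%g,B:%g,C:%g,D:%g);",
                       0.1 * scale, 0.1 * scale, 0.2 * scale, 0.2 * scale))
}

# fixed 8-taxon balanced reference tree of a given root-to-tip height
balanced8 <- function(height = 0.05) {
  e <- height / 3
  nwk <- "(((A:e,B:e):e,(C:e,D:e):e):e,((E:e,F:e):e,(G:e,H:e):e):e);"
  parse_newick(gsub(":e", sprintf(":%.10g", e), nwk, fixed = TRUE))
}

# 10-taxon caterpillar-ish reference with sturdy internal edges, used by
# the congruence-screen scenarios
reference10 <- function() {
  parse_newick(paste0(
    "(((t1:0.1,t2:0.1):0.1,(t3:0.1,t4:0.1):0.1):0.1,",
    "((t5:0.1,t6:0.1):0.1,(t7:0.1,t8:0.1):0.1):0.1,",
    "(t9:0.1,t10:0.1):0.1);"))
}

# brute-force patristic distance: sum edge lengths along the i-j path
# via the unique path in the tree graph (independent of cophenetic)
brute_patristic <- function(tree) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  adj <- vector("list", nn)
  for (k in seq_len(nrow(tree$edge))) {
    a <- tree$edge[k, 1]; b <- tree$edge[k, 2]; w <- tree$edge.length[k]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  d <- matrix(NA_real_, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (s in seq_len(n)) {
    dist <- rep(NA_real_, nn); dist[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (r in seq_len(NROW(adj[[v]]))) {
        u <- adj[[v]][r, 1]; w <- adj[[v]][r, 2]
        if (is.na(dist[u])) { dist[u] <- dist[v] + w; queue <- c(queue, u) }
      }
    }
    d[s, ] <- dist[seq_len(n)]
  }
  ord <- sort(tree$tip.label)
  d[ord, ord]
}

# canonical non-trivial split keys of a tree via phangorn (independent
# of the package's own bipartition walk)
phangorn_splits <- function(tree) {
  sp <- phangorn::as.splits(ape::unroot(tree))
  labs <- attr(sp, "labels")
  all_taxa <- sort(labs)
  keys <- vapply(sp, function(idx) {
    side <- sort(labs[idx])
    if (length(side) <= 1L || length(side) >= length(labs) - 1L) return(NA_character_)
    if (!(all_taxa[1L] %in% side)) side <- sort(setdiff(all_taxa, side))
    paste(side, collapse = ",")
  }, "")
  unique(keys[!is.na(keys)])
}
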