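#' Neighbor-joining tree from a distance matrix
#'
#' The classical agglomerative algorithm of Saitou & Nei with two
#' determinism guarantees: ties in the Q-criterion are broken by the
#' lexicographically smallest pair of cluster names (a cluster is named
#' by its smallest member taxon), and negative intermediate branch
#' lengths are clamped to zero with the deficit transferred to the
#' sibling edge, so total path lengths through the new node are
#' preserved. On an additive (tree-metric) matrix the generating
#' topology and branch lengths are recovered exactly.
#'
#' @param D symmetric distance matrix with taxon dimnames; all entries
#'   must be defined (no `NA`/`NaN`: impute or drop taxa first).
#' @return an unrooted `phylo` object.
#' @export
neighbor_joining <- function(D) {
  if (!is.matrix(D)) D <- as.matrix(D)
  taxa <- rownames(D)
  if (is.null(taxa)) stop("distance matrix needs taxon dimnames")
  n <- nrow(D)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  if (any(!is.finite(D))) {
    stop("distance matrix has undefined entries; remove those taxa or impute")
  }
  # active clusters: newick fragment + representative (smallest) taxon name
  frag <- paste0(sanitize_label(taxa))
  rep_name <- taxa
  act <- D
  while (nrow(act) > 3L) {
    m <- nrow(act)
    r <- rowSums(act)
    Q <- (m - 2) * act - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    # lexicographically smallest (sorted) name pair among ties
    keys <- apply(cand, 1L, function(ij) {
      nm <- sort(c(rep_name[ij[1L]], rep_name[ij[2L]]))
      paste(nm, collapse = "\r")
    })
    pick <- cand[order(keys)[1L], ]
    i <- pick[1L]; j <- pick[2L]
    dij <- act[i, j]
    li <- dij / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- dij - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    newfrag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt_len(li), frag[j], fmt_len(lj))
    newrep <- min(rep_name[i], rep_name[j])
    dnew <- (act[i, ] + act[j, ] - dij) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    act <- rbind(cbind(act[keep, keep, drop = FALSE], dnew[keep]),
                 c(dnew[keep], 0))
    frag <- c(frag[keep], newfrag)
    rep_name <- c(rep_name[keep], newrep)
    rownames(act) <- colnames(act) <- rep_name
  }
  if (nrow(act) == 3L) {
    # three-point formulas for the terminal star
    l1 <- (act[1, 2] + act[1, 3] - act[2, 3]) / 2
    l2 <- (act[1, 2] + act[2, 3] - act[1, 3]) / 2
    l3 <- (act[1, 3] + act[2, 3] - act[1, 2]) / 2
    l1 <- max(l1, 0); l2 <- max(l2, 0); l3 <- max(l3, 0)
    nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", frag[1], fmt_len(l1),
                   frag[2], fmt_len(l2), frag[3], fmt_len(l3))
  } else {
    stop("internal error: unexpected cluster count")
  }
  tr <- ape::read.tree(text = nwk)
  tr$tip.label <- desanitize_label(tr$tip.label)
  tr
}

fmt_len <- function(x) formatC(x, format = "g", digits = 17)

# newick-reserved characters in labels are escaped by underscoring;
# labels used here come from validated containers so this is defensive
sanitize_label <- function(x) gsub("[(),:; \t]", "_", x)
desanitize_label <- function(x) x

#' Bootstrap-supported neighbor-joining tree
#'
#' Infers the point tree from the full alignment, then resamples columns
#' with replacement (site bootstrap, same length; partition boundaries
#' ignored), re-infers each replicate, and labels every internal edge of
#' the point tree with 100 times the fraction of replicates whose tree
#' contains the same bipartition. Replicate r uses seed `seed + r`, so a
#' fixed seed makes the whole run reproducible. Replicates whose
#' resampled matrix leaves some pair with no comparable column are
#' dropped from the denominator (counted in attribute `"n_dropped"`).
#'
#' @param x an [msa] or [supermatrix].
#' @param B number of bootstrap replicates (>= 1).
#' @param seed integer seed.
#' @param model a [distance_model()] used for every inference.
#' @return the point `phylo` tree with supports as node labels;
#'   attributes `"n_effective"` and `"n_dropped"` record the bootstrap
#'   accounting.
#' @export
bootstrap_support <- function(x, B = 100L, seed = 1L,
                              model = distance_model("uncorrected")) {
  a <- if (is_supermatrix(x)) x$aln else x
  stopifnot(is_msa(a))
  if (B < 1L) stop("B must be at least 1")
  D <- corrected_distance_matrix(a, model)
  if (any(!is.finite(D))) {
    stop("undefined distances in the full alignment; cannot infer a point tree")
  }
  point <- neighbor_joining(D)
  bp <- bipartitions(point, include_trivial = FALSE)
  if (nrow(bp) == 0L) {
    point$node.label <- rep("", point$Nnode)
    attr(point, "n_effective") <- 0L
    attr(point, "n_dropped") <- 0L
    return(point)
  }
  counts <- stats::setNames(rep(0L, nrow(bp)), bp$split)
  ncol_a <- n_sites(a)
  eff <- 0L
  dropped <- 0L
  for (r in seq_len(B)) {
    set.seed(seed + r)
    cols <- sample.int(ncol_a, ncol_a, replace = TRUE)
    Dr <- corrected_distance_matrix(a[, cols], model)
    if (any(!is.finite(Dr))) { dropped <- dropped + 1L; next }
    tr <- neighbor_joining(Dr)
    rb <- bipartitions(tr, include_trivial = FALSE)
    hit <- names(counts) %in% rb$split
    counts[hit] <- counts[hit] + 1L
    eff <- eff + 1L
  }
  env <- new.env(parent = emptyenv())
  for (k in names(counts)) {
    env[[k]] <- if (eff > 0L) 100 * counts[[k]] / eff else NA_real_
  }
  point <- set_split_supports(point, env)
  attr(point, "n_effective") <- eff
  attr(point, "n_dropped") <- dropped
  point
}
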