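#' Parse a Newick tree with branch lengths and support values
#'
#' Trees are plain \pkg{ape} `phylo` objects throughout the package.
#' Internal node labels that parse as numbers in \[0, 100\] are taken as
#' support values (the usual convention of maximum-likelihood and
#' bootstrap programs: `label:length` after a closing parenthesis means
#' (support, length)). Supports in \[0, 1\] are rescaled to 0-100 with a
#' warning. Missing branch lengths default to 0 with a warning; negative
#' branch lengths are an error.
#'
#' @param text a Newick string, or a path to a file holding one.
#' @return a `phylo` object; node labels carry supports where present.
#' @export
parse_newick <- function(text) {
  tr <- if (length(text) == 1L && !grepl("\\(", text) && file.exists(text)) {
    ape::read.tree(text)
  } else {
    ape::read.tree(text = text)
  }
  if (is.null(tr)) stop("could not parse Newick input")
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate leaf label: ",
         tr$tip.label[duplicated(tr$tip.label)][1L])
  }
  if (is.null(tr$edge.length)) {
    warning("no branch lengths in Newick input; defaulting to 0")
    tr$edge.length <- rep(0, nrow(tr$edge))
  }
  if (anyNA(tr$edge.length)) {
    warning("missing branch lengths defaulted to 0")
    tr$edge.length[is.na(tr$edge.length)] <- 0
  }
  if (any(tr$edge.length < 0)) stop("negative branch length in input tree")
  if (!is.null(tr$node.label)) {
    sup <- suppressWarnings(as.numeric(tr$node.label))
    num <- !is.na(sup)
    if (any(num) && all(sup[num] >= 0 & sup[num] <= 1) && any(sup[num] > 0)) {
      warning("support values in [0, 1] rescaled to 0-100")
      sup[num] <- 100 * sup[num]
    }
    if (any(num & (sup < 0 | sup > 100))) {
      stop("support values must lie in [0, 100]")
    }
    tr$node.label <- ifelse(num, formatC(sup, format = "g", digits = 15), tr$node.label)
  }
  tr
}

#' Write a tree as Newick
#'
#' @param tree a `phylo` object.
#' @param path optional file; if omitted the Newick string is returned.
#' @return the Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL) {
  s <- ape::write.tree(tree, digits = 17)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

node_supports <- function(tree) {
  n_int <- tree$Nnode
  if (is.null(tree$node.label)) return(rep(NA_real_, n_int))
  suppressWarnings(as.numeric(tree$node.label))
}

#' Bipartitions (splits) of a tree
#'
#' One bipartition per edge under the unrooted interpretation (the two
#' edges incident to a root of degree 2 induce the same split once, not
#' twice). Each split is canonically oriented: the reported side is the
#' one containing the lexicographically smallest taxon. Non-trivial
#' splits carry the support value of their internal edge when one is
#' recorded.
#'
#' @param tree a `phylo` object with at least 2 leaves.
#' @param include_trivial also return the leaf (terminal-edge) splits.
#' @return data.frame with columns `split` (canonical `|`-free key:
#'   taxa of the canonical side, sorted, comma-separated), `size`
#'   (canonical side size), `support` (numeric or NA), `trivial`.
#' @export
bipartitions <- function(tree, include_trivial = FALSE) {
  taxa <- sort(tree$tip.label)
  n <- length(taxa)
  stopifnot(n >= 2L)
  sup <- node_supports(tree)
  ntip <- length(tree$tip.label)
  res <- list()
  # clade membership below every edge, by postorder accumulation
  po <- ape::reorder.phylo(tree, "postorder")
  below <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- tree$tip.label[i]
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1L]; ch <- po$edge[k, 2L]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  keys <- character(0); sups <- numeric(0); sizes <- integer(0); triv <- logical(0)
  for (k in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[k, 2L]
    side <- sort(below[[ch]])
    if (length(side) == 0L || length(side) == n) next
    if (!(taxa[1L] %in% side)) side <- setdiff(taxa, side)
    key <- paste(side, collapse = ",")
    s <- if (ch > ntip) sup[ch - ntip] else NA_real_
    j <- match(key, keys)
    if (is.na(j)) {
      keys <- c(keys, key)
      sups <- c(sups, s)
      sizes <- c(sizes, min(length(side), n - length(side)))
      triv <- c(triv, min(length(side), n - length(side)) == 1L)
    } else if (!is.na(s) && (is.na(sups[j]) || s > sups[j])) {
      sups[j] <- s
    }
  }
  out <- data.frame(split = keys, size = sizes, support = sups,
                    trivial = triv, stringsAsFactors = FALSE)
  if (!include_trivial) out <- out[!out$trivial, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "taxa") <- taxa
  out
}

split_sides <- function(key, taxa) {
  a <- strsplit(key, ",", fixed = TRUE)[[1L]]
  list(a = a, b = setdiff(taxa, a))
}

#' Are two splits of the same taxon set compatible?
#'
#' Two bipartitions can coexist in one tree iff at least one of the four
#' pairwise side intersections is empty. A split is compatible with a
#' reference set iff it is compatible with every member.
#'
#' @param split a split key (comma-separated canonical side) or the
#'   `split` column of a [bipartitions()] row.
#' @param reference_splits character vector of split keys.
#' @param taxa the common taxon set both splits are defined on.
#' @return logical.
#' @export
compatible <- function(split, reference_splits, taxa) {
  taxa <- sort(taxa)
  s1 <- split_sides(split, taxa)
  if (!all(c(s1$a, s1$b) %in% taxa) || length(s1$a) + length(s1$b) != length(taxa)) {
    stop("split is not defined on the given taxon set")
  }
  for (r in reference_splits) {
    s2 <- split_sides(r, taxa)
    if (length(s2$a) + length(s2$b) != length(taxa)) {
      stop("reference split is not defined on the given taxon set")
    }
    ok <- !length(intersect(s1$a, s2$a)) || !length(intersect(s1$a, s2$b)) ||
          !length(intersect(s1$b, s2$a)) || !length(intersect(s1$b, s2$b))
    if (!ok) return(FALSE)
  }
  TRUE
}

#' Patristic distance matrix
#'
#' The patristic distance between two leaves is the sum of branch lengths
#' along the unique path connecting them.
#'
#' @param tree a `phylo` object with branch lengths.
#' @return symmetric numeric matrix with zero diagonal, taxa as dimnames.
#' @export
patristic_matrix <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  d <- stats::cophenetic(tree)
  d[sort(rownames(d)), sort(rownames(d))]
}

#' Restrict a tree to a taxon subset
#'
#' Returns the induced subtree: unsampled leaves are pruned and the
#' resulting degree-2 nodes are suppressed with their branch lengths
#' summed, so patristic distances among retained taxa are unchanged.
#' When several original internal edges collapse onto one retained edge,
#' the retained edge carries the maximum of their support values.
#'
#' @param tree a `phylo` object.
#' @param taxa leaves to keep (at least 2).
#' @return a `phylo` object on `taxa`.
#' @export
restrict_tree <- function(tree, taxa) {
  unknown <- setdiff(taxa, tree$tip.label)
  if (length(unknown)) stop("unknown taxa: ", paste(unknown, collapse = ", "))
  if (length(taxa) < 2L) stop("keep at least 2 taxa")
  if (setequal(taxa, tree$tip.label)) return(tree)
  sub <- ape::keep.tip(tree, taxa)
  # recompute supports: original splits restricted to the kept taxa
  orig <- bipartitions(tree, include_trivial = FALSE)
  kept <- sort(sub$tip.label)
  restricted_support <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(orig))) {
    sides <- split_sides(orig$split[i], attr(orig, "taxa"))
    a <- intersect(sides$a, kept); b <- intersect(sides$b, kept)
    if (length(a) < 1L || length(b) < 1L) next
    if (min(length(a), length(b)) < 2L) next
    side <- if (kept[1L] %in% a) sort(a) else sort(b)
    key <- paste(side, collapse = ",")
    s <- orig$support[i]
    old <- restricted_support[[key]]
    if (!is.na(s) && (is.null(old) || is.na(old) || s > old)) {
      restricted_support[[key]] <- s
    } else if (is.null(old)) {
      restricted_support[[key]] <- s
    }
  }
  set_split_supports(sub, restricted_support)
}

# write supports (an env keyed by canonical split) onto a tree's node labels
set_split_supports <- function(tree, support_env) {
  ntip <- length(tree$tip.label)
  taxa <- sort(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  below <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- tree$tip.label[i]
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1L]; ch <- po$edge[k, 2L]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  lab <- rep("", tree$Nnode)
  for (nd in seq_len(tree$Nnode)) {
    side <- sort(below[[ntip + nd]])
    if (length(side) %in% c(0L, length(taxa))) next
    if (!(taxa[1L] %in% side)) side <- setdiff(taxa, side)
    key <- paste(side, collapse = ",")
    s <- support_env[[key]]
    if (!is.null(s) && !is.na(s)) {
      lab[nd] <- formatC(s, format = "g", digits = 15)
    }
  }
  tree$node.label <- lab
  tree
}

#' Support value of a clade
#'
#' Looks for the edge whose bipartition isolates exactly the given taxon
#' set (unrooted interpretation) and returns its recorded support.
#'
#' @param tree a `phylo` object.
#' @param taxa a proper, non-empty subset of the leaves.
#' @return a list with `present` (does the tree contain that split?) and
#'   `support` (numeric, NA when the edge carries no value or the clade
#'   is absent).
#' @export
clade_support <- function(tree, taxa) {
  leaves <- sort(tree$tip.label)
  if (!all(taxa %in% leaves)) {
    stop("unknown taxa: ", paste(setdiff(taxa, leaves), collapse = ", "))
  }
  if (!length(taxa) || length(taxa) >= length(leaves)) {
    stop("taxa must be a proper non-empty subset of the leaves")
  }
  side <- sort(taxa)
  if (!(leaves[1L] %in% side)) side <- setdiff(leaves, side)
  key <- paste(side, collapse = ",")
  bp <- bipartitions(tree, include_trivial = TRUE)
  j <- match(key, bp$split)
  if (is.na(j)) return(list(present = FALSE, support = NA_real_))
  list(present = TRUE, support = bp$support[j])
}
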