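#' Long-branch-attraction quartet geometry
#'
#' Builds the classic two-long/two-short ("Felsenstein zone") unrooted
#' quartet ((L1,S1),(L2,S2)): each long leaf is sister to a short leaf,
#' the central edge is short, and methods that underestimate multiple
#' substitutions tend to pull L1 and L2 together instead. An optional
#' outgroup with its own long stem can be attached at the midpoint of
#' the central edge, mimicking rooting with a distant outgroup.
#'
#' @param long_len terminal branch length of the two long leaves L1, L2.
#' @param short_len terminal branch length of the two short leaves S1, S2.
#' @param internal_len length of the central edge.
#' @param outgroup_len stem length of the optional outgroup leaf `Out`;
#'   `NULL` for no outgroup.
#' @return a `phylo` object; attribute `"true_split"` records the
#'   generating non-trivial split as a canonical key.
#' @export
make_lba_tree <- function(long_len = 1.0, short_len = 0.1,
                          internal_len = 0.02, outgroup_len = NULL) {
  stopifnot(long_len >= 0, short_len >= 0, internal_len >= 0)
  if (is.null(outgroup_len)) {
    nwk <- sprintf("((L1:%s,S1:%s):%s,L2:%s,S2:%s);",
                   fmt_len(long_len), fmt_len(short_len),
                   fmt_len(internal_len), fmt_len(long_len),
                   fmt_len(short_len))
  } else {
    stopifnot(outgroup_len >= 0)
    half <- internal_len / 2
    nwk <- sprintf("((L1:%s,S1:%s):%s,(L2:%s,S2:%s):%s,Out:%s);",
                   fmt_len(long_len), fmt_len(short_len), fmt_len(half),
                   fmt_len(long_len), fmt_len(short_len), fmt_len(half),
                   fmt_len(outgroup_len))
  }
  tr <- ape::read.tree(text = nwk)
  attr(tr, "true_split") <- "L1,S1"
  tr
}

#' Implant a horizontal transfer / contamination into one gene
#'
#' Replaces the recipient taxon's cells within the named gene by the
#' donor's, leaving every other cell untouched — the ground-truth
#' generator for the supported-branch congruence screen: a convincingly
#' alien sequence inside an otherwise clean supermatrix.
#'
#' @param sm a [supermatrix].
#' @param gene partition name.
#' @param donor,recipient distinct taxon names; the donor block must not
#'   be entirely missing.
#' @return the modified [supermatrix]; attribute `"implants"` logs the
#'   event(s).
#' @export
implant_transfer <- function(sm, gene, donor, recipient) {
  stopifnot(is_supermatrix(sm))
  i <- match(gene, sm$partitions$name)
  if (is.na(i)) stop("unknown partition: ", gene)
  if (donor == recipient) stop("donor and recipient must differ")
  for (t in c(donor, recipient)) {
    if (!t %in% taxa_names(sm)) stop("unknown taxon: ", t)
  }
  cols <- sm$partitions$start[i]:sm$partitions$end[i]
  block <- sm$aln[donor, cols]
  if (all(is_missing_cell(block))) stop("donor block is entirely missing in ", gene)
  a <- unclass(sm$aln)
  a[recipient, cols] <- a[donor, cols]
  out <- supermatrix(msa(a, alphabet = attr(sm$aln, "alphabet")), sm$partitions)
  log_old <- attr(sm, "implants")
  attr(out, "implants") <- rbind(log_old, data.frame(
    gene = gene, donor = donor, recipient = recipient,
    stringsAsFactors = FALSE))
  out
}

#' Mask cells or gene-by-taxon blocks as missing data
#'
#' Raises the missing-data fraction of a supermatrix to a target by
#' setting uniformly chosen units to `?`, without touching cells that
#' are already missing. With `unit = "cell"` individual cells are
#' masked; with `unit = "gene_by_taxon"` entire gene-by-taxon blocks
#' are, emulating the absent-sequence pattern of real supermatrices.
#' The achieved fraction lands within one unit of the closest feasible
#' value, and a fixed seed reproduces the mask exactly.
#'
#' @param sm a [supermatrix].
#' @param target_fraction desired overall missing fraction in \[0, 1).
#' @param unit `"cell"` or `"gene_by_taxon"`.
#' @param seed integer seed.
#' @return the masked [supermatrix].
#' @export
mask_missing <- function(sm, target_fraction,
                         unit = c("cell", "gene_by_taxon"), seed = 1L) {
  stopifnot(is_supermatrix(sm))
  unit <- match.arg(unit)
  if (target_fraction < 0 || target_fraction >= 1) {
    stop("target_fraction must be in [0, 1)")
  }
  a <- unclass(sm$aln)
  mm <- is_missing_cell(sm$aln)
  total <- length(a)
  current <- sum(mm)
  want <- round(target_fraction * total)
  if (want < current) {
    stop(sprintf(
      "target fraction %.3f is below the current missing fraction %.3f",
      target_fraction, current / total))
  }
  need <- want - current
  set.seed(seed)
  if (unit == "cell") {
    avail <- which(!mm)
    k <- min(need, length(avail))
    if (k > 0L) a[sample(avail, k)] <- "?"
  } else {
    p <- sm$partitions
    blocks <- expand.grid(taxon = rownames(a), part = seq_len(nrow(p)),
                          stringsAsFactors = FALSE)
    sizes <- integer(nrow(blocks))
    free <- integer(nrow(blocks))
    for (b in seq_len(nrow(blocks))) {
      cols <- p$start[blocks$part[b]]:p$end[blocks$part[b]]
      sizes[b] <- length(cols)
      free[b] <- sum(!mm[blocks$taxon[b], cols])
    }
    open <- which(free > 0L)
    ord <- sample(open)
    gained <- 0L
    for (b in ord) {
      if (gained >= need) break
      # stop before overshooting past the nearest feasible point
      if (gained + free[b] - need > need - gained) break
      cols <- p$start[blocks$part[b]]:p$end[blocks$part[b]]
      a[blocks$taxon[b], cols] <- "?"
      gained <- gained + free[b]
    }
  }
  supermatrix(msa(a, alphabet = attr(sm$aln, "alphabet")), sm$partitions)
}
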