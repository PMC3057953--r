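#' Supported-branch congruence screen against a reference tree
#'
#' An a-posteriori orthology check: every non-trivial split of each
#' single-gene tree whose bootstrap support reaches the threshold is
#' tested for compatibility with the concatenated reference topology
#' restricted to that gene's taxon set. A well-supported split that
#' cannot coexist with the reference counts as a conflict; pooled over
#' genes, the conflict rate (conflicting / supported splits) summarizes
#' how cleanly the gene set behaves. Genes whose trees are induced
#' subtrees of the reference produce a rate of exactly 0; contaminated
#' or paralogous genes surface as strongly supported conflicts.
#'
#' @param gene_trees named list of `phylo` gene trees with bootstrap
#'   supports as node labels. Every leaf must occur in the reference.
#' @param reference the concatenated reference `phylo` tree.
#' @param threshold minimum support for a split to be testable
#'   (default 70, the conventional bootstrap cut-off).
#' @return an object of class `congruence_report`: list with `per_gene`
#'   (data.frame: gene, n_supported, n_conflicting, n_shared_taxa),
#'   `conflicts` (data.frame: gene, split, support), `conflict_rate`,
#'   `n_supported`, `n_conflicting`, and `no_testable_branches` (TRUE
#'   when no split anywhere reached the threshold, in which case the
#'   rate is reported as 0).
#' @export
congruence_screen <- function(gene_trees, reference, threshold = 70) {
  if (!length(gene_trees)) stop("empty gene list")
  if (is.null(names(gene_trees)) || any(!nzchar(names(gene_trees)))) {
    stop("gene trees must be named")
  }
  per <- vector("list", length(gene_trees))
  confs <- list()
  for (g in seq_along(gene_trees)) {
    gt <- gene_trees[[g]]
    nm <- names(gene_trees)[g]
    unknown <- setdiff(gt$tip.label, reference$tip.label)
    if (length(unknown)) {
      stop("gene ", nm, " has leaves absent from the reference: ",
           paste(unknown, collapse = ", "))
    }
    shared <- gt$tip.label
    if (length(shared) < 4L) {
      message("gene ", nm, " has fewer than 4 taxa; no testable branches")
      per[[g]] <- data.frame(gene = nm, n_supported = 0L, n_conflicting = 0L,
                             n_shared_taxa = length(shared),
                             stringsAsFactors = FALSE)
      next
    }
    ref_r <- restrict_tree(reference, shared)
    ref_splits <- bipartitions(ref_r, include_trivial = FALSE)$split
    bp <- bipartitions(gt, include_trivial = FALSE)
    sup_ok <- !is.na(bp$support) & bp$support >= threshold
    n_sup <- sum(sup_ok)
    n_conf <- 0L
    for (i in which(sup_ok)) {
      if (!compatible(bp$split[i], ref_splits, sort(shared))) {
        n_conf <- n_conf + 1L
        confs[[length(confs) + 1L]] <- data.frame(
          gene = nm, split = bp$split[i], support = bp$support[i],
          stringsAsFactors = FALSE)
      }
    }
    per[[g]] <- data.frame(gene = nm, n_supported = n_sup,
                           n_conflicting = n_conf,
                           n_shared_taxa = length(shared),
                           stringsAsFactors = FALSE)
  }
  per_gene <- do.call(rbind, per)
  n_supported <- sum(per_gene$n_supported)
  n_conflicting <- sum(per_gene$n_conflicting)
  structure(list(
    per_gene = per_gene,
    conflicts = if (length(confs)) do.call(rbind, confs) else
      data.frame(gene = character(), split = character(),
                 support = numeric(), stringsAsFactors = FALSE),
    conflict_rate = if (n_supported > 0L) n_conflicting / n_supported else 0,
    n_supported = n_supported,
    n_conflicting = n_conflicting,
    no_testable_branches = n_supported == 0L
  ), class = "congruence_report")
}

#' @export
print.congruence_report <- function(x, ...) {
  cat(sprintf(
    "congruence screen: %d supported splits, %d conflicting (rate %.3f)%s\n",
    x$n_supported, x$n_conflicting, x$conflict_rate,
    if (x$no_testable_branches) " [no testable branches]" else ""))
  flagged <- x$per_gene[x$per_gene$n_conflicting > 0L, , drop = FALSE]
  if (nrow(flagged)) {
    cat("genes with supported conflicts:\n")
    print(flagged, row.names = FALSE)
  }
  invisible(x)
}
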