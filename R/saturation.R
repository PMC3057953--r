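#' Saturation slope: uncorrected versus patristic distances
#'
#' Quantifies substitutional saturation by ordinary least squares of the
#' uncorrected p-distance between two taxa on their patristic distance
#' in a reference tree (typically the best tree from a model-based
#' analysis, whose branch lengths account for multiple substitutions).
#' Data without saturation accumulate observed differences as fast as
#' tree distance, slope = 1; multiple substitutions compress observed
#' distances, so the slope falls below 1 as saturation grows (the most
#' saturated datasets in practice sit near 0.3-0.5). The fit uses a free
#' intercept and every unordered pair of taxa shared between alignment
#' and tree whose p-distance is defined.
#'
#' @param x an [msa] or [supermatrix].
#' @param tree a `phylo` reference tree with branch lengths; at least 3
#'   taxa must be shared with `x`.
#' @return an object of class `saturation_fit`: list with `slope`,
#'   `intercept`, `r_squared`, `n_pairs`, `excluded_pairs`.
#' @export
saturation_slope <- function(x, tree) {
  a <- if (is_supermatrix(x)) x$aln else x
  stopifnot(is_msa(a))
  shared <- intersect(rownames(a), tree$tip.label)
  if (length(shared) < 3L) stop("fewer than 3 taxa shared between alignment and tree")
  p <- p_distance(a[shared, ])
  g <- patristic_matrix(ape::keep.tip(tree, shared))
  ord <- sort(shared)
  p <- p[ord, ord]; g <- g[ord, ord]
  iu <- upper.tri(p)
  px <- g[iu]   # patristic on x
  py <- p[iu]   # uncorrected on y
  keep <- is.finite(py) & is.finite(px)
  excluded <- sum(!keep)
  if (sum(keep) < 3L) stop("fewer than 3 usable taxon pairs")
  fit <- stats::lm(py[keep] ~ px[keep])
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((py[keep] - mean(py[keep]))^2)
  r2 <- if (tss > 0) max(0, min(1, 1 - rss / tss)) else 1
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2,
                 n_pairs = sum(keep),
                 excluded_pairs = excluded),
            class = "saturation_fit")
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat(sprintf(
    "saturation fit: slope %.3f (1 = no saturation), intercept %.4f, R^2 %.3f, %d pairs (%d excluded)\n",
    x$slope, x$intercept, x$r_squared, x$n_pairs, x$excluded_pairs))
  invisible(x)
}

#' Per-partition saturation slopes
#'
#' Applies [saturation_slope()] to each gene of a supermatrix against
#' one fixed tree, and ranks genes by slope in decreasing order (higher
#' slope = less saturated = less prone to carry non-phylogenetic
#' signal). Partitions with fewer than 3 usable pairs are reported with
#' `NA` slope, never dropped silently.
#'
#' @param sm a [supermatrix].
#' @param tree a `phylo` reference tree.
#' @return data.frame, one row per partition, sorted by decreasing
#'   slope: `partition`, `slope`, `intercept`, `r_squared`, `n_pairs`,
#'   `excluded_pairs`.
#' @export
saturation_by_partition <- function(sm, tree) {
  stopifnot(is_supermatrix(sm))
  rows <- lapply(sm$partitions$name, function(nm) {
    g <- extract_partition(sm, nm, drop_all_missing = TRUE)
    r <- tryCatch(saturation_slope(g, tree), error = function(e) NULL)
    if (is.null(r)) {
      data.frame(partition = nm, slope = NA_real_, intercept = NA_real_,
                 r_squared = NA_real_, n_pairs = 0L, excluded_pairs = NA_integer_,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(partition = nm, slope = r$slope, intercept = r$intercept,
                 r_squared = r$r_squared, n_pairs = r$n_pairs,
                 excluded_pairs = r$excluded_pairs, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out[order(-out$slope, out$partition, na.last = TRUE), , drop = FALSE]
}
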