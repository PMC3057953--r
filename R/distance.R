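#' Uncorrected (p) distance matrix
#'
#' For each pair of taxa, the proportion of differing sites among the
#' columns where neither sequence holds a missing symbol (pairwise
#' deletion). Pairs with zero comparable columns are undefined (`NaN`).
#' Supermatrices with heavy missing data keep usable pairs this way,
#' where complete deletion could empty the matrix.
#'
#' @param x an [msa] or [supermatrix].
#' @return symmetric matrix of proportions with zero diagonal; attribute
#'   `"n_comparable"` holds the per-pair comparable-column counts.
#' @export
p_distance <- function(x) {
  a <- if (is_supermatrix(x)) x$aln else x
  stopifnot(is_msa(a), n_taxa(a) >= 2L)
  m <- unclass(a)
  m[is_missing_cell(a)] <- NA
  n <- nrow(m)
  taxa <- rownames(m)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  nc <- matrix(ncol(m), n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) {
    xi <- m[i, ]
    for (j in (i + 1L):n) {
      xj <- m[j, ]
      ok <- !is.na(xi) & !is.na(xj)
      cnt <- sum(ok)
      pij <- if (cnt == 0L) NaN else sum(xi[ok] != xj[ok]) / cnt
      d[i, j] <- d[j, i] <- pij
      nc[i, j] <- nc[j, i] <- cnt
    }
  }
  attr(d, "n_comparable") <- nc
  d
}

#' Distance-correction model
#'
#' The s-state Poisson/gamma family (equal-rate corrections in the
#' Jukes-Cantor style): closed forms that recover the expected number of
#' substitutions per site from an observed proportion of differences,
#' for nucleotide (s = 4) or amino-acid (s = 20) data, optionally with
#' gamma-distributed rate variation across sites.
#'
#' @param kind `"uncorrected"`, `"poisson"`, or `"gamma"`.
#' @param s alphabet size, 4 or 20.
#' @param shape gamma shape a > 0 (required for `kind = "gamma"`).
#' @return an object of class `distance_model`.
#' @export
distance_model <- function(kind = c("uncorrected", "poisson", "gamma"),
                           s = 4, shape = NULL) {
  kind <- match.arg(kind)
  if (!s %in% c(4, 20)) stop("alphabet size s must be 4 or 20")
  if (kind == "gamma") {
    if (is.null(shape) || !is.finite(shape) || shape <= 0) {
      stop("gamma correction needs a finite positive shape")
    }
  }
  structure(list(kind = kind, s = s, shape = shape),
            class = "distance_model")
}

#' Apply a distance correction
#'
#' Maps observed proportions of differing sites p to evolutionary
#' distances: identity for `uncorrected`; the s-state Poisson correction
#' \eqn{-(s-1)/s \log(1 - s p/(s-1))}; or its gamma-rates counterpart
#' \eqn{a (s-1)/s ((1 - s p/(s-1))^{-1/a} - 1)}. Values at or beyond the
#' saturation plateau p >= (s-1)/s are undefined and returned as `NaN`
#' rather than raising an error; multiple-substitution corrections never
#' shrink a distance.
#'
#' @param p numeric vector or matrix of observed proportions in \[0, 1\].
#' @param model a [distance_model()].
#' @return corrected distances, same shape as `p`.
#' @export
correct_distance <- function(p, model) {
  stopifnot(inherits(model, "distance_model"))
  s <- model$s
  lim <- (s - 1) / s
  if (model$kind == "uncorrected") return(p)
  arg <- 1 - p / lim
  bad <- !is.na(p) & p >= lim
  arg[bad] <- NA
  out <- switch(model$kind,
    poisson = -lim * log(arg),
    gamma = model$shape * lim * (arg^(-1 / model$shape) - 1)
  )
  out[bad] <- NaN
  out
}

#' Model-corrected distance matrix from an alignment
#'
#' Convenience composition of [p_distance()] and [correct_distance()].
#'
#' @inheritParams p_distance
#' @param model a [distance_model()].
#' @return symmetric distance matrix (undefined entries `NaN`).
#' @export
corrected_distance_matrix <- function(x, model = distance_model("uncorrected")) {
  p <- p_distance(x)
  d <- correct_distance(p, model)
  attr(d, "n_comparable") <- attr(p, "n_comparable")
  d
}
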