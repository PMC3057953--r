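#' Supermatrix: concatenated gene alignments with partitions
#'
#' A `supermatrix` couples an [msa] with an ordered partition table: one
#' row per gene giving its name and 1-based inclusive column range.
#' Partitions are non-overlapping and jointly cover every column, so
#' extracting all partitions and re-concatenating reproduces the
#' alignment exactly.
#'
#' @param aln an [msa].
#' @param partitions data.frame with columns `name`, `start`, `end` and
#'   optionally `alphabet`, `model`.
#' @return an object of class `supermatrix` (a list with elements `aln`
#'   and `partitions`).
#' @export
supermatrix <- function(aln, partitions) {
  stopifnot(is_msa(aln), is.data.frame(partitions))
  p <- partitions
  if (is.null(p$alphabet)) p$alphabet <- attr(aln, "alphabet")
  p$alphabet[is.na(p$alphabet)] <- attr(aln, "alphabet")
  if (is.null(p$model)) p$model <- ""
  p <- p[, c("name", "start", "end", "alphabet", "model")]
  if (anyDuplicated(p$name)) stop("duplicate partition name")
  if (any(p$start > p$end) || any(p$start < 1L) || any(p$end > n_sites(aln))) {
    stop("partition ranges must satisfy 1 <= start <= end <= alignment length")
  }
  o <- order(p$start)
  po <- p[o, ]
  if (any(po$start[-1L] != po$end[-nrow(po)] + 1L) || po$start[1L] != 1L ||
      po$end[nrow(po)] != n_sites(aln)) {
    stop("partitions must be non-overlapping and cover every column")
  }
  structure(list(aln = aln, partitions = p), class = "supermatrix")
}

#' @rdname supermatrix
#' @export
is_supermatrix <- function(x) inherits(x, "supermatrix")

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("supermatrix: %d taxa x %d sites, %d partition(s)\n",
              n_taxa(x$aln), n_sites(x$aln), nrow(x$partitions)))
  cat(sprintf("missing data: %.1f%%\n", 100 * missing_fraction(x)))
  print(utils::head(x$partitions, 10L), row.names = FALSE)
  invisible(x)
}

#' Concatenate gene alignments into a supermatrix
#'
#' Builds the standard phylogenomic "supergene": the taxon set is the
#' union over genes, taxa absent from a gene get a block of `?`, and each
#' gene becomes one partition in input order. Taxon matching is exact
#' string match.
#'
#' @param genes named list of [msa] objects, one per gene.
#' @return a [supermatrix].
#' @examples
#' g1 <- msa(c(a = "ACGT", b = "ACGA", c = "ACCA"), "nt")
#' g2 <- msa(c(a = "GGGTTT", b = "GGGTTA"), "nt")
#' sm <- concatenate(list(G1 = g1, G2 = g2))
#' missing_fraction(sm)  # 6 fill cells of 30
#' @export
concatenate <- function(genes) {
  if (!length(genes)) stop("no genes to concatenate")
  if (is.null(names(genes)) || any(!nzchar(names(genes)))) {
    stop("genes must be named")
  }
  if (anyDuplicated(names(genes))) {
    stop("duplicate gene name: ", names(genes)[duplicated(names(genes))][1L])
  }
  stopifnot(all(vapply(genes, is_msa, TRUE)))
  alphs <- vapply(genes, attr, "", "alphabet")
  if (length(unique(alphs)) > 1L) {
    stop("genes mix alphabets (", paste(unique(alphs), collapse = ", "),
         "); concatenate genes of one alphabet at a time")
  }
  taxa <- unique(unlist(lapply(genes, rownames)))
  lens <- vapply(genes, ncol, 1L)
  total <- sum(lens)
  m <- matrix("?", nrow = length(taxa), ncol = total,
              dimnames = list(taxa, NULL))
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  for (i in seq_along(genes)) {
    g <- genes[[i]]
    m[rownames(g), starts[i]:ends[i]] <- unclass(g)
  }
  parts <- data.frame(name = names(genes), start = starts, end = ends,
                      alphabet = alphs[1L], model = "",
                      stringsAsFactors = FALSE, row.names = NULL)
  supermatrix(msa(m, alphabet = alphs[1L]), parts)
}

#' Extract one partition as an alignment
#'
#' @param sm a [supermatrix].
#' @param name partition name.
#' @param drop_all_missing drop taxa whose block is entirely missing.
#' @return an [msa].
#' @export
extract_partition <- function(sm, name, drop_all_missing = FALSE) {
  stopifnot(is_supermatrix(sm))
  i <- match(name, sm$partitions$name)
  if (is.na(i)) stop("unknown partition: ", name)
  a <- sm$aln[, sm$partitions$start[i]:sm$partitions$end[i]]
  if (drop_all_missing) {
    keep <- rowSums(!is_missing_cell(a)) > 0L
    a <- a[keep, ]
  }
  a
}

#' Overall missing-data fraction of a supermatrix
#'
#' The proportion of cells holding a missing symbol (`-`, `?`, and `N`
#' for nucleotides or `X` for amino acids) over all taxa-by-site cells.
#' Indel gaps are not distinguished from absent data.
#'
#' @param sm a [supermatrix] or [msa].
#' @return proportion in \[0, 1\].
#' @export
missing_fraction <- function(sm) {
  a <- if (is_supermatrix(sm)) sm$aln else sm
  mean(is_missing_cell(a))
}

#' Per-taxon missing-data profile
#'
#' @param sm a [supermatrix].
#' @return data.frame with one row per taxon: `taxon`, `frac_missing`
#'   (fraction of missing cells), and `n_partitions_missing` (partitions
#'   whose entire block for that taxon is missing).
#' @export
per_taxon_missing <- function(sm) {
  stopifnot(is_supermatrix(sm))
  mm <- is_missing_cell(sm$aln)
  p <- sm$partitions
  block_missing <- sapply(seq_len(nrow(p)), function(i) {
    rowMeans(mm[, p$start[i]:p$end[i], drop = FALSE]) == 1
  })
  if (is.null(dim(block_missing))) block_missing <- matrix(block_missing, nrow = 1L)
  data.frame(taxon = rownames(mm),
             frac_missing = rowMeans(mm),
             n_partitions_missing = rowSums(block_missing),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Subset a supermatrix to a set of taxa
#'
#' Keeps columns and partitions untouched; only rows are dropped. Row
#' order follows the original matrix.
#'
#' @param sm a [supermatrix].
#' @param keep character vector of taxon names to retain (at least 2).
#' @return a [supermatrix].
#' @export
subset_taxa <- function(sm, keep) {
  stopifnot(is_supermatrix(sm))
  unknown <- setdiff(keep, taxa_names(sm))
  if (length(unknown)) {
    stop("unknown taxa: ", paste(unknown, collapse = ", "))
  }
  if (length(unique(keep)) < 2L) stop("keep at least 2 taxa")
  rows <- rownames(sm$aln)[rownames(sm$aln) %in% keep]
  supermatrix(sm$aln[rows, ], sm$partitions)
}

#' Read / write a plain-text partition table
#'
#' One partition per line, `name = start-end [alphabet]`.
#'
#' @param path file path.
#' @return data.frame usable as the `partitions` argument of
#'   [supermatrix()].
#' @export
read_partitions <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  m <- regmatches(lines,
    regexec("^(\\S+)\\s*=\\s*(\\d+)\\s*-\\s*(\\d+)(?:\\s+(\\S+))?$", lines))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad)) stop("malformed partition line: ", lines[bad][1L])
  data.frame(
    name = vapply(m, `[`, "", 2L),
    start = as.integer(vapply(m, `[`, "", 3L)),
    end = as.integer(vapply(m, `[`, "", 4L)),
    alphabet = {
      a <- vapply(m, `[`, "", 5L); a[!nzchar(a)] <- NA; a
    },
    model = "", stringsAsFactors = FALSE)
}

#' @rdname read_partitions
#' @param partitions a partition data.frame.
#' @export
write_partitions <- function(partitions, path) {
  writeLines(sprintf("%s = %d-%d %s", partitions$name, partitions$start,
                     partitions$end, partitions$alphabet), path)
  invisible(path)
}
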