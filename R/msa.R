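#' Multiple sequence alignment container
#'
#' An `msa` object is a character matrix (taxa in rows, columns in sites)
#' with an `alphabet` attribute, either `"nt"` or `"aa"`. All residues are
#' stored uppercase. The missing-state symbols are `-` and `?` for both
#' alphabets, plus `N` for nucleotides and `X` for amino acids; all of them
#' count as missing for the missing-data statistics (indels are not
#' distinguished from absent data).
#'
#' @param x named character vector of equal-length sequence strings, or a
#'   character matrix with one row per taxon (rownames = taxon names).
#' @param alphabet `"nt"` or `"aa"`.
#' @return an object of class `msa`.
#' @examples
#' a <- msa(c(A = "ACGTA", B = "ACGTT"), alphabet = "nt")
#' n_taxa(a); n_sites(a)
#' @export
msa <- function(x, alphabet = c("nt", "aa")) {
  alphabet <- match.arg(alphabet)
  if (is.character(x) && !is.matrix(x)) {
    if (is.null(names(x))) stop("sequences must be named by taxon")
    lens <- nchar(x)
    if (length(unique(lens)) > 1L) {
      bad <- names(x)[which(lens != lens[1L])[1L]]
      stop("alignment rows have unequal lengths; first offending taxon: ",
           bad, call. = FALSE)
    }
    m <- do.call(rbind, strsplit(x, "", fixed = TRUE))
    rownames(m) <- names(x)
    x <- m
  }
  if (!is.matrix(x) || !is.character(x)) stop("x must be a character matrix")
  if (is.null(rownames(x))) stop("alignment matrix must have taxon rownames")
  validate_msa(structure(toupper(x), class = "msa", alphabet = alphabet))
}

#' @rdname msa
#' @export
is_msa <- function(x) inherits(x, "msa")

#' Residue and missing-state alphabets
#'
#' @param alphabet `"nt"` or `"aa"`.
#' @return character vector of allowed symbols.
#' @keywords internal
residue_states <- function(alphabet) {
  switch(alphabet,
    nt = c("A", "C", "G", "T"),
    aa = c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
    stop("unknown alphabet: ", alphabet)
  )
}

missing_states <- function(alphabet) {
  switch(alphabet, nt = c("-", "?", "N"), aa = c("-", "?", "X"))
}

validate_msa <- function(x) {
  taxa <- rownames(x)
  if (anyDuplicated(taxa)) {
    stop("duplicate taxon name: ", taxa[duplicated(taxa)][1L], call. = FALSE)
  }
  if (any(!nzchar(taxa))) stop("empty taxon name", call. = FALSE)
  alphabet <- attr(x, "alphabet")
  ok <- c(residue_states(alphabet), missing_states(alphabet))
  bad <- setdiff(unique(as.vector(unclass(x))), ok)
  if (length(bad)) {
    stop("characters outside the ", alphabet, " alphabet: ",
         paste(bad, collapse = " "), call. = FALSE)
  }
  x
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("msa: %d taxa x %d sites (%s)\n",
              nrow(x), ncol(x), attr(x, "alphabet")))
  show <- utils::head(rownames(x), 6L)
  for (t in show) {
    s <- paste(x[t, seq_len(min(40L, ncol(x)))], collapse = "")
    cat(sprintf("  %-20s %s%s\n", t, s, if (ncol(x) > 40L) "..." else ""))
  }
  if (nrow(x) > 6L) cat(sprintf("  ... and %d more taxa\n", nrow(x) - 6L))
  invisible(x)
}

#' @export
`[.msa` <- function(x, i, j, ...) {
  m <- unclass(x)[i, j, drop = FALSE]
  structure(m, class = "msa", alphabet = attr(x, "alphabet"))
}

#' @rdname msa
#' @export
n_taxa <- function(x) nrow(x)

#' @rdname msa
#' @export
n_sites <- function(x) ncol(x)

#' @rdname msa
#' @export
taxa_names <- function(x) {
  if (is_supermatrix(x)) rownames(x$aln) else rownames(x)
}

#' Logical mask of missing cells
#'
#' @param x an `msa`.
#' @return logical matrix, `TRUE` where the cell holds a missing symbol.
#' @export
is_missing_cell <- function(x) {
  m <- matrix(unclass(x) %in% missing_states(attr(x, "alphabet")),
              nrow = nrow(x), dimnames = dimnames(x))
  m
}

#' Sequences as strings
#' @param x an `msa`.
#' @return named character vector of sequence strings.
#' @export
as_strings <- function(x) {
  stats::setNames(apply(unclass(x), 1L, paste, collapse = ""), rownames(x))
}
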