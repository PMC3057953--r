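#' Read a multiple sequence alignment
#'
#' Reads FASTA, relaxed PHYLIP (sequential or interleaved), or NEXUS
#' (`DATA`/`CHARACTERS` matrix only) into an [msa]. Parsing is delegated to
#' \pkg{ape}; the result is validated against the strict `msa` invariants
#' (equal row lengths, unique taxon names, characters restricted to the
#' alphabet plus missing symbols). Interleaved and sequential layouts of
#' the same matrix yield identical objects. `SETS`/`ASSUMPTIONS` blocks of
#' NEXUS files are ignored (a warning notes their presence).
#'
#' @param path file path.
#' @param format one of `"fasta"`, `"phylip"`, `"nexus"`.
#' @param alphabet `"nt"` or `"aa"`.
#' @return an [msa].
#' @seealso [write_alignment()]
#' @export
read_alignment <- function(path, format = c("fasta", "phylip", "nexus"),
                           alphabet = c("nt", "aa")) {
  format <- match.arg(format)
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (file.info(path)$size == 0) stop("empty alignment file: ", path)
  rows <- switch(format,
    fasta = read_fasta_rows(path),
    phylip = read_phylip_rows(path),
    nexus = read_nexus_rows(path)
  )
  lens <- vapply(rows, length, 1L)
  if (length(unique(lens)) > 1L) {
    bad <- names(rows)[which(lens != lens[1L])[1L]]
    stop("ragged alignment in ", path, "; offending taxon: ", bad,
         call. = FALSE)
  }
  m <- do.call(rbind, rows)
  rownames(m) <- names(rows)
  msa(m, alphabet = alphabet)
}

read_fasta_rows <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no FASTA headers found in ", path)
  nm <- sub("^>\\s*", "", lines[hdr])
  nm <- sub("\\s.*$", "", nm)
  if (anyDuplicated(nm)) {
    stop("duplicate taxon name: ", nm[duplicated(nm)][1L], call. = FALSE)
  }
  ends <- c(hdr[-1L] - 1L, length(lines))
  rows <- lapply(seq_along(hdr), function(i) {
    body <- lines[seq.int(hdr[i] + 1L, ends[i])]
    strsplit(paste(gsub("\\s", "", body), collapse = ""), "", fixed = TRUE)[[1L]]
  })
  names(rows) <- nm
  rows
}

read_phylip_rows <- function(path) {
  # relaxed PHYLIP: whitespace-separated names; sequential or interleaved.
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hd <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  ntax <- suppressWarnings(as.integer(hd[1L]))
  nchar_tot <- suppressWarnings(as.integer(hd[2L]))
  if (is.na(ntax) || is.na(nchar_tot)) {
    stop("malformed PHYLIP header in ", path)
  }
  body <- lines[-1L]
  if (length(body) < ntax) stop("PHYLIP file has fewer rows than taxa")
  first <- lapply(body[seq_len(ntax)], function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1L]]
    list(name = f[1L], seq = paste(f[-1L], collapse = ""))
  })
  nm <- vapply(first, `[[`, "", "name")
  if (anyDuplicated(nm)) {
    stop("duplicate taxon name: ", nm[duplicated(nm)][1L], call. = FALSE)
  }
  seqs <- vapply(first, `[[`, "", "seq")
  extra <- body[-seq_len(ntax)]
  if (length(extra)) {
    # interleaved continuation blocks cycle through taxa in order
    for (i in seq_along(extra)) {
      f <- strsplit(trimws(extra[i]), "\\s+")[[1L]]
      # continuation lines may or may not repeat the taxon name
      if (f[1L] %in% nm && length(f) > 1L) {
        k <- match(f[1L], nm)
        seqs[k] <- paste0(seqs[k], paste(f[-1L], collapse = ""))
      } else {
        k <- ((i - 1L) %% ntax) + 1L
        seqs[k] <- paste0(seqs[k], paste(f, collapse = ""))
      }
    }
  }
  got <- nchar(seqs)
  if (any(got != nchar_tot)) {
    bad <- nm[which(got != nchar_tot)[1L]]
    stop("ragged alignment in ", path, "; offending taxon: ", bad,
         call. = FALSE)
  }
  stats::setNames(strsplit(seqs, "", fixed = TRUE), nm)
}

read_nexus_rows <- function(path) {
  raw <- readLines(path, warn = FALSE)
  if (any(grepl("BEGIN\\s+(SETS|ASSUMPTIONS)", raw, ignore.case = TRUE))) {
    warning("NEXUS SETS/ASSUMPTIONS blocks ignored; only the character matrix is read")
  }
  x <- ape::read.nexus.data(path)
  if (anyDuplicated(names(x))) {
    stop("duplicate taxon name: ", names(x)[duplicated(names(x))][1L],
         call. = FALSE)
  }
  x
}

#' Write a multiple sequence alignment
#'
#' Writes FASTA, sequential relaxed PHYLIP, or a NEXUS `DATA` matrix.
#' `write_alignment()` followed by [read_alignment()] is the identity on
#' every valid [msa].
#'
#' @param x an [msa] (or [supermatrix], whose alignment is written).
#' @param path output file path.
#' @param format one of `"fasta"`, `"phylip"`, `"nexus"`.
#' @export
write_alignment <- function(x, path, format = c("fasta", "phylip", "nexus")) {
  format <- match.arg(format)
  if (is_supermatrix(x)) x <- x$aln
  stopifnot(is_msa(x))
  s <- as_strings(x)
  con <- file(path, "w")
  on.exit(close(con))
  switch(format,
    fasta = writeLines(paste0(">", names(s), "\n", s), con),
    phylip = {
      writeLines(sprintf("%d %d", n_taxa(x), n_sites(x)), con)
      writeLines(sprintf("%s  %s", names(s), s), con)
    },
    nexus = {
      dt <- if (attr(x, "alphabet") == "nt") "DNA" else "PROTEIN"
      writeLines(c(
        "#NEXUS",
        "BEGIN DATA;",
        sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", n_taxa(x), n_sites(x)),
        sprintf("  FORMAT DATATYPE=%s MISSING=? GAP=- INTERLEAVE=NO;", dt),
        "  MATRIX",
        sprintf("    %s  %s", names(s), s),
        "  ;",
        "END;"), con)
    }
  )
  invisible(path)
}
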