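#' Multiple sequence alignments
#'
#' An `msa` object holds aligned sequences over the 21-state alphabet
#' (20 amino acids plus the gap `-`).  The first row is the query, which
#' contains no gaps after A3M normalisation; every row has the query's
#' length `L`.
#'
#' @param ids Character vector of sequence identifiers.
#' @param rows Character vector of aligned sequences (equal lengths).
#' @return An object of class `msa` with elements `ids` and `rows`.
#' @export
new_msa <- function(ids, rows) {
  if (length(rows) < 1L) stop_protgeom("an MSA needs at least one row")
  if (length(ids) != length(rows)) {
    stop_protgeom("ids and rows must have the same length")
  }
  L <- nchar(rows[1])
  if (L < 1L) stop_protgeom("query row is empty")
  if (any(nchar(rows) != L)) {
    bad <- which(nchar(rows) != L)[1]
    stop_protgeom(sprintf(
      "row '%s' has length %d after normalisation, expected %d",
      ids[bad], nchar(rows[bad]), L
    ))
  }
  structure(list(ids = ids, rows = toupper(rows)), class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf(
    "<msa> %d sequences, query length %d (query: %s)\n",
    length(x$rows), nchar(x$rows[1]), x$ids[1]
  ))
  invisible(x)
}

#' Number of sequences and query length of an MSA
#'
#' @param msa An [new_msa()] object.
#' @return `msa_depth()`: the number of rows; `msa_length()`: the query
#'   length L.
#' @export
msa_depth <- function(msa) length(msa$rows)

#' @rdname msa_depth
#' @export
msa_length <- function(msa) nchar(msa$rows[1])

#' Read an alignment in A3M/FASTA layout
#'
#' In the A3M dialect, lowercase letters mark insertions relative to the
#' query; they are deleted from every row so that all returned rows share
#' the query's length.  The first record is taken as the query.
#'
#' @param path Path to an A3M or aligned-FASTA file.
#' @return An [new_msa()] object.
#' @export
read_a3m <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_protgeom("empty alignment file: ", path)
  hdr <- grepl("^>", lines)
  if (!hdr[1]) stop_protgeom("not FASTA/A3M: first line is not a header")
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- vapply(strsplit(ids, "\\s+"), `[`, character(1), 1)
  grp <- cumsum(hdr)
  seqs <- unname(vapply(
    split(lines[!hdr], grp[!hdr]),
    paste0, character(1), collapse = ""
  ))
  if (length(seqs) != length(ids)) {
    stop_protgeom("record without sequence in ", path)
  }
  # A3M normalisation: drop lowercase (insertion) characters.
  norm <- gsub("[a-z]", "", gsub("\\.", "", seqs))
  bad <- grepl("[^A-Z\\-]", norm)
  if (any(bad)) {
    stop_protgeom(sprintf(
      "illegal characters in record '%s'", ids[which(bad)[1]]
    ))
  }
  new_msa(ids, norm)
}

#' Write an MSA as aligned FASTA
#'
#' @param msa An [new_msa()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_msa <- function(msa, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", msa$ids, "\n", msa$rows), con)
  invisible(path)
}

#' Randomly subsample MSA rows
#'
#' The query is always retained.  The subsample size is drawn on a log
#' scale: `k = max(1, round(10^u))` with `u ~ Uniform(0, log10 N_seq)`,
#' then `k - 1` further rows are drawn without replacement.  Used as a
#' per-epoch data augmentation during training.
#'
#' @param msa An [new_msa()] object.
#' @return A subsampled `msa`; the identity when there is a single row.
#' @export
subsample_msa <- function(msa) {
  n <- msa_depth(msa)
  if (n == 1L) return(msa)
  u <- runif(1, 0, log10(n))
  k <- min(n, max(1L, as.integer(round(10^u))))
  keep <- c(1L, 1L + sample.int(n - 1L, k - 1L))
  new_msa(msa$ids[keep], msa$rows[keep])
}
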