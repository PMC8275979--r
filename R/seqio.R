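#' Read a FASTA file of IUPAC nucleotide sequences
#'
#' Reads plain or gzip-compressed FASTA into a [Biostrings::DNAStringSet].
#' Residues are uppercased and U is normalized to T so RNA input is accepted
#' while all downstream logic operates over DNA codes. Any residue outside
#' the 15-letter IUPAC nucleotide alphabet raises an error naming the record
#' and the offending character. Soft-masked (lowercase) residues are
#' uppercased and retained; masking policy lives in the genome partitioner's
#' N-fraction filter, not here.
#'
#' The full FASTA header is kept as the element name; [seqIds()] and
#' [seqDescs()] split it at the first whitespace.
#'
#' @param path path to a FASTA file (".gz" suffix handled transparently).
#' @return a [Biostrings::DNAStringSet]; empty input yields an empty set.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1 demo", "acgu", ">s2", "NNRY"), fa)
#' readFasta(fa)
#' @export
readFasta <- function(path) {
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L)
    return(Biostrings::DNAStringSet())
  s <- chartr("U", "T", toupper(as.character(raw)))
  bad <- gsub(sprintf("[%s]", paste(IUPAC_LETTERS, collapse = "")), "", s)
  offending <- which(nchar(bad) > 0L)
  if (length(offending)) {
    i <- offending[1L]
    stop(sprintf("record '%s' contains non-IUPAC character '%s'",
                 sub("\\s.*$", "", names(raw)[i]), substr(bad[i], 1L, 1L)))
  }
  if (any(nchar(s) == 0L))
    stop("record '", sub("\\s.*$", "", names(raw)[which(nchar(s) == 0L)[1L]]),
         "' is empty")
  out <- Biostrings::DNAStringSet(s)
  names(out) <- names(raw)
  out
}

#' Write sequences to FASTA
#'
#' Round-trip safe with [readFasta()]: identifiers, descriptions and
#' residues are reproduced exactly on re-read.
#'
#' @param x a [Biostrings::DNAStringSet] (or coercible).
#' @param path output file path.
#' @param lineWidth residues per sequence line (default 60).
#' @return invisibly, the number of records written.
#' @export
writeFasta <- function(x, path, lineWidth = 60L) {
  x <- .asSet(x)
  Biostrings::writeXStringSet(x, filepath = path, width = as.integer(lineWidth))
  invisible(length(x))
}

#' Sequence identifiers and descriptions
#'
#' A FASTA header is split at the first whitespace: the leading token is the
#' identifier, the remainder (possibly empty) the description.
#'
#' @param x a named [Biostrings::DNAStringSet].
#' @return character vector, one element per sequence.
#' @export
seqIds <- function(x) {
  nm <- names(x)
  if (is.null(nm)) return(rep("", length(x)))
  sub("\\s.*$", "", nm)
}

#' @rdname seqIds
#' @export
seqDescs <- function(x) {
  nm <- names(x)
  if (is.null(nm)) return(rep("", length(x)))
  ifelse(grepl("\\s", nm), sub("^\\S+\\s+", "", nm), "")
}

# Compose a FASTA header from identifier + description.
.makeHeader <- function(id, desc) {
  ifelse(nchar(desc) > 0L, paste(id, desc), id)
}
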