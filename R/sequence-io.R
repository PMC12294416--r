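#' Read protein sequences from a FASTA file
#'
#' Reads a multi-record FASTA file into an [Biostrings::AAStringSet].
#' Sequences are uppercased and internal whitespace removed; every record is
#' validated against the 20-letter canonical alphabet. Validation is total:
#' the file either yields valid records or a located error — residues are
#' never silently dropped.
#'
#' The set's names carry the full FASTA headers; record identifiers (the
#' first whitespace-delimited token of each header) must be unique and are
#' retrievable with [proteinIds()].
#'
#' @param path Path to a plain-text FASTA file.
#' @param ambiguity How to treat ambiguity codes (B, J, O, U, X, Z):
#'   \code{"reject"} (default) raises a located error; \code{"mask"} replaces
#'   them with the sentinel residue \code{"X"}, which matches no cleavage
#'   pattern and disqualifies any containing fragment from database matching.
#' @return An [Biostrings::AAStringSet], one element per FASTA record in file
#'   order.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">P1 demo", "MKVL", ">P2", "ggfr"), fa)
#' prot <- readProteinFasta(fa)
#' as.character(prot)
#' @seealso [writeProteinFasta()], [proteinIds()]
#' @export
readProteinFasta <- function(path, ambiguity = c("reject", "mask")) {
  ambiguity <- match.arg(ambiguity)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("no FASTA records in ", path)
  seqs <- toupper(gsub("[[:space:]]", "", as.character(raw)))
  headers <- names(raw)
  if (is.null(headers) || any(!nzchar(trimws(headers))))
    stop("malformed FASTA: record without a header in ", path)
  ids <- vapply(strsplit(trimws(headers), "[[:space:]]+"), `[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate record id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  empty <- !nzchar(seqs)
  if (any(empty))
    stop("empty sequence for record(s): ", paste(ids[empty], collapse = ", "))
  seqs <- .resolveAmbiguity(seqs, ids, ambiguity)
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- headers
  out
}

.resolveAmbiguity <- function(seqs, ids, ambiguity) {
  allowed <- canonicalResidues()
  if (ambiguity == "mask") {
    seqs <- chartr(paste(ambiguityResidues(), collapse = ""),
                   strrep(.SENTINEL, length(ambiguityResidues())), seqs)
    allowed <- c(allowed, .SENTINEL)
  }
  badRe <- paste0("[^", paste(allowed, collapse = ""), "]")
  hit <- regexpr(badRe, seqs)
  if (any(hit > 0L)) {
    i <- which(hit > 0L)[1L]
    stop("invalid residue '", substr(seqs[i], hit[i], hit[i]),
         "' in record '", ids[i], "' at position ", hit[i])
  }
  seqs
}

#' @rdname readProteinFasta
#' @param proteins An [Biostrings::AAStringSet] as returned by
#'   [readProteinFasta()].
#' @export
proteinIds <- function(proteins) {
  if (is.null(names(proteins))) stop("proteins must be named")
  vapply(strsplit(trimws(names(proteins)), "[[:space:]]+"),
         `[`, character(1), 1L)
}

#' Write protein sequences to FASTA
#'
#' Writes at 60 columns; \code{readProteinFasta(writeProteinFasta(x))} is the
#' identity on valid sets.
#'
#' @param proteins A named [Biostrings::AAStringSet] (or named character
#'   vector) of protein sequences.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @seealso [readProteinFasta()]
#' @export
writeProteinFasta <- function(proteins, path) {
  if (is.character(proteins)) proteins <- Biostrings::AAStringSet(proteins)
  Biostrings::writeXStringSet(proteins, filepath = path, width = 60L)
  invisible(path)
}
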