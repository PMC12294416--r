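#' Construct an activity database from peptide/activity pairs
#'
#' @param peptide Character vector of peptide sequences (canonical residues,
#'   uppercase; one element per peptide-activity pair).
#' @param activity Character vector of activity labels, parallel to
#'   \code{peptide}. Labels are matched verbatim (trimmed, case-sensitive).
#' @return An [ActivityDB-class]; duplicate (peptide, activity) pairs are
#'   collapsed and the vocabulary is built in first-appearance order.
#' @examples
#' db <- activityDB(c("VW", "VW", "IPP"),
#'                  c("ACE inhibitor", "DPP IV inhibitor", "ACE inhibitor"))
#' dbEntries(db)
#' @seealso [loadActivityDB()], [mergeDBs()]
#' @export
activityDB <- function(peptide = character(0), activity = character(0)) {
  if (length(peptide) != length(activity))
    stop("peptide and activity must have equal length")
  peptide <- toupper(trimws(peptide))
  activity <- trimws(activity)
  bad <- which(!vapply(peptide, .isCanonicalSeq, logical(1)))
  if (length(bad))
    stop("invalid residue in peptide '", peptide[bad[1L]],
         "' (row ", bad[1L], ")")
  if (any(!nzchar(activity)))
    stop("empty activity label (row ", which(!nzchar(activity))[1L], ")")
  vocab <- unique(activity)
  entries <- lapply(split(activity, factor(peptide, levels = unique(peptide))),
                    unique)
  new("ActivityDB", entries = entries, vocabulary = vocab)
}

#' Load a peptide-activity database from delimited text
#'
#' Expects a TSV with a header row and columns \code{peptide},
#' \code{activity} and optionally \code{source_id}; one row per (peptide,
#' activity) pair. Rows are aggregated by peptide, duplicate pairs
#' collapsed, and the activity vocabulary recorded in first-appearance
#' order.
#'
#' @param path TSV file path.
#' @return An [ActivityDB-class].
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("peptide\tactivity", "VW\tACE inhibitor",
#'              "VW\tDPP IV inhibitor"), f)
#' loadActivityDB(f)
#' @seealso [writeActivityDB()], [activityDB()]
#' @export
loadActivityDB <- function(path) {
  if (!file.exists(path)) stop("activity database not found: ", path)
  ## na.strings emptied: "NA" is a valid Asn-Ala dipeptide, not a missing value
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = character(0))
  need <- c("peptide", "activity")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("activity database ", path, " is missing required column(s): ",
         paste(miss, collapse = ", "))
  activityDB(tab$peptide, tab$activity)
}

#' @rdname loadActivityDB
#' @param db An [ActivityDB-class] to write.
#' @export
writeActivityDB <- function(db, path) {
  stopifnot(is(db, "ActivityDB"))
  ent <- db@entries
  tab <- data.frame(
    peptide = rep(names(ent), lengths(ent)),
    activity = unlist(ent, use.names = FALSE),
    source_id = "local",
    stringsAsFactors = FALSE)
  .writeTSV(tab, path)
  invisible(path)
}

#' Merge two activity databases
#'
#' Entry-wise union of activity sets; commutative and idempotent up to
#' vocabulary order (first-appearance order of \code{a} then \code{b}).
#'
#' @param a,b [ActivityDB-class] objects.
#' @return The merged [ActivityDB-class].
#' @export
mergeDBs <- function(a, b) {
  stopifnot(is(a, "ActivityDB"), is(b, "ActivityDB"))
  peps <- unique(c(names(a@entries), names(b@entries)))
  entries <- lapply(peps, function(p) {
    unique(c(a@entries[[p]], b@entries[[p]]))
  })
  names(entries) <- peps
  vocab <- unique(c(a@vocabulary, b@vocabulary))
  new("ActivityDB", entries = entries, vocabulary = vocab)
}

## shared TSV writer: header row, tab-separated, UTF-8, LF endings
.writeTSV <- function(tab, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(tab), collapse = "\t"), con, sep = "\n")
  if (nrow(tab)) {
    rows <- do.call(paste, c(lapply(tab, as.character), sep = "\t"))
    writeLines(rows, con, sep = "\n")
  }
  invisible(path)
}
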