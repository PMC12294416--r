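#' Load an external peptide score table
#'
#' Reads a TSV with columns \code{peptide} and \code{score}: the interface
#' to an external bioactivity ranker whose per-peptide probability scores in
#' [0, 1] are consumed, never computed, by this package.
#'
#' @param path TSV file path.
#' @return data.frame with columns \code{peptide} (validated, uppercase) and
#'   \code{score}; duplicate peptides are rejected.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("peptide\tscore", "AKW\t0.73", "GG\t0.12"), f)
#' loadScores(f)
#' @seealso [classifyBioactive()]
#' @export
loadScores <- function(path) {
  if (!file.exists(path)) stop("score table not found: ", path)
  ## na.strings emptied: "NA" is a valid Asn-Ala dipeptide, not a missing value
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = character(0))
  miss <- setdiff(c("peptide", "score"), names(tab))
  if (length(miss))
    stop("score table ", path, " is missing required column(s): ",
         paste(miss, collapse = ", "))
  tab$peptide <- toupper(trimws(as.character(tab$peptide)))
  tab$score <- suppressWarnings(as.numeric(tab$score))
  bad <- which(!vapply(tab$peptide, .isCanonicalSeq, logical(1)))
  if (length(bad))
    stop("invalid peptide '", tab$peptide[bad[1L]], "' at row ", bad[1L])
  dup <- which(duplicated(tab$peptide))
  if (length(dup))
    stop("duplicate peptide '", tab$peptide[dup[1L]], "' at row ", dup[1L])
  oob <- which(is.na(tab$score) | tab$score < 0 | tab$score > 1)
  if (length(oob))
    stop("score out of [0, 1] for peptide '", tab$peptide[oob[1L]],
         "' at row ", oob[1L])
  tab[, c("peptide", "score")]
}

#' Classify scored peptides at a bioactivity threshold
#'
#' Peptides scoring at or above the threshold are classified bioactive (the
#' boundary is inclusive); the two sets partition the input.
#'
#' @param scores data.frame with columns \code{peptide}, \code{score} (see
#'   [loadScores()]).
#' @param threshold Classification threshold in [0, 1]; default 0.50.
#' @return list with data.frames \code{bioactive} (score >= threshold) and
#'   \code{inactive}, preserving input order.
#' @examples
#' sc <- data.frame(peptide = c("AK", "GG"), score = c(0.50, 0.49))
#' classifyBioactive(sc)$bioactive
#' @export
classifyBioactive <- function(scores, threshold = 0.50) {
  stopifnot(is.data.frame(scores),
            all(c("peptide", "score") %in% names(scores)))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 1)
    stop("threshold must be a single number in [0, 1]")
  if (any(is.na(scores$score) | scores$score < 0 | scores$score > 1))
    stop("scores must lie in [0, 1]")
  hit <- scores$score >= threshold
  list(bioactive = scores[hit, , drop = FALSE],
       inactive = scores[!hit, , drop = FALSE])
}

#' Per-protein, per-enzyme counts of threshold-bioactive peptides
#'
#' Joins a score-threshold partition back to digest provenance: for every
#' protein x enzyme, the number of its distinct released peptides classified
#' bioactive. Unique sequences are scored once and may be credited to
#' several digests. Every scored peptide must be traceable to at least one
#' digest.
#'
#' @param partition Output of [classifyBioactive()].
#' @param results List of [DigestResult-class] objects (the provenance).
#' @return data.frame with columns \code{protein_id}, \code{enzyme},
#'   \code{bioactive_peptides}, plus an \code{"in total"} row per enzyme.
#' @export
perProteinBioactiveCounts <- function(partition, results) {
  stopifnot(is.list(partition),
            all(c("bioactive", "inactive") %in% names(partition)))
  scored <- c(partition$bioactive$peptide, partition$inactive$peptide)
  released <- unique(unlist(lapply(results, function(r) r@peptides),
                            use.names = FALSE))
  orphan <- setdiff(scored, released)
  if (length(orphan))
    stop("scored peptide(s) not traceable to any digest: ",
         paste(utils::head(orphan, 3), collapse = ", "))
  hitSet <- partition$bioactive$peptide
  out <- data.frame(
    protein_id = vapply(results, function(r) r@proteinId, character(1)),
    enzyme = vapply(results, function(r) r@protease, character(1)),
    bioactive_peptides = vapply(results, function(r)
      sum(r@peptides %in% hitSet), integer(1)),
    stringsAsFactors = FALSE)
  out <- out[order(out$protein_id, out$enzyme), , drop = FALSE]
  totals <- stats::aggregate(bioactive_peptides ~ enzyme, data = out, FUN = sum)
  totals <- data.frame(protein_id = "in total", enzyme = totals$enzyme,
                       bioactive_peptides = totals$bioactive_peptides,
                       stringsAsFactors = FALSE)
  out <- rbind(out, totals[order(totals$enzyme), , drop = FALSE])
  rownames(out) <- NULL
  out
}
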