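#' Match released peptides against an activity database
#'
#' The "search for active fragments" stage: exactly those distinct released
#' peptides whose full sequence is a database key are reported. A database
#' peptide buried inside a longer released fragment does not count: only
#' full-fragment exact matches are bioactive matches.
#'
#' @param result A [DigestResult-class].
#' @param db An [ActivityDB-class].
#' @return A data.frame with one row per matched peptide, in order of first
#'   occurrence along the protein: columns \code{protein_id}, \code{enzyme},
#'   \code{peptide}, \code{n_occurrences} (positional fragments carrying that
#'   sequence) and the list-column \code{activities}.
#' @examples
#' sp <- proteaseSpec("demo", "3.4.22.2", list("P1:[K]"))
#' db <- activityDB("GG", "ACE inhibitor")
#' matchFragments(digestProtein("AKGGKAV", sp, id = "P"), db)
#' @seealso [buildSummary()], [buildActivityProfile()]
#' @export
matchFragments <- function(result, db) {
  stopifnot(is(result, "DigestResult"), is(db, "ActivityDB"))
  hits <- result@peptides[result@peptides %in% names(db@entries)]
  occ <- table(result@fragments$sequence)
  out <- data.frame(
    protein_id = rep(result@proteinId, length(hits)),
    enzyme = rep(result@protease, length(hits)),
    peptide = hits,
    n_occurrences = as.integer(occ[hits]),
    stringsAsFactors = FALSE)
  out$activities <- unname(db@entries[hits])
  rownames(out) <- NULL
  out
}

#' Collect matches across digests
#'
#' @param results List of [DigestResult-class] objects.
#' @param db An [ActivityDB-class].
#' @return Row-bound [matchFragments()] output over all digests.
#' @rdname matchFragments
#' @export
matchAll <- function(results, db) {
  parts <- lapply(results, matchFragments, db = db)
  out <- do.call(rbind, parts)
  if (is.null(out))
    out <- data.frame(protein_id = character(0), enzyme = character(0),
                      peptide = character(0), n_occurrences = integer(0),
                      activities = I(list()), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

## one row per (protein, enzyme, peptide, activity)
.matchesLong <- function(matches) {
  n <- lengths(matches$activities)
  data.frame(
    protein_id = rep(matches$protein_id, n),
    enzyme = rep(matches$enzyme, n),
    peptide = rep(matches$peptide, n),
    activity = as.character(unlist(matches$activities, use.names = FALSE)),
    stringsAsFactors = FALSE)
}

#' Per-protein, per-enzyme peptide count summary
#'
#' Builds the digestion summary: for every protein x enzyme the number of
#' released peptides and the number of those with a database activity, plus
#' a grand-total row per enzyme (\code{protein_id == "in total"}). With
#' \code{counting = "distinct"} (default) both columns count distinct
#' peptide sequences; \code{"occurrence"} counts positional fragments.
#'
#' @param results List of [DigestResult-class] objects covering a complete
#'   protein x enzyme grid (each cell exactly once).
#' @param matches Combined match table from [matchAll()].
#' @param counting \code{"distinct"} or \code{"occurrence"}.
#' @return data.frame with columns \code{protein_id}, \code{enzyme},
#'   \code{total_peptides}, \code{bioactive_peptides}; proteins sorted
#'   alphabetically, totals rows last.
#' @seealso [matchAll()], [buildActivityProfile()]
#' @export
buildSummary <- function(results, matches, counting = c("distinct", "occurrence")) {
  counting <- match.arg(counting)
  cells <- data.frame(
    protein_id = vapply(results, function(r) r@proteinId, character(1)),
    enzyme = vapply(results, function(r) r@protease, character(1)),
    stringsAsFactors = FALSE)
  key <- paste(cells$protein_id, cells$enzyme, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate digest for cell(s): ",
         paste(unique(sub("\r", " x ", key[duplicated(key)])), collapse = ", "))
  full <- expand.grid(protein_id = unique(cells$protein_id),
                      enzyme = unique(cells$enzyme),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(paste(full$protein_id, full$enzyme, sep = "\r"), key)
  if (length(missing))
    stop("missing digest for cell(s): ",
         paste(sub("\r", " x ", missing), collapse = ", "))
  tot <- vapply(results, function(r) {
    if (counting == "distinct") length(r@peptides)
    else sum(nchar(r@fragments$sequence) >= r@minPeptideLength)
  }, numeric(1))
  mkey <- paste(matches$protein_id, matches$enzyme, sep = "\r")
  bio <- vapply(seq_len(nrow(cells)), function(i) {
    sel <- mkey == key[i]
    if (counting == "distinct") sum(sel) else sum(matches$n_occurrences[sel])
  }, numeric(1))
  out <- data.frame(protein_id = cells$protein_id, enzyme = cells$enzyme,
                    total_peptides = as.integer(tot),
                    bioactive_peptides = as.integer(bio),
                    stringsAsFactors = FALSE)
  out <- out[order(out$protein_id, out$enzyme), , drop = FALSE]
  totals <- stats::aggregate(cbind(total_peptides, bioactive_peptides) ~ enzyme,
                             data = out, FUN = sum)
  totals <- data.frame(protein_id = "in total", enzyme = totals$enzyme,
                       total_peptides = totals$total_peptides,
                       bioactive_peptides = totals$bioactive_peptides,
                       stringsAsFactors = FALSE)
  totals <- totals[order(totals$enzyme), , drop = FALSE]
  out <- rbind(out, totals)
  rownames(out) <- NULL
  out
}

#' Per-activity peptide counts for one protease
#'
#' Counts distinct (protein, peptide) pairs carrying each activity label; a
#' multifunctional peptide contributes once per activity per protein, so the
#' column can sum above the number of distinct bioactive peptides. Every
#' vocabulary label is reported, zeros included.
#'
#' @param matches Combined match table from [matchAll()].
#' @param vocabulary Full activity vocabulary (see [activityVocabulary()]).
#' @param protease Protease name to profile; \code{NULL} profiles all
#'   matches together.
#' @return data.frame with columns \code{activity} (alphabetical) and
#'   \code{count}; attributes \code{protease} and \code{bioactive_total}
#'   (distinct (protein, peptide) pairs with >= 1 activity).
#' @export
buildActivityProfile <- function(matches, vocabulary, protease = NULL) {
  if (!is.null(protease)) matches <- matches[matches$enzyme == protease, , drop = FALSE]
  long <- .matchesLong(matches)
  unknown <- setdiff(unique(long$activity), vocabulary)
  if (length(unknown))
    stop("activity label(s) outside the vocabulary: ",
         paste(unknown, collapse = ", "))
  long <- unique(long[, c("protein_id", "peptide", "activity")])
  counts <- table(factor(long$activity, levels = sort(vocabulary)))
  out <- data.frame(activity = names(counts), count = as.integer(counts),
                    stringsAsFactors = FALSE)
  attr(out, "protease") <- if (is.null(protease)) NA_character_ else protease
  attr(out, "bioactive_total") <-
    nrow(unique(matches[, c("protein_id", "peptide")]))
  out
}

#' Protein-by-enzyme vs activity count matrix
#'
#' The heatmap stage: a matrix with one row per protein x enzyme and one
#' column per activity label (full vocabulary, alphabetical), each cell the
#' number of distinct matched peptides of that protein/enzyme carrying that
#' activity; plus the same counts in long format.
#'
#' @param matches Combined match table from [matchAll()].
#' @param vocabulary Full activity vocabulary.
#' @param grid data.frame with columns \code{protein_id}, \code{enzyme}
#'   giving the full set of rows (so all-zero rows are kept); defaults to
#'   the cells present in \code{matches}.
#' @return list with \code{matrix} (rownames \code{"protein|enzyme"}) and
#'   \code{long} (columns protein_id, enzyme, activity, count).
#' @seealso [plotActivityHeatmap()]
#' @export
buildHeatmapMatrix <- function(matches, vocabulary, grid = NULL) {
  if (is.null(grid))
    grid <- unique(matches[, c("protein_id", "enzyme")])
  grid <- unique(grid[, c("protein_id", "enzyme")])
  grid <- grid[order(grid$protein_id, grid$enzyme), , drop = FALSE]
  long0 <- .matchesLong(matches)
  unknown <- setdiff(unique(long0$activity), vocabulary)
  if (length(unknown))
    stop("activity label(s) outside the vocabulary: ",
         paste(unknown, collapse = ", "))
  vocab <- sort(vocabulary)
  rowKey <- paste(grid$protein_id, grid$enzyme, sep = "|")
  mat <- matrix(0L, nrow = nrow(grid), ncol = length(vocab),
                dimnames = list(rowKey, vocab))
  if (nrow(long0)) {
    long0 <- unique(long0)
    k <- paste(long0$protein_id, long0$enzyme, sep = "|")
    bad <- setdiff(unique(k), rowKey)
    if (length(bad))
      stop("matches for cell(s) absent from the grid: ",
           paste(bad, collapse = ", "))
    tab <- table(factor(k, levels = rowKey),
                 factor(long0$activity, levels = vocab))
    mat[] <- as.integer(tab)
  }
  long <- data.frame(
    protein_id = rep(grid$protein_id, each = length(vocab)),
    enzyme = rep(grid$enzyme, each = length(vocab)),
    activity = rep(vocab, times = nrow(grid)),
    count = as.integer(t(mat)),
    stringsAsFactors = FALSE)
  list(matrix = mat, long = long)
}

#' Render the activity heatmap
#'
#' Draws the protein-by-enzyme vs activity count matrix with
#' \pkg{pheatmap} (no clustering: rows and columns keep their deterministic
#' order).
#'
#' @param mat Matrix from [buildHeatmapMatrix()]\code{$matrix}.
#' @param path Optional PNG path; \code{NULL} draws to the active device.
#' @return Invisibly, \code{path}.
#' @export
plotActivityHeatmap <- function(mat, path = NULL) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stop("plotActivityHeatmap requires the 'pheatmap' package")
  if (!is.null(path)) {
    grDevices::png(path, width = 1400, height = 900, res = 120)
    on.exit(grDevices::dev.off())
  }
  pheatmap::pheatmap(mat, cluster_rows = FALSE, cluster_cols = FALSE)
  invisible(path)
}
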