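#' Find all cleavage sites of a protease on a protein
#'
#' Under the complete-hydrolysis assumption every bond matching the enzyme's
#' recognition patterns is cleaved; this returns exactly those bonds, sorted
#' ascending. Bond \code{i} separates residues \code{i} and \code{i+1}.
#'
#' @param sequence A residue string, or a length-1 [Biostrings::AAStringSet].
#' @param spec A [ProteaseSpec-class].
#' @return Sorted integer vector of cut bond indices (possibly empty).
#' @examples
#' sp <- proteaseSpec("demo", "3.4.22.2", list("P1:[KR]"))
#' findSites("AKRG", sp)
#' @seealso [digestProtein()], [bondMatches()]
#' @export
findSites <- function(sequence, spec) {
  stopifnot(is(spec, "ProteaseSpec"))
  sequence <- .asSingleSequence(sequence)
  residues <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  which(.matchBonds(spec, residues))
}

.asSingleSequence <- function(sequence) {
  if (is(sequence, "AAStringSet") || is(sequence, "AAString"))
    sequence <- as.character(sequence)
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("sequence must be a single nonempty residue string")
  unname(sequence)
}

#' Exhaustive in silico digestion of one protein by one protease
#'
#' Simulates ideal and complete hydrolysis: all matching bonds are cut
#' simultaneously, so the positional fragments are the maximal uncut
#' substrings between consecutive sites (and the termini). The distinct
#' fragment sequences of length >= \code{minPeptideLength} form the digest's
#' peptide set; its size is the "total peptides" count.
#'
#' @param sequence A residue string or length-1 [Biostrings::AAStringSet].
#' @param spec A [ProteaseSpec-class].
#' @param id Protein identifier recorded in the result (defaults to the
#'   sequence's name, or \code{"protein"}).
#' @param minPeptideLength Minimum fragment length counted as a peptide
#'   (default 2: single residues are not peptides).
#' @return A [DigestResult-class].
#' @examples
#' sp <- proteaseSpec("demo", "3.4.22.2", list("P1:[KR]"))
#' d <- digestProtein("AKRG", sp, id = "P1")
#' fragments(d)
#' peptides(d)
#' @seealso [findSites()], [matchFragments()], [redigestIsStable()]
#' @export
digestProtein <- function(sequence, spec, id = NULL, minPeptideLength = 2L) {
  stopifnot(is(spec, "ProteaseSpec"))
  if (is.null(id)) {
    nm <- names(sequence)
    id <- if (!is.null(nm) && nzchar(nm[1L])) {
      strsplit(trimws(nm[1L]), "[[:space:]]+")[[1L]][1L]
    } else "protein"
  }
  sequence <- .asSingleSequence(sequence)
  minPeptideLength <- as.integer(minPeptideLength)
  if (is.na(minPeptideLength) || minPeptideLength < 1L)
    stop("minPeptideLength must be >= 1")
  sites <- findSites(sequence, spec)
  L <- nchar(sequence)
  starts <- c(0L, sites)            # 0-based inclusive
  ends <- c(sites, L)               # exclusive
  frag <- data.frame(start = starts, end = ends,
                     sequence = substring(sequence, starts + 1L, ends),
                     stringsAsFactors = FALSE)
  keep <- !duplicated(frag$sequence) & nchar(frag$sequence) >= minPeptideLength
  new("DigestResult", proteinId = id, protease = spec@name,
      sequence = sequence, sites = as.integer(sites), fragments = frag,
      peptides = frag$sequence[keep], minPeptideLength = minPeptideLength)
}

#' Verify that complete hydrolysis is a fixed point
#'
#' Re-digests every positional fragment of a digest with the same protease;
#' returns TRUE iff each fragment comes back uncut. Any correctly produced
#' digest satisfies this (no fragment contains an internal cleavage site);
#' a FALSE return signals a corrupted result.
#'
#' @param result A [DigestResult-class].
#' @param spec The [ProteaseSpec-class] that produced it.
#' @return Logical.
#' @export
redigestIsStable <- function(result, spec) {
  stopifnot(is(result, "DigestResult"), is(spec, "ProteaseSpec"))
  for (fr in result@fragments$sequence) {
    if (length(findSites(fr, spec)) > 0L) return(FALSE)
  }
  TRUE
}

#' Digest a protein set with several proteases
#'
#' Convenience wrapper running [digestProtein()] over every protein x enzyme
#' combination.
#'
#' @param proteins Named [Biostrings::AAStringSet] or named character vector.
#' @param specs List of [ProteaseSpec-class] objects.
#' @param minPeptideLength Passed to [digestProtein()].
#' @return A list of [DigestResult-class], one per protein x enzyme, ordered
#'   enzyme-major.
#' @export
digestSet <- function(proteins, specs, minPeptideLength = 2L) {
  if (is(proteins, "AAStringSet")) {
    ids <- proteinIds(proteins)
    seqs <- as.character(proteins)
  } else {
    ids <- names(proteins)
    seqs <- proteins
  }
  if (is.null(ids) || any(!nzchar(ids))) stop("proteins must be named")
  out <- list()
  for (spec in specs) {
    for (i in seq_along(seqs)) {
      out[[length(out) + 1L]] <-
        digestProtein(seqs[[i]], spec, id = ids[[i]],
                      minPeptideLength = minPeptideLength)
    }
  }
  out
}
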