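#' @import methods
NULL

#' CleavagePattern: one recognition motif of a protease
#'
#' A cleavage pattern constrains residues at relative bond positions in
#' Schechter-Berger notation (P4, P3, P2, P1, P1', P2'). A peptide bond is
#' matched when every constrained position holds a residue from the stated
#' set; P1 must always be constrained, and cleavage is C-terminal to P1.
#'
#' @slot constraints Named list mapping position labels to nonempty character
#'   vectors of canonical residue letters.
#' @seealso [compilePattern()], [bondMatches()]
#' @export
setClass("CleavagePattern", representation(constraints = "list"))

setValidity("CleavagePattern", function(object) {
  cons <- object@constraints
  if (length(cons) == 0L || is.null(names(cons)))
    return("constraints must be a nonempty named list")
  bad <- setdiff(names(cons), .positionLabels())
  if (length(bad))
    return(paste0("unknown position label(s): ", paste(bad, collapse = ", ")))
  if (!"P1" %in% names(cons))
    return("P1 must be constrained (cleavage is defined C-terminal to P1)")
  for (pos in names(cons)) {
    set <- cons[[pos]]
    if (!is.character(set) || length(set) == 0L)
      return(paste0("empty residue class at ", pos))
    if (!all(set %in% canonicalResidues()))
      return(paste0("non-canonical residue(s) at ", pos, ": ",
                    paste(setdiff(set, canonicalResidues()), collapse = "")))
    if (anyDuplicated(set))
      return(paste0("duplicated residues at ", pos))
  }
  TRUE
})

#' ProteaseSpec: a named enzyme as a union of cleavage patterns
#'
#' A bond is cut if any one of the enzyme's patterns matches it
#' (pattern-union semantics).
#'
#' @slot name Enzyme name (nonempty).
#' @slot ec EC number in dotted-quad format, e.g. \code{"3.4.22.2"}.
#' @slot patterns Nonempty list of [CleavagePattern-class] objects.
#' @seealso [builtinProtease()], [findSites()]
#' @export
setClass("ProteaseSpec",
  representation(name = "character", ec = "character", patterns = "list"))

setValidity("ProteaseSpec", function(object) {
  if (length(object@name) != 1L || !nzchar(object@name))
    return("name must be a nonempty string")
  if (length(object@ec) != 1L ||
      !grepl("^[0-9]+\\.[0-9]+\\.[0-9]+\\.[0-9]+$", object@ec))
    return("ec must match the EC dotted-quad format, e.g. 3.4.22.2")
  if (length(object@patterns) == 0L)
    return("patterns must be nonempty")
  ok <- vapply(object@patterns, function(p) is(p, "CleavagePattern"), logical(1))
  if (!all(ok))
    return("patterns must all be CleavagePattern objects")
  TRUE
})

#' DigestResult: fragments released from one protein by one protease
#'
#' Produced by [digestProtein()] under complete hydrolysis: every matching
#' bond is cut, so no fragment contains an internal cleavage site.
#'
#' @slot proteinId Protein identifier.
#' @slot protease Protease name.
#' @slot sequence The parent residue string.
#' @slot sites Sorted integer vector of cut bond indices (bond i separates
#'   residues i and i+1, 1-based).
#' @slot fragments data.frame with columns \code{start} (0-based inclusive),
#'   \code{end} (exclusive), \code{sequence}, in N-to-C order.
#' @slot peptides Character vector of distinct fragment sequences with length
#'   >= \code{minPeptideLength}, ordered by first occurrence.
#' @slot minPeptideLength Minimum length for a fragment to count as a peptide.
#' @seealso [digestProtein()], [peptides()], [totalPeptides()]
#' @export
setClass("DigestResult",
  representation(proteinId = "character", protease = "character",
                 sequence = "character", sites = "integer",
                 fragments = "data.frame", peptides = "character",
                 minPeptideLength = "integer"))

setValidity("DigestResult", function(object) {
  fr <- object@fragments
  if (!all(c("start", "end", "sequence") %in% names(fr)))
    return("fragments must have columns start, end, sequence")
  if (nrow(fr) != length(object@sites) + 1L)
    return("fragment count must equal site count + 1")
  if (is.unsorted(object@sites, strictly = TRUE) && length(object@sites) > 1L)
    return("sites must be strictly increasing")
  if (paste(fr$sequence, collapse = "") != object@sequence)
    return("fragments must concatenate to the parent sequence")
  slice <- substring(object@sequence, fr$start + 1L, fr$end)
  if (!all(slice == fr$sequence))
    return("fragment sequences must equal parent slices [start, end)")
  TRUE
})

#' ActivityDB: peptide to activity-label catalogue
#'
#' The searchable stand-in for a bioactive-peptide database export: a map
#' from peptide sequence to its set of activity labels, plus the label
#' vocabulary in first-appearance order.
#'
#' @slot entries Named list: peptide sequence -> character vector of activity
#'   labels (nonempty, unique).
#' @slot vocabulary Character vector of all labels present, first-appearance
#'   order.
#' @seealso [loadActivityDB()], [matchFragments()]
#' @export
setClass("ActivityDB",
  representation(entries = "list", vocabulary = "character"))

setValidity("ActivityDB", function(object) {
  ent <- object@entries
  if (length(ent)) {
    if (is.null(names(ent)) || any(!nzchar(names(ent))))
      return("entries must be named by peptide sequence")
    if (anyDuplicated(names(ent)))
      return("duplicate peptide entries")
    badPep <- !vapply(names(ent), .isCanonicalSeq, logical(1))
    if (any(badPep))
      return(paste0("non-canonical peptide(s): ",
                    paste(utils::head(names(ent)[badPep], 3), collapse = ", ")))
    nAct <- vapply(ent, length, integer(1))
    if (any(nAct == 0L)) return("empty activity set")
    if (any(vapply(ent, function(a) any(!nzchar(a)), logical(1))))
      return("empty activity label")
  }
  if (!setequal(object@vocabulary, unique(unlist(ent, use.names = FALSE))))
    return("vocabulary must equal the union of entry labels")
  TRUE
})

#' SyntheticPanel: generated proteins, database and ground truth
#'
#' A fully synthetic test panel: proteins with bioactive motifs planted in
#' cleavable contexts, an activity database containing the planted motifs
#' plus decoys, a score table, and per protein-by-enzyme truth (expected
#' sites, fragments, peptides and matches) computed analytically at
#' generation time, independently of the digestion engine.
#'
#' @slot proteins An [Biostrings::AAStringSet] of generated proteins.
#' @slot db The [ActivityDB-class] with planted motifs and decoys.
#' @slot enzymes Named list of [ProteaseSpec-class] objects.
#' @slot truth Nested list: \code{truth[[enzyme]][[protein]]} holds
#'   \code{sites}, \code{fragments}, \code{peptides}, \code{matched} (named
#'   list peptide -> activities) and \code{planted} (per-planting release
#'   records).
#' @slot scores data.frame with columns \code{peptide}, \code{score}; the
#'   number of scores >= 0.5 is fixed by construction and stored in
#'   \code{params$nAboveThreshold}.
#' @slot seed Integer seed that reproduces the panel byte-identically.
#' @slot params Generation parameters.
#' @seealso [genPanel()], [writePanel()]
#' @export
setClass("SyntheticPanel",
  representation(proteins = "AAStringSet", db = "ActivityDB",
                 enzymes = "list", truth = "list", scores = "data.frame",
                 seed = "integer", params = "list"))

.isCanonicalSeq <- function(x) {
  nzchar(x) && !grepl(paste0("[^", paste(canonicalResidues(), collapse = ""), "]"), x)
}
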