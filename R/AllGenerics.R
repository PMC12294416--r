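#' Accessors for pipeline objects
#'
#' Small accessor generics, in preference to direct slot access.
#'
#' @param x A [ProteaseSpec-class], [DigestResult-class], [ActivityDB-class]
#'   or [SyntheticPanel-class] object, as appropriate.
#' @return The requested component; see the individual methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("proteaseName", function(x) standardGeneric("proteaseName"))
#' @rdname accessors
#' @export
setGeneric("ecNumber", function(x) standardGeneric("ecNumber"))
#' @rdname accessors
#' @export
setGeneric("cleavagePatterns", function(x) standardGeneric("cleavagePatterns"))
#' @rdname accessors
#' @export
setGeneric("cleavageSites", function(x) standardGeneric("cleavageSites"))
#' @rdname accessors
#' @export
setGeneric("fragments", function(x) standardGeneric("fragments"))
#' @rdname accessors
#' @export
setGeneric("peptides", function(x) standardGeneric("peptides"))
#' @rdname accessors
#' @export
setGeneric("totalPeptides", function(x) standardGeneric("totalPeptides"))
#' @rdname accessors
#' @export
setGeneric("dbEntries", function(x) standardGeneric("dbEntries"))
#' @rdname accessors
#' @export
setGeneric("activityVocabulary", function(x) standardGeneric("activityVocabulary"))
#' @rdname accessors
#' @export
setGeneric("panelProteins", function(x) standardGeneric("panelProteins"))
#' @rdname accessors
#' @export
setGeneric("panelDB", function(x) standardGeneric("panelDB"))
#' @rdname accessors
#' @export
setGeneric("panelEnzymes", function(x) standardGeneric("panelEnzymes"))
#' @rdname accessors
#' @export
setGeneric("panelTruth", function(x) standardGeneric("panelTruth"))
#' @rdname accessors
#' @export
setGeneric("panelScores", function(x) standardGeneric("panelScores"))

#' @rdname accessors
#' @export
setMethod("proteaseName", "ProteaseSpec", function(x) x@name)
#' @rdname accessors
#' @export
setMethod("ecNumber", "ProteaseSpec", function(x) x@ec)
#' @rdname accessors
#' @export
setMethod("cleavagePatterns", "ProteaseSpec", function(x) x@patterns)

#' @rdname accessors
#' @export
setMethod("proteaseName", "DigestResult", function(x) x@protease)
#' @rdname accessors
#' @export
setMethod("cleavageSites", "DigestResult", function(x) x@sites)
#' @rdname accessors
#' @export
setMethod("fragments", "DigestResult", function(x) x@fragments)
#' @rdname accessors
#' @export
setMethod("peptides", "DigestResult", function(x) x@peptides)
#' @rdname accessors
#' @export
setMethod("totalPeptides", "DigestResult", function(x) length(x@peptides))

#' @rdname accessors
#' @export
setMethod("dbEntries", "ActivityDB", function(x) x@entries)
#' @rdname accessors
#' @export
setMethod("activityVocabulary", "ActivityDB", function(x) x@vocabulary)
#' @rdname accessors
#' @export
setMethod("length", "ActivityDB", function(x) length(x@entries))

#' @rdname accessors
#' @export
setMethod("panelProteins", "SyntheticPanel", function(x) x@proteins)
#' @rdname accessors
#' @export
setMethod("panelDB", "SyntheticPanel", function(x) x@db)
#' @rdname accessors
#' @export
setMethod("panelEnzymes", "SyntheticPanel", function(x) x@enzymes)
#' @rdname accessors
#' @export
setMethod("panelTruth", "SyntheticPanel", function(x) x@truth)
#' @rdname accessors
#' @export
setMethod("panelScores", "SyntheticPanel", function(x) x@scores)

setMethod("show", "CleavagePattern", function(object) {
  cat("CleavagePattern:", patternToText(object), "\n")
})

setMethod("show", "ProteaseSpec", function(object) {
  cat("ProteaseSpec '", object@name, "' (EC ", object@ec, ")\n", sep = "")
  for (p in object@patterns) cat("  ", patternToText(p), "\n", sep = "")
})

setMethod("show", "DigestResult", function(object) {
  cat("DigestResult: protein '", object@proteinId, "' x protease '",
      object@protease, "'\n", sep = "")
  cat("  parent length: ", nchar(object@sequence),
      "; cleavage sites: ", length(object@sites),
      "; fragments: ", nrow(object@fragments),
      "; distinct peptides (len >= ", object@minPeptideLength, "): ",
      length(object@peptides), "\n", sep = "")
})

setMethod("show", "ActivityDB", function(object) {
  cat("ActivityDB: ", length(object@entries), " peptides, ",
      length(object@vocabulary), " activity labels\n", sep = "")
  if (length(object@vocabulary))
    cat("  labels: ", paste(utils::head(object@vocabulary, 5), collapse = ", "),
        if (length(object@vocabulary) > 5) ", ..." else "", "\n", sep = "")
})

setMethod("show", "SyntheticPanel", function(object) {
  cat("SyntheticPanel: ", length(object@proteins), " proteins x ",
      length(object@enzymes), " enzymes (seed ", object@seed, ")\n", sep = "")
  cat("  database: ", length(object@db@entries), " peptides (",
      object@params$nDecoys, " decoys), ",
      length(object@db@vocabulary), " activity labels\n", sep = "")
  cat("  scores: ", nrow(object@scores), " peptides, ",
      object@params$nAboveThreshold, " at or above 0.50\n", sep = "")
})
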