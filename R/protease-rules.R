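#' Compile a cleavage pattern from the rule mini-language
#'
#' One pattern is written as whitespace-separated \code{position:class}
#' pairs, e.g. \code{"P2:[AVLIFWY] P1:[KR]"}. Positions follow
#' Schechter-Berger notation (\code{P4}, \code{P3}, \code{P2}, \code{P1},
#' \code{P1'}, \code{P2'}); the residue class is a union of one or more
#' bracketed residue sets \code{[KR]} and named classes \code{<hydrophobic>}.
#' \code{P1} must be constrained: cleavage is C-terminal to P1.
#'
#' @param text A single rule string.
#' @param classes Named list of residue classes resolvable as \code{<name>}
#'   tokens; defaults to [defaultResidueClasses()].
#' @return A [CleavagePattern-class].
#' @examples
#' compilePattern("P1:[KR]")
#' compilePattern("P2:<hydrophobic> P1:[KR]")
#' compilePattern("P1:[K] P1':[P]")
#' @seealso [patternToText()], [bondMatches()]
#' @export
compilePattern <- function(text, classes = defaultResidueClasses()) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    stop("rule text must be a single nonempty string")
  toks <- gregexpr("[^[:space:]]+", text)[[1L]]
  words <- regmatches(text, gregexpr("[^[:space:]]+", text))[[1L]]
  constraints <- list()
  for (k in seq_along(words)) {
    word <- words[k]
    col <- toks[k]
    m <- regexec("^(P[0-9]['′]?):(.*)$", word)[[1L]]
    if (m[1L] == -1L)
      stop("syntax error at column ", col,
           ": expected position:class, got '", word, "'")
    parts <- regmatches(word, regexec("^(P[0-9]['′]?):(.*)$", word))[[1L]]
    pos <- chartr("′", "'", parts[2L])
    if (!pos %in% .positionLabels())
      stop("unknown position '", pos, "' at column ", col,
           " (allowed: ", paste(.positionLabels(), collapse = ", "), ")")
    if (pos %in% names(constraints))
      stop("position ", pos, " constrained twice (column ", col, ")")
    constraints[[pos]] <- .parseResidueClass(parts[3L], classes,
                                             col + nchar(pos) + 1L)
  }
  if (!"P1" %in% names(constraints))
    stop("missing P1 constraint: cleavage is defined C-terminal to P1")
  new("CleavagePattern", constraints = constraints)
}

.parseResidueClass <- function(spec, classes, col) {
  if (!nzchar(spec)) stop("empty residue class at column ", col)
  residues <- character(0)
  rest <- spec
  off <- 0L
  while (nzchar(rest)) {
    if (startsWith(rest, "[")) {
      close <- regexpr("]", rest, fixed = TRUE)
      if (close == -1L)
        stop("syntax error at column ", col + off, ": unclosed '['")
      inner <- substr(rest, 2L, close - 1L)
      if (!nzchar(inner))
        stop("empty residue class at column ", col + off)
      letters <- strsplit(inner, "", fixed = TRUE)[[1L]]
      bad <- setdiff(letters, canonicalResidues())
      if (length(bad))
        stop("unknown residue(s) '", paste(bad, collapse = ""),
             "' at column ", col + off)
      residues <- c(residues, letters)
      off <- off + close
      rest <- substr(rest, close + 1L, nchar(rest))
    } else if (startsWith(rest, "<")) {
      close <- regexpr(">", rest, fixed = TRUE)
      if (close == -1L)
        stop("syntax error at column ", col + off, ": unclosed '<'")
      nm <- substr(rest, 2L, close - 1L)
      if (!nm %in% names(classes))
        stop("unknown residue class <", nm, "> at column ", col + off,
             " (known: ", paste(names(classes), collapse = ", "), ")")
      residues <- c(residues, classes[[nm]])
      off <- off + close
      rest <- substr(rest, close + 1L, nchar(rest))
    } else {
      stop("syntax error at column ", col + off,
           ": expected '[' or '<', got '", substr(rest, 1L, 1L), "'")
    }
  }
  sort(unique(residues))
}

#' Serialize a cleavage pattern back to rule text
#'
#' Positions are emitted in N-to-C order with sorted, expanded residue sets;
#' re-compiling the output yields an equivalent matcher (compilation is
#' injective up to class normalization).
#'
#' @param pattern A [CleavagePattern-class].
#' @return A single rule string.
#' @export
patternToText <- function(pattern) {
  stopifnot(is(pattern, "CleavagePattern"))
  cons <- pattern@constraints
  ord <- intersect(.positionLabels(), names(cons))
  paste(vapply(ord, function(pos) {
    paste0(pos, ":[", paste(sort(cons[[pos]]), collapse = ""), "]")
  }, character(1)), collapse = " ")
}

#' Construct a protease specification
#'
#' @param name Enzyme name.
#' @param ec EC number in dotted-quad format.
#' @param patterns List of [CleavagePattern-class] objects, or rule strings
#'   to be compiled; a bond is cut if any pattern matches.
#' @param classes Residue classes used when compiling rule strings.
#' @return A [ProteaseSpec-class].
#' @examples
#' proteaseSpec("trypsin-like", "3.4.21.4", list("P1:[KR] P1':[ACDEFGHIKLMNQRSTVWY]"))
#' @export
proteaseSpec <- function(name, ec, patterns, classes = defaultResidueClasses()) {
  patterns <- lapply(patterns, function(p) {
    if (is.character(p)) compilePattern(p, classes) else p
  })
  new("ProteaseSpec", name = name, ec = ec, patterns = patterns)
}

#' Built-in protease specificity rules
#'
#' Explicit, documented approximations of the cleavage preferences of three
#' plant cysteine proteases, assembled from their qualitative descriptions:
#' \describe{
#'   \item{papain (EC 3.4.22.2)}{cuts after K/R when P2 is hydrophobic, and
#'     after hydrophobic residues (predominantly hydrophobic motifs).}
#'   \item{ficin (EC 3.4.22.3)}{favours arginine at P1; also cuts after the
#'     aromatic residues F/Y.}
#'   \item{bromelain (stem bromelain, EC 3.4.22.32)}{cuts adjacent to lysine,
#'     tyrosine and hydrophobic residues.}
#' }
#' These defaults are qualitative approximations, not a re-encoding of any
#' particular database's internal specificity matrices; reproducing another
#' tool's output requires supplying that tool's own rules via a rule file
#' ([readProteaseRules()]) or [proteaseSpec()].
#'
#' @param name One of \code{"papain"}, \code{"ficin"}, \code{"bromelain"}.
#' @param classes Residue classes used to expand \code{<hydrophobic>};
#'   redefining the class redefines the enzymes.
#' @return A [ProteaseSpec-class].
#' @examples
#' builtinProtease("bromelain")
#' @export
builtinProtease <- function(name, classes = defaultResidueClasses()) {
  known <- c("papain", "ficin", "bromelain")
  if (!is.character(name) || length(name) != 1L || !name %in% known)
    stop("unknown protease '", name, "'; available: ",
         paste(known, collapse = ", "))
  switch(name,
    papain = proteaseSpec("papain", "3.4.22.2",
      list("P2:<hydrophobic> P1:[KR]", "P1:<hydrophobic>"), classes),
    ficin = proteaseSpec("ficin", "3.4.22.3",
      list("P1:[R]", "P1:[FY]"), classes),
    bromelain = proteaseSpec("bromelain", "3.4.22.32",
      list("P1:[KY]<hydrophobic>"), classes))
}

#' Test whether a protease cuts a given peptide bond
#'
#' Bond \code{i} separates residues \code{i} and \code{i+1} (1-based). The
#' bond matches when at least one of the spec's patterns is satisfied with P1
#' at residue \code{i}, P1' at \code{i+1}, P2 at \code{i-1}, and so on. A
#' constraint referring to a position outside the sequence fails that
#' pattern (no wildcard padding at the termini).
#'
#' @param spec A [ProteaseSpec-class].
#' @param sequence A residue string.
#' @param bond Bond index, \code{1 <= bond <= nchar(sequence) - 1}.
#' @return Logical.
#' @examples
#' sp <- proteaseSpec("demo", "3.4.22.2", list("P1:[K]"))
#' bondMatches(sp, "AKG", 2)
#' @seealso [findSites()]
#' @export
bondMatches <- function(spec, sequence, bond) {
  stopifnot(is(spec, "ProteaseSpec"))
  sequence <- as.character(sequence)
  L <- nchar(sequence)
  if (!is.numeric(bond) || length(bond) != 1L || bond < 1L || bond > L - 1L)
    stop("bond index out of range: must satisfy 1 <= bond <= ", L - 1L)
  .matchBonds(spec, strsplit(sequence, "", fixed = TRUE)[[1L]])[as.integer(bond)]
}

## vectorized matcher over all bonds 1..L-1; returns logical(L-1)
.matchBonds <- function(spec, residues) {
  L <- length(residues)
  if (L < 2L) return(logical(0))
  bonds <- seq_len(L - 1L)
  hit <- logical(L - 1L)
  for (p in spec@patterns) {
    ok <- rep(TRUE, L - 1L)
    for (pos in names(p@constraints)) {
      idx <- bonds + .POSITION_OFFSETS[[pos]]
      inside <- idx >= 1L & idx <= L
      ok <- ok & inside
      ok[inside & ok] <- residues[idx[inside & ok]] %in% p@constraints[[pos]]
      if (!any(ok)) break
    }
    hit <- hit | ok
    if (all(hit)) break
  }
  hit
}

#' Read a protease rule file
#'
#' Plain-text format: \code{#} comments, \code{name=} and \code{ec=} header
#' lines, then one cleavage pattern per line in the [compilePattern()]
#' grammar.
#'
#' @param path Rule file path.
#' @param classes Residue classes for \code{<name>} tokens.
#' @return A [ProteaseSpec-class].
#' @examples
#' rf <- tempfile(fileext = ".rules")
#' writeLines(c("name=demo", "ec=3.4.22.2", "# cut after basics", "P1:[KR]"), rf)
#' readProteaseRules(rf)
#' @export
readProteaseRules <- function(path, classes = defaultResidueClasses()) {
  if (!file.exists(path)) stop("rule file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  name <- ec <- NULL
  pats <- list()
  for (ln in lines) {
    if (grepl("^name\\s*=", ln)) {
      name <- trimws(sub("^name\\s*=", "", ln))
    } else if (grepl("^ec\\s*=", ln)) {
      ec <- trimws(sub("^ec\\s*=", "", ln))
    } else {
      pats[[length(pats) + 1L]] <- compilePattern(ln, classes)
    }
  }
  if (is.null(name) || is.null(ec))
    stop("rule file must carry 'name=' and 'ec=' header lines: ", path)
  if (length(pats) == 0L) stop("rule file has no cleavage patterns: ", path)
  proteaseSpec(name, ec, pats)
}
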