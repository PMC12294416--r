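## run expr with a locally seeded RNG, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(as.integer(seed))
  expr
}

## independent, loop-based cleavage-site scan used to compute synthetic-panel
## ground truth; deliberately separate from the vectorized engine in
## .matchBonds so panel recovery is a genuine two-implementation cross-check
.scanSites <- function(sequence, spec) {
  L <- nchar(sequence)
  sites <- integer(0)
  if (L < 2L) return(sites)
  for (b in seq_len(L - 1L)) {
    for (p in spec@patterns) {
      ok <- TRUE
      for (pos in names(p@constraints)) {
        i <- b + .POSITION_OFFSETS[[pos]]
        if (i < 1L || i > L ||
            !substr(sequence, i, i) %in% p@constraints[[pos]]) {
          ok <- FALSE
          break
        }
      }
      if (ok) {
        sites <- c(sites, b)
        break
      }
    }
  }
  sites
}

## slice a sequence at bond indices into positional fragment sequences
.sliceAt <- function(sequence, sites) {
  starts <- c(0L, sites)
  ends <- c(sites, nchar(sequence))
  substring(sequence, starts + 1L, ends)
}

#' Generate a random protein sequence
#'
#' Draws residues independently from a composition over the canonical
#' alphabet; the same seed and parameters reproduce the sequence exactly
#' (the caller's RNG state is untouched).
#'
#' @param seed Integer seed.
#' @param length Sequence length (>= 1).
#' @param weights Optional named numeric composition weights over (a subset
#'   of) the canonical residues; default uniform. Must be nonnegative, not
#'   all zero.
#' @param id Name given to the record.
#' @return A length-1 named [Biostrings::AAStringSet].
#' @examples
#' genProtein(1, 30)
#' genProtein(1, 10, weights = c(A = 1))
#' @seealso [genPanel()]
#' @export
genProtein <- function(seed, length, weights = NULL, id = "SYNP1") {
  if (!is.numeric(length) || length < 1L) stop("length must be >= 1")
  alphabet <- canonicalResidues()
  if (is.null(weights)) {
    prob <- rep(1, length(alphabet))
  } else {
    if (is.null(names(weights)) ||
        !all(names(weights) %in% alphabet) ||
        any(weights < 0) || sum(weights) <= 0 || anyNA(weights))
      stop("weights must be a nonnegative, non-degenerate named vector over ",
           "canonical residues")
    prob <- rep(0, length(alphabet))
    prob[match(names(weights), alphabet)] <- weights
  }
  seq <- .withSeed(seed, paste(
    sample(alphabet, size = as.integer(length), replace = TRUE, prob = prob),
    collapse = ""))
  out <- Biostrings::AAStringSet(seq)
  names(out) <- id
  out
}

#' Plant a bioactive motif in a cleavable context
#'
#' Inserts \code{motif} into \code{sequence} so that, under complete
#' hydrolysis with \code{spec}, the motif is expected to be released intact:
#' its N-terminal boundary is made to follow a cut site (or the terminus) and
#' its C-terminal residue is made a cut site with a compatible P1' successor
#' (or the terminus). If the motif itself contains a matching internal bond
#' it cannot be released; the expected sub-fragments are recorded instead and
#' the release flag is FALSE.
#'
#' @param sequence Residue string (or length-1 [Biostrings::AAStringSet]).
#' @param motif Peptide to plant (canonical residues).
#' @param spec A [ProteaseSpec-class].
#' @param position 0-based residue offset in \code{sequence} after which the
#'   insertion is made (0 = N-terminus, \code{nchar(sequence)} = C-terminus).
#'   When no pattern of \code{spec} can cut after the motif's C-terminal
#'   residue, the insertion falls back to the C-terminus, where release
#'   requires no cut on that side.
#' @return list with \code{sequence} (the modified string), \code{start}
#'   (0-based offset of the motif in it), \code{released} (logical), and
#'   \code{expected} (the motif, or its sub-fragments when not releasable),
#'   computed by an independent position scan of the final sequence.
#' @examples
#' sp <- proteaseSpec("demo", "3.4.22.2", list("P1:[K]"))
#' plantMotif("AAAA", "GG", sp, position = 2)
#' @seealso [genPanel()]
#' @export
plantMotif <- function(sequence, motif, spec, position) {
  sequence <- .asSingleSequence(sequence)
  stopifnot(is(spec, "ProteaseSpec"))
  if (!.isCanonicalSeq(motif)) stop("motif must be a canonical residue string")
  L <- nchar(sequence)
  position <- as.integer(position)
  if (is.na(position) || position < 0L || position > L)
    stop("position must lie in 0..", L)

  rflank <- .boundaryFlank(spec, motif, "right", optional = position == L)
  if (is.null(rflank)) {
    ## no pattern can cut after the motif's last residue: fall back to the
    ## C-terminus, where release needs no cut on that side
    position <- L
    rflank <- ""
  }
  lflank <- if (position == 0L) "" else .boundaryFlank(spec, motif, "left")
  if (is.null(lflank))
    stop("impossible placement: no pattern of '", spec@name,
         "' can delimit motif '", motif, "' at position ", position)

  newSeq <- paste0(substr(sequence, 1L, position), lflank, motif, rflank,
                   substr(sequence, position + 1L, L))
  start <- position + nchar(lflank)
  sites <- .scanSites(newSeq, spec)
  len <- nchar(motif)
  newL <- nchar(newSeq)
  internal <- sites[sites > start & sites < start + len]
  boundariesCut <- (start == 0L || start %in% sites) &&
    (start + len == newL || (start + len) %in% sites)
  released <- length(internal) == 0L && boundariesCut
  expected <- if (length(internal) == 0L) motif else
    .sliceAt(motif, internal - start)
  list(sequence = newSeq, start = start, released = released,
       expected = expected)
}

## minimal residue context that forces a cut at a motif boundary; returns
## NULL when no pattern of the spec is compatible, "" when nothing is needed
.boundaryFlank <- function(spec, motif, side = c("left", "right"),
                           optional = FALSE) {
  side <- match.arg(side)
  len <- nchar(motif)
  for (p in spec@patterns) {
    cons <- p@constraints
    offs <- .POSITION_OFFSETS[names(cons)]
    if (side == "left") {
      ## cut at the bond preceding the motif: P1 and deeper sit in the flank,
      ## P1'/P2' must be satisfied by the motif's own first residues
      primeOK <- TRUE
      for (pos in names(cons)[offs > 0L]) {
        i <- .POSITION_OFFSETS[[pos]]
        if (i > len || !substr(motif, i, i) %in% cons[[pos]]) {
          primeOK <- FALSE
          break
        }
      }
      if (!primeOK) next
      depth <- max(1L, max(-offs[offs <= 0L]) + 1L)
      flank <- rep("G", depth)
      ok <- TRUE
      for (pos in names(cons)[offs <= 0L]) {
        slot <- depth + .POSITION_OFFSETS[[pos]]   # P1 at the flank's end
        if (slot < 1L) { ok <- FALSE; break }
        flank[slot] <- sort(cons[[pos]])[1L]
      }
      if (ok) return(paste(flank, collapse = ""))
    } else {
      ## cut at the bond after the motif's last residue: P1 and deeper must be
      ## satisfied by the motif itself, P1'/P2' by an appended flank
      nOK <- TRUE
      for (pos in names(cons)[offs <= 0L]) {
        i <- len + .POSITION_OFFSETS[[pos]]
        if (i < 1L || !substr(motif, i, i) %in% cons[[pos]]) {
          nOK <- FALSE
          break
        }
      }
      if (!nOK) next
      primeOffs <- offs[offs > 0L]
      if (length(primeOffs) == 0L) return("")
      depth <- max(primeOffs)
      flank <- rep("G", depth)
      for (pos in names(cons)[offs > 0L])
        flank[.POSITION_OFFSETS[[pos]]] <- sort(cons[[pos]])[1L]
      return(paste(flank, collapse = ""))
    }
  }
  if (optional) "" else NULL
}

## activity labels drawn on for synthetic vocabularies
.syntheticLabelPool <- function() {
  c("ACE inhibitor", "dipeptidyl peptidase IV inhibitor", "antioxidative",
    "antithrombotic", "renin inhibitor", "alpha-glucosidase inhibitor",
    "antiamnestic", "neuropeptide", "antibacterial", "anticancer",
    "hypotensive", "immunostimulating", "regulating", "stimulating")
}

#' Generate a synthetic score table with a fixed fraction above threshold
#'
#' Exactly \code{round(fracAbove * n)} peptides receive scores >= 0.50,
#' including up to three boundary values of exactly 0.50; the rest score
#' strictly below.
#'
#' @param peptides Character vector of unique peptide sequences.
#' @param seed Integer seed.
#' @param fracAbove Fraction of peptides scored at or above 0.50.
#' @return data.frame with columns \code{peptide}, \code{score} and
#'   attribute \code{nAboveThreshold}.
#' @seealso [classifyBioactive()]
#' @export
genScores <- function(peptides, seed, fracAbove = 0.4) {
  stopifnot(!anyDuplicated(peptides), fracAbove >= 0, fracAbove <= 1)
  n <- length(peptides)
  k <- as.integer(round(fracAbove * n))
  .withSeed(seed, {
    hi <- sample(n, k)
    score <- 0.4999 * stats::runif(n)
    score[hi] <- 0.5 + 0.5 * stats::runif(k)
    score[hi[seq_len(min(3L, k))]] <- 0.50
    out <- data.frame(peptide = peptides, score = score,
                      stringsAsFactors = FALSE)
    attr(out, "nAboveThreshold") <- k
    out
  })
}

#' Generate a fully synthetic test panel with known ground truth
#'
#' Builds proteins carrying bioactive motifs planted in cleavable contexts,
#' an activity database holding the planted motifs plus decoys guaranteed
#' absent from every digest, and a score table with a constructed number of
#' scores at or above 0.50. Ground truth (expected cleavage sites,
#' fragments, distinct peptides, matches and per-planting release flags) is
#' computed at generation time by an independent position scan, never by the
#' digestion engine, so pipeline-vs-truth comparisons cross two separate
#' implementations.
#'
#' Each protein is assembled from random background segments interleaved
#' with planted motifs. Motif bodies use only residues that no enzyme
#' accepts at P1 (so motifs carry no internal cleavage site), motifs end in
#' a residue every enzyme cuts after unconditionally, and each planting is
#' preceded by such a residue — making every planted motif releasable by
#' every enzyme in the panel.
#'
#' @param seed Integer seed; identical seed and parameters reproduce the
#'   panel byte-identically.
#' @param nProteins Number of proteins (default 16).
#' @param nMotifsPerProtein Planted motifs per protein (default 8).
#' @param vocabSize Number of activity labels (default 10, max 14).
#' @param nDecoys Decoy database entries (default 30).
#' @param backgroundLength Total background residues per protein (default 240).
#' @param enzymes Named list of [ProteaseSpec-class]; default papain, ficin
#'   and bromelain built-ins.
#' @param minPeptideLength Minimum peptide length used in the truth tables.
#' @param fracAbove Fraction of scored peptides at or above 0.50.
#' @return A [SyntheticPanel-class].
#' @examples
#' p <- genPanel(seed = 1, nProteins = 3, nMotifsPerProtein = 2,
#'               backgroundLength = 60, nDecoys = 5)
#' p
#' @seealso [plantMotif()], [writePanel()]
#' @export
genPanel <- function(seed, nProteins = 16L, nMotifsPerProtein = 8L,
                     vocabSize = 10L, nDecoys = 30L, backgroundLength = 240L,
                     enzymes = NULL, minPeptideLength = 2L, fracAbove = 0.4) {
  if (is.null(enzymes)) {
    enzymes <- list(papain = builtinProtease("papain"),
                    ficin = builtinProtease("ficin"),
                    bromelain = builtinProtease("bromelain"))
  }
  if (is.null(names(enzymes)))
    names(enzymes) <- vapply(enzymes, proteaseName, character(1))
  stopifnot(nProteins >= 1L, nMotifsPerProtein >= 0L, vocabSize >= 1L,
            nDecoys >= 0L, backgroundLength >= 10L)
  alphabet <- canonicalResidues()
  p1All <- unique(unlist(lapply(enzymes, function(e)
    unlist(lapply(e@patterns, function(p) p@constraints[["P1"]])))))
  quiet <- setdiff(alphabet, p1All)
  ## residues cut after unconditionally by every enzyme (P1-only patterns)
  anchors <- Reduce(intersect, lapply(enzymes, function(e) {
    unique(unlist(lapply(e@patterns, function(p) {
      if (identical(names(p@constraints), "P1")) p@constraints[["P1"]]
      else character(0)
    })))
  }))
  if (length(quiet) < 4L || length(anchors) == 0L)
    stop("enzyme panel leaves no quiet/anchor residues for motif planting")
  vocab <- utils::head(.syntheticLabelPool(), vocabSize)
  if (length(vocab) < vocabSize)
    stop("vocabSize must be at most ", length(.syntheticLabelPool()))

  .withSeed(seed, {
    ## motif pool: quiet body + universal anchor terminus
    nPool <- max(6L, ceiling(nProteins * nMotifsPerProtein / 10))
    pool <- character(0)
    while (length(pool) < nPool) {
      body <- paste(sample(quiet, sample(1:4, 1L), replace = TRUE),
                    collapse = "")
      cand <- paste0(body, sample(anchors, 1L))
      if (!cand %in% pool) pool <- c(pool, cand)
    }
    ## activities: round-robin base label so all vocabSize labels occur,
    ## plus random extras (multifunctional entries)
    motifActs <- lapply(seq_along(pool), function(i) {
      extra <- sample(vocab, sample(0:2, 1L))
      unique(c(vocab[((i - 1L) %% length(vocab)) + 1L], extra))
    })
    names(motifActs) <- pool

    ## proteins: background segments interleaved with anchored motifs
    ids <- sprintf("SYNP%02d", seq_len(nProteins))
    seqs <- character(nProteins)
    plantings <- vector("list", nProteins)
    segLen <- max(3L, backgroundLength %/% (nMotifsPerProtein + 1L))
    for (i in seq_len(nProteins)) {
      chosen <- if (nMotifsPerProtein > 0L)
        sample(pool, nMotifsPerProtein, replace = TRUE) else character(0)
      parts <- character(0)
      rec <- data.frame(motif = character(0), start = integer(0))
      at <- 0L
      for (m in chosen) {
        seg <- paste(sample(alphabet, segLen, replace = TRUE), collapse = "")
        lead <- sample(anchors, 1L)
        parts <- c(parts, seg, lead, m)
        at <- at + nchar(seg) + 1L
        rec <- rbind(rec, data.frame(motif = m, start = at))
        at <- at + nchar(m)
      }
      parts <- c(parts, paste(sample(alphabet, segLen, replace = TRUE),
                              collapse = ""))
      seqs[i] <- paste(parts, collapse = "")
      plantings[[i]] <- rec
    }
    proteins <- Biostrings::AAStringSet(seqs)
    names(proteins) <- ids

    ## truth per enzyme x protein from the independent scan
    truth <- lapply(enzymes, function(spec) {
      perProt <- lapply(seq_len(nProteins), function(i) {
        sites <- .scanSites(seqs[i], spec)
        frags <- .sliceAt(seqs[i], sites)
        peps <- unique(frags[nchar(frags) >= minPeptideLength])
        rec <- plantings[[i]]
        released <- vapply(seq_len(nrow(rec)), function(j) {
          s <- rec$start[j]
          len <- nchar(rec$motif[j])
          noInternal <- !any(sites > s & sites < s + len)
          cutL <- s == 0L || s %in% sites
          cutR <- (s + len) == nchar(seqs[i]) || (s + len) %in% sites
          noInternal && cutL && cutR
        }, logical(1))
        list(sites = sites, fragments = frags, peptides = peps,
             planted = cbind(rec, released = released))
      })
      names(perProt) <- ids
      perProt
    })

    ## database: planted motifs + decoys absent from every expected peptide set
    allTruthPeps <- unique(unlist(lapply(truth, function(tt)
      lapply(tt, `[[`, "peptides")), use.names = FALSE))
    decoys <- character(0)
    while (length(decoys) < nDecoys) {
      cand <- paste(sample(alphabet, sample(3:6, 1L), replace = TRUE),
                    collapse = "")
      if (!cand %in% allTruthPeps && !cand %in% pool && !cand %in% decoys)
        decoys <- c(decoys, cand)
    }
    decoyActs <- lapply(seq_along(decoys), function(i)
      unique(sample(vocab, sample(1:2, 1L))))
    names(decoyActs) <- decoys
    ## with nothing planted the database holds decoys only, so the expected
    ## match count is zero everywhere by construction
    ent <- c(if (nMotifsPerProtein > 0L) motifActs, decoyActs)
    db <- activityDB(rep(names(ent), lengths(ent)),
                     unlist(ent, use.names = FALSE))

    ## complete the truth tables with expected matches
    truth <- lapply(truth, function(perProt) {
      lapply(perProt, function(tt) {
        hit <- tt$peptides[tt$peptides %in% names(ent)]
        tt$matched <- ent[hit]
        tt
      })
    })

    scores <- genScores(sort(allTruthPeps), seed = sample.int(2^30, 1L),
                        fracAbove = fracAbove)
    params <- list(nProteins = nProteins,
                   nMotifsPerProtein = nMotifsPerProtein,
                   vocabSize = vocabSize, nDecoys = nDecoys,
                   backgroundLength = backgroundLength,
                   minPeptideLength = minPeptideLength,
                   fracAbove = fracAbove,
                   nAboveThreshold = attr(scores, "nAboveThreshold"),
                   motifPool = pool, decoys = decoys)
    new("SyntheticPanel", proteins = proteins, db = db, enzymes = enzymes,
        truth = truth, scores = scores, seed = as.integer(seed),
        params = params)
  })
}

#' Write a synthetic panel to disk
#'
#' Emits \code{proteins.fasta}, \code{activity_db.tsv}, \code{scores.tsv}
#' and a plain-text \code{truth.json} ground-truth table into \code{dir}.
#'
#' @param panel A [SyntheticPanel-class].
#' @param dir Output directory (created if needed).
#' @return Invisibly, \code{dir}.
#' @export
writePanel <- function(panel, dir) {
  stopifnot(is(panel, "SyntheticPanel"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeProteinFasta(panel@proteins, file.path(dir, "proteins.fasta"))
  writeActivityDB(panel@db, file.path(dir, "activity_db.tsv"))
  .writeTSV(panel@scores, file.path(dir, "scores.tsv"))
  truth <- lapply(panel@truth, function(perProt) lapply(perProt, function(tt) {
    list(sites = tt$sites, fragments = tt$fragments, peptides = tt$peptides,
         matched = tt$matched,
         planted = list(motif = tt$planted$motif, start = tt$planted$start,
                        released = tt$planted$released))
  }))
  jsonlite::write_json(list(seed = panel@seed, truth = truth),
                       file.path(dir, "truth.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(dir)
}
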