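# Brute-force oracle: an independent, deliberately naive implementation of
# the cleavage-pattern semantics, coded against the written definition (per
# bond, per pattern, per position) and kept separate from the package's
# vectorized engine.

POSITION_OFFSETS <- c("P4" = -3L, "P3" = -2L, "P2" = -1L,
                      "P1" = 0L, "P1'" = 1L, "P2'" = 2L)

oracleBondMatch <- function(spec, residues, bond) {
  L <- length(residues)
  for (p in cleavagePatterns(spec)) {
    cons <- p@constraints
    ok <- TRUE
    for (pos in names(cons)) {
      i <- bond + POSITION_OFFSETS[[pos]]
      if (i < 1L || i > L || !(residues[i] %in% cons[[pos]])) {
        ok <- FALSE
        break
      }
    }
    if (ok) return(TRUE)
  }
  FALSE
}

oracleSites <- function(sequence, spec) {
  residues <- strsplit(sequence, "", fixed = TRUE)[[1]]
  L <- length(residues)
  if (L < 2L) return(integer(0))
  which(vapply(seq_len(L - 1L), function(b)
    oracleBondMatch(spec, residues, b), logical(1)))
}

oracleFragments <- function(sequence, spec) {
  sites <- oracleSites(sequence, spec)
  starts <- c(0L, sites)
  ends <- c(sites, nchar(sequence))
  substring(sequence, starts + 1L, ends)
}

oracleDigestPeptides <- function(sequence, spec, minLen = 2L) {
  fr <- oracleFragments(sequence, spec)
  unique(fr[nchar(fr) >= minLen])
}

# random instance generators (fixed alphabet, caller controls the seed)
randomSequence <- function(len) {
  paste(sample(canonicalResidues(), len, replace = TRUE), collapse = "")
}

randomPattern <- function() {
  positions <- c("P1", sample(setdiff(names(POSITION_OFFSETS), "P1"),
                              sample(0:2, 1)))
  cons <- lapply(positions, function(p)
    sort(sample(canonicalResidues(), sample(1:6, 1))))
  names(cons) <- positions
  methods::new("CleavagePattern", constraints = cons)
}

randomSpec <- function(nPatterns = sample(1:3, 1)) {
  proteaseSpec(name = "random", ec = "3.4.22.99",
               patterns = replicate(nPatterns, randomPattern(), simplify = FALSE))
}
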