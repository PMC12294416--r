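#' Canonical amino-acid alphabet and residue classes
#'
#' The pipeline works over the 20 canonical one-letter amino-acid codes.
#' Ambiguity codes (B, J, O, U, X, Z) are rejected on input by default; a
#' permissive mode maps them to the sentinel residue \code{"X"}, which matches
#' no cleavage pattern and disqualifies any containing fragment from database
#' matching.
#'
#' @return \code{canonicalResidues()} returns the 20 canonical residue
#'   letters; \code{ambiguityResidues()} the rejected ambiguity codes;
#'   \code{defaultResidueClasses()} a named list of residue classes usable in
#'   the cleavage-rule grammar as \code{<name>} tokens.
#' @examples
#' canonicalResidues()
#' defaultResidueClasses()$hydrophobic
#' @export
canonicalResidues <- function() {
  strsplit("ACDEFGHIKLMNPQRSTVWY", "", fixed = TRUE)[[1]]
}

#' @rdname canonicalResidues
#' @export
ambiguityResidues <- function() {
  c("B", "J", "O", "U", "X", "Z")
}

## sentinel for permissive ambiguity handling; never canonical, never cleaved
.SENTINEL <- "X"

#' @rdname canonicalResidues
#' @export
defaultResidueClasses <- function() {
  list(
    hydrophobic = c("A", "V", "L", "I", "F", "W", "Y", "M"),
    aromatic    = c("F", "W", "Y"),
    basic       = c("K", "R", "H")
  )
}

## relative bond positions in Schechter-Berger notation mapped to residue
## offsets from the bond index (P1 sits at the bond index itself; cleavage is
## C-terminal to P1)
.POSITION_OFFSETS <- c(
  "P4" = -3L, "P3" = -2L, "P2" = -1L, "P1" = 0L, "P1'" = 1L, "P2'" = 2L
)

.positionLabels <- function() names(.POSITION_OFFSETS)
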