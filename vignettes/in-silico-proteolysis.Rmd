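---
title: "In silico proteolysis and bioactive peptide mining with PepDigest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In silico proteolysis and bioactive peptide mining with PepDigest}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PepDigest)
```

## The procedure and its assumptions

PepDigest simulates single-protease hydrolysis of protein sequences and
mines the released peptides for documented bioactivities. The pipeline has
four stages, each exposed as ordinary functions:

1. **Digestion.** A protease is a union of cleavage patterns over relative
   bond positions in Schechter–Berger notation (P4…P2′), with cleavage
   C-terminal to P1. Under the working assumption of *ideal and complete
   hydrolysis*, every bond matching any pattern is cut simultaneously. This
   is the standard simplification of rule-based digestion tools: it ignores
   steric accessibility, competition between sites, and all kinetic
   parameters (enzyme concentration, time, pH, temperature), and therefore
   yields a qualitative inventory of theoretically releasable fragments,
   not a quantitative release profile. No missed-cleavage enumeration is
   performed, and enzymes act singly, never as a cocktail.
2. **Matching.** A released peptide is bioactive if its *full* sequence is a
   key of the user-supplied activity database. A database dipeptide buried
   inside a longer fragment is not counted: an uncleavable context would
   never release it, and substring counting would inflate counts with
   fragments that complete hydrolysis cannot produce.
3. **Profiling.** Counts are tabulated per protein × enzyme (summary
   table), per activity × enzyme (activity tables), and per
   (protein × enzyme) × activity (heatmap matrix). A multifunctional
   peptide counts once under each of its labels, so per-activity columns
   may sum above the distinct-peptide count.
4. **Threshold classification.** Scores from an external sequence-based
   ranker are consumed from a table and classified bioactive at
   score ≥ 0.50, boundary inclusive. The ranker itself is out of scope by
   design: reimplementing a trained model would produce numbers with no
   provenance.

## Tunable parameters

* `minPeptideLength` (default 2, residues): fragments shorter than this are
  not peptides. Free amino acids are conventionally excluded from peptide
  counts; the toggle exists because database tools do not all agree.
* `counting` (`"distinct"` default, or `"occurrence"`): whether a sequence
  released *k* times from one protein counts once or *k* times. Distinct
  counting makes results insensitive to repeats and matches the reading of
  "distinct peptide sequences with documented bioactive properties";
  occurrence counting is provided because digestion reports sometimes count
  positional fragments.
* `scoreThreshold` (default 0.50, inclusive) for external scores in [0, 1].
* Residue classes (default `<hydrophobic>` = {A, V, L, I, F, W, Y, M},
  `<aromatic>` = {F, W, Y}, `<basic>` = {K, R, H}) are user-redefinable;
  "hydrophobic" has no single canonical definition, so the set used is
  explicit and documented rather than implied.
* Built-in enzymes (papain, ficin, bromelain) are qualitative
  approximations assembled from the enzymes' described preferences — papain
  favouring hydrophobic motifs, ficin P1-arginine plus aromatic sites,
  bromelain sites adjacent to lysine, tyrosine and hydrophobic residues.
  They are **not** a re-encoding of any database's internal specificity
  matrices, which are not public; users who need to reproduce a specific
  tool's output must supply that tool's rules via `readProteaseRules()`.

## Numerical and design choices

* **Bond indexing.** Bonds are numbered 1…L−1 on the residue string; bond
  *i* separates residues *i* and *i+1*; P1 sits at residue *i*. All
  fragment coordinates in outputs are 0-based half-open `[start, end)`.
* **Termini.** A pattern constraint that falls off either end of the
  sequence fails that pattern. No wildcard padding is invented: a P2
  constraint simply cannot be satisfied at bond 1.
* **Ambiguity codes.** B, J, O, U, X, Z are rejected with a located error by
  default. A permissive mode maps them to the sentinel `X`, which belongs to
  no pattern's residue set and cannot equal any database key, so affected
  fragments are silently disqualified from matching rather than guessed at.
  Which sequence variant (isoform, signal-peptide state) to digest is the
  caller's decision; the FASTA given to the pipeline is treated as ground
  truth.
* **Ordering.** Peptides are reported in order of first occurrence along
  the protein; activity vocabularies are emitted alphabetically in all
  outputs so that reruns and diffs are stable regardless of database row
  order. All tables are TSV with LF endings, and the run log contains no
  timestamps, making whole-directory byte-identity across reruns a tested
  contract.
* **Motif planting at the C-terminus.** `plantMotif()` places a motif so a
  cut site precedes it and its last residue is itself a cut site. When no
  pattern of the enzyme can cut after the motif's final residue, interior
  release is impossible under C-terminal-to-P1 cleavage — flanking such a
  motif with cleavable residues would only release motif-plus-anchor. The
  function therefore falls back to placing the motif at the C-terminus,
  where release needs no cut on that side; truly impossible placements (no
  pattern can cut *before* the motif either) are errors.

## What the synthetic generator emulates — and what it does not

`genPanel()` builds a 16-protein × 3-enzyme panel mirroring the shape of a
typical storage-protein screening experiment. Each protein is random
background (uniform residue composition, 240 residues by default)
interleaved with 8 planted motifs. Motif bodies use only residues that no
panel enzyme accepts at P1, so motifs carry no internal cleavage site;
motifs end in, and are preceded by, a residue that every panel enzyme cuts
after unconditionally (F or Y for the built-ins). Every planting is
therefore releasable by every enzyme, and the panel's ground truth —
expected sites, fragments, peptides, matches and per-planting release
flags — is computed at generation time by a deliberately separate,
loop-based position scan, never by the digestion engine. Pipeline-vs-truth
agreement is thus a genuine two-implementation cross-check, and the test
suite adds a third, independently coded brute-force oracle.

The database holds the planted motifs plus 30 decoy peptides
rejection-sampled to be absent from every expected peptide set, giving a
zero-false-positive control. The score table assigns exactly
`round(0.4 · n)` of the released peptides scores ≥ 0.50, including values of
exactly 0.50 to pin the inclusive boundary.

The generator does **not** emulate real rapeseed (or any) proteome
composition, domain structure, post-translational modification, or the
empirical length/potency distributions of curated activity databases.
Passing the recovery tests therefore demonstrates that the *machinery* —
rule evaluation, slicing, counting, joining — is exact, not that the
built-in rules reproduce any particular published count table; those depend
on unpublished specificity encodings and database versions and are
explicitly not a target.

## Validation problem sizes

The package validates itself at these scales (chosen to characterise the
algorithms well while keeping a full test run under a minute): engine vs
brute-force oracle on 1000 random rule/sequence pairs with lengths 1–500;
conservation, site-count and fixed-point identities on 300 further random
digests; planted-motif recovery, count reconciliation, determinism and
table-shape checks on the default 16 × 3 panel (384 plantings); threshold
classification on the panel's ~1100-peptide score table with a constructed
above-threshold count. `scripts/acceptance.R` recomputes the same
quantities from scratch under a caller-supplied seed.

## Command-line surface

The package's functions are the primary interface; `inst/scripts/pepdigest.R`
wraps them for shell use with `run`, `digest`, `synth` and `classify`
subcommands. Matching and profiling are not exposed as standalone
subcommands: they are meaningless without a digest in hand, so the `run`
subcommand executes digest → match → profile (→ classify) as one
deterministic unit, which also keeps the on-disk outputs mutually
consistent by construction.

## Known limitations

* Complete hydrolysis over-predicts: real digests are rarely exhaustive,
  so released-peptide lists are best read as candidate inventories.
* Conversely, qualitative rule sets under-cut wherever a real enzyme's
  specificity is broader than its textbook description.
* Exact full-sequence matching misses database peptides embedded in longer
  fragments; this is intentional (see above) but means counts are lower
  bounds with respect to substring-based tools.
* Scores are taken at face value from the external table; no calibration or
  uncertainty is attached to the 0.50 threshold.
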