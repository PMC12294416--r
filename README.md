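# PepDigest

In silico proteolysis and bioactive peptide mining in R.

Plant-derived cysteine proteases — papain, ficin and stem bromelain — are
widely used to hydrolyse plant storage proteins into peptides with
health-relevant activities (ACE inhibition, DPP-IV inhibition, antioxidant
action, and others). Screening such hydrolysates computationally is a
standard first step before any wet-lab work: digest the protein sequences
*in silico* under each enzyme's cleavage specificity, look the released
fragments up in a peptide-activity database, and rank the enzymes by how
many (bioactive) peptides they release. PepDigest implements that workflow
as a reusable, fully testable pipeline for bioinformaticians and food/
nutraceutical protein scientists.

## The model

Cleavage specificity is written in Schechter–Berger notation. For a peptide
bond between residues *i* and *i+1*, position P1 is residue *i*, P1′ is
residue *i+1*, P2 is *i−1*, and so on; cleavage is C-terminal to P1. An
enzyme is a union of patterns, each constraining some positions to residue
sets:

```
P2:[AVLIFWYM] P1:[KR]     # cut after K/R when preceded by a hydrophobic residue
P1:<hydrophobic>          # cut after any hydrophobic residue
```

Digestion assumes **ideal and complete hydrolysis**: every bond matching any
pattern is cut simultaneously, so fragments are the maximal uncut substrings
and contain no internal cleavage site (digestion is a fixed point). The
distinct fragment sequences of length ≥ 2 are the digest's peptides;
peptides whose full sequence occurs in the activity database are its
bioactive peptides (substring hits do not count). Externally scored
peptides (e.g. by a sequence-based bioactivity ranker) are classified
bioactive at score ≥ 0.50, boundary inclusive.

The built-in enzyme rules are explicit qualitative approximations (papain:
hydrophobic motifs; ficin: P1-arginine and aromatic sites; bromelain:
lysine, tyrosine and hydrophobic residues); every rule is overridable from
a plain-text rule file, and kinetics (enzyme concentration, time, pH,
temperature) are deliberately out of scope.

## Worked example

```r
library(PepDigest)

sp <- builtinProtease("bromelain")
sp
#> ProteaseSpec 'bromelain' (EC 3.4.22.32)
#>   P1:[AFIKLMVWY]

d <- digestProtein("MKWVTFISLLFLFSSAYSRGV", sp, id = "demo")
d
#> DigestResult: protein 'demo' x protease 'bromelain'
#>   parent length: 21; cleavage sites: 13; fragments: 14; distinct peptides (len >= 2): 4

peptides(d)
#> [1] "TF"   "SL"   "SSA"  "SRGV"

db <- activityDB(c("TF", "SS"), c("ACE inhibitor", "antioxidative"))
matchFragments(d, db)
#>   protein_id    enzyme peptide n_occurrences    activities
#> 1       demo bromelain      TF             1 ACE inhibitor
```

The 13 cleavage sites are every bond whose P1 residue is in bromelain's set
`[AFIKLMVWY]`; of the 14 fragments, 4 are distinct peptides of length ≥ 2,
and exactly one ("TF") is a full-sequence database hit — "SS" is present in
the database but only *inside* the fragment "SSA", so it does not count.

A full run over a protein FASTA, an activity database and an optional score
table is one call:

```r
cfg <- pipelineConfig(fasta = "proteins.fasta",
                      enzymes = c("papain", "ficin", "bromelain"),
                      db = "activity_db.tsv", scores = "scores.tsv",
                      out = "results")
res <- runPipeline(cfg)
```

writing `summary.tsv` (peptide and bioactive-peptide counts per protein ×
enzyme with per-enzyme totals), `activities_<enzyme>.tsv` (per-activity
counts over the full vocabulary), `heatmap_long.tsv`/`matches.tsv`,
per-enzyme peptide FASTAs, and a deterministic run log. The same pipeline
is scriptable from a shell via `inst/scripts/pepdigest.R`
(`run`, `digest`, `synth`, `classify`).

Because real activity databases are versioned, licensed exports, the
package ships none; `genPanel()` generates a fully synthetic
16-protein × 3-enzyme panel — proteins with bioactive motifs planted in
cleavable contexts, a database of planted motifs plus guaranteed-absent
decoys, and a score table with a constructed above-threshold count — whose
ground truth is computed independently of the digestion engine.

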