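test_that("protein generation is seed-deterministic and honours composition", {
  a <- genProtein(5, 50)
  b <- genProtein(5, 50)
  expect_identical(as.character(a), as.character(b))
  expect_false(identical(as.character(genProtein(6, 50)), as.character(a)))

  one <- genProtein(5, 1)
  expect_equal(unname(nchar(as.character(one))), 1L)

  polyA <- genProtein(5, 10, weights = c(A = 1))
  expect_equal(unname(as.character(polyA)), "AAAAAAAAAA")

  expect_error(genProtein(5, 10, weights = c(A = -1)), "weights")
  expect_error(genProtein(5, 10, weights = c(ZZ = 1)), "weights")

  # the caller's RNG stream is not disturbed
  set.seed(123); x <- runif(1)
  set.seed(123); invisible(genProtein(1, 10)); y <- runif(1)
  expect_identical(x, y)
})

test_that("planted motifs in cleavable contexts are released by the digestion engine", {
  spK <- proteaseSpec("d", "3.4.22.2", list("P1:[K]"))

  pl <- plantMotif("AAAA", "GG", spK, position = 2)
  expect_true(pl$released)
  d <- digestProtein(pl$sequence, spK)
  expect_true("GG" %in% peptides(d))
  frag <- fragments(d)
  expect_true(any(frag$sequence == "GG" & frag$start == pl$start))

  # a motif with an internal cut site cannot be released intact
  pl2 <- plantMotif("AAAA", "AKA", spK, position = 2)
  expect_false(pl2$released)
  expect_equal(pl2$expected, c("AK", "A"))
  expect_false("AKA" %in% peptides(digestProtein(pl2$sequence, spK)))

  # incompatible P1' requirement makes interior placement impossible
  spKP <- proteaseSpec("d", "3.4.22.2", list("P1:[K] P1':[P]"))
  expect_error(plantMotif("AAAA", "GG", spKP, position = 2),
               "impossible placement")
})

test_that("random plantings under each built-in enzyme are recovered 100%", {
  set.seed(61)
  quiet <- setdiff(canonicalResidues(),
                   c(defaultResidueClasses()$hydrophobic, "K", "R"))
  for (enzyme in c("papain", "ficin", "bromelain")) {
    spec <- builtinProtease(enzyme)
    hits <- 0L
    flagged <- 0L
    for (rep in 1:35) {
      bg <- randomSequence(sample(30:60, 1))
      motif <- paste(c(sample(quiet, sample(1:4, 1), replace = TRUE),
                       sample(c("F", "Y"), 1)), collapse = "")
      pl <- plantMotif(bg, motif, spec, position = sample(0:nchar(bg), 1))
      if (pl$released) {
        flagged <- flagged + 1L
        hits <- hits + ("TRUE" == as.character(
          motif %in% peptides(digestProtein(pl$sequence, spec))))
      }
    }
    expect_gt(flagged, 25)           # construction releases almost always
    expect_equal(hits, flagged)      # every release flag is honoured
  }
})

test_that("panels regenerate byte-identically from the same seed", {
  a <- genPanel(seed = 3, nProteins = 3, nMotifsPerProtein = 2,
                backgroundLength = 60, nDecoys = 5)
  b <- genPanel(seed = 3, nProteins = 3, nMotifsPerProtein = 2,
                backgroundLength = 60, nDecoys = 5)
  expect_identical(as.character(panelProteins(a)), as.character(panelProteins(b)))
  expect_identical(dbEntries(panelDB(a)), dbEntries(panelDB(b)))
  expect_identical(panelTruth(a), panelTruth(b))
  expect_identical(panelScores(a), panelScores(b))
  c <- genPanel(seed = 4, nProteins = 3, nMotifsPerProtein = 2,
                backgroundLength = 60, nDecoys = 5)
  expect_false(identical(as.character(panelProteins(a)),
                         as.character(panelProteins(c))))
})

test_that("panel truth is internally consistent and decoys never match", {
  pan <- genPanel(seed = 8, nProteins = 5, nMotifsPerProtein = 3,
                  backgroundLength = 80, nDecoys = 10)
  truth <- panelTruth(pan)
  decoys <- pan@params$decoys
  for (enzName in names(truth)) {
    for (prot in names(truth[[enzName]])) {
      tt <- truth[[enzName]][[prot]]
      # conservation and counting identities hold inside the truth tables
      seqn <- as.character(panelProteins(pan))[[match(prot, proteinIds(panelProteins(pan)))]]
      expect_equal(paste(tt$fragments, collapse = ""), seqn)
      expect_equal(length(tt$fragments), length(tt$sites) + 1L)
      expect_lte(length(tt$matched), length(tt$peptides))
      expect_true(all(names(tt$matched) %in% tt$peptides))
      expect_length(intersect(decoys, tt$peptides), 0)
    }
  }
  # zero planted motifs means zero expected bioactives beyond chance; with
  # decoys excluded by construction, matches must be empty
  bare <- genPanel(seed = 9, nProteins = 3, nMotifsPerProtein = 0,
                   backgroundLength = 60, nDecoys = 8)
  for (enzName in names(panelTruth(bare)))
    for (prot in names(panelTruth(bare)[[enzName]])) {
      expect_length(panelTruth(bare)[[enzName]][[prot]]$matched, 0)
    }
})

test_that("written panels reload into consistent pipeline inputs", {
  pan <- genPanel(seed = 12, nProteins = 3, nMotifsPerProtein = 2,
                  backgroundLength = 60, nDecoys = 5)
  dir <- tempfile()
  writePanel(pan, dir)
  expect_true(all(file.exists(file.path(dir,
    c("proteins.fasta", "activity_db.tsv", "scores.tsv", "truth.json")))))
  prot <- readProteinFasta(file.path(dir, "proteins.fasta"))
  expect_identical(unname(as.character(prot)),
                   unname(as.character(panelProteins(pan))))
  db <- loadActivityDB(file.path(dir, "activity_db.tsv"))
  expect_setequal(names(dbEntries(db)), names(dbEntries(panelDB(pan))))
  sc <- loadScores(file.path(dir, "scores.tsv"))
  expect_equal(nrow(sc), nrow(panelScores(pan)))
})
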