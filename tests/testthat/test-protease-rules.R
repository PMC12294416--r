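test_that("the rule grammar compiles legal patterns and rejects illegal ones", {
  p <- compilePattern("P1:[KR]")
  expect_s4_class(p, "CleavagePattern")
  expect_equal(p@constraints, list(P1 = c("K", "R")))

  p <- compilePattern("P1:[K] P1':[P]")
  expect_equal(p@constraints[["P1'"]], "P")

  p <- compilePattern("P2:<hydrophobic> P1:[KR]")
  expect_setequal(p@constraints$P2, defaultResidueClasses()$hydrophobic)

  # named classes and bracket sets union within one position
  p <- compilePattern("P1:[KY]<hydrophobic>")
  expect_setequal(p@constraints$P1,
                  union(c("K", "Y"), defaultResidueClasses()$hydrophobic))

  expect_error(compilePattern("P1:[]"), "empty residue class")
  expect_error(compilePattern("P2:[K]"), "missing P1")
  expect_error(compilePattern("P9:[K]"), "unknown position")
  expect_error(compilePattern("P1:[K1]"), "unknown residue")
  expect_error(compilePattern("P1:<greasy>"), "unknown residue class")
  expect_error(compilePattern("P1-[K]"), "column 1")
  expect_error(compilePattern("P1:[K"), "unclosed")
})

test_that("built-in enzymes encode the documented preferences", {
  ficin <- builtinProtease("ficin")
  expect_equal(ecNumber(ficin), "3.4.22.3")
  p1Sets <- lapply(cleavagePatterns(ficin), function(p) p@constraints$P1)
  expect_true(any(vapply(p1Sets, function(s) "R" %in% s, logical(1))))

  brom <- builtinProtease("bromelain")
  expect_equal(ecNumber(brom), "3.4.22.32")
  p1 <- unique(unlist(lapply(cleavagePatterns(brom),
                             function(p) p@constraints$P1)))
  expect_true(all(c("K", "Y") %in% p1))
  expect_true(all(defaultResidueClasses()$hydrophobic %in% p1))

  papain <- builtinProtease("papain")
  expect_equal(ecNumber(papain), "3.4.22.2")
  expect_true(all(defaultResidueClasses()$hydrophobic %in%
                    unique(unlist(lapply(cleavagePatterns(papain),
                                         function(p) p@constraints$P1)))))

  expect_error(builtinProtease("trypsin"), "papain, ficin, bromelain")
})

test_that("bond matching follows P1/P1' semantics with no terminal padding", {
  spK <- proteaseSpec("d", "3.4.22.2", list("P1:[K]"))
  expect_true(bondMatches(spK, "AKG", 2))
  expect_false(bondMatches(spK, "AKG", 1))

  spKP <- proteaseSpec("d", "3.4.22.2", list("P1:[K] P1':[P]"))
  expect_true(bondMatches(spKP, "AKPG", 2))
  expect_false(bondMatches(spKP, "AKGG", 2))

  spFK <- proteaseSpec("d", "3.4.22.2", list("P2:[F] P1:[K]"))
  expect_true(bondMatches(spFK, "FKA", 2))
  expect_false(bondMatches(spFK, "KAV", 1))  # P2 falls off the N-terminus

  expect_error(bondMatches(spK, "AKG", 3), "out of range")
  expect_error(bondMatches(spK, "AKG", 0), "out of range")
})

test_that("engine agrees with the brute-force oracle bond by bond", {
  set.seed(11)
  for (rep in 1:40) {
    sp <- randomSpec()
    seqn <- randomSequence(sample(2:80, 1))
    residues <- strsplit(seqn, "", fixed = TRUE)[[1]]
    for (b in seq_len(nchar(seqn) - 1L)) {
      expect_identical(bondMatches(sp, seqn, b),
                       oracleBondMatch(sp, residues, b))
    }
  }
})

test_that("enlarging a residue class never unmatches a bond (monotonicity)", {
  set.seed(12)
  for (rep in 1:25) {
    sp <- randomSpec(1)
    cons <- sp@patterns[[1]]@constraints
    pos <- sample(names(cons), 1)
    bigger <- cons
    bigger[[pos]] <- union(bigger[[pos]],
                           sample(canonicalResidues(), sample(1:5, 1)))
    spBig <- proteaseSpec("bigger", "3.4.22.99",
                          list(methods::new("CleavagePattern",
                                            constraints = bigger)))
    seqn <- randomSequence(60)
    expect_true(all(findSites(seqn, sp) %in% findSites(seqn, spBig)))
  }
})

test_that("pattern union means logical OR over patterns", {
  set.seed(13)
  for (rep in 1:25) {
    a <- randomPattern()
    b <- randomPattern()
    spA <- proteaseSpec("a", "3.4.22.99", list(a))
    spB <- proteaseSpec("b", "3.4.22.99", list(b))
    spAB <- proteaseSpec("ab", "3.4.22.99", list(a, b))
    seqn <- randomSequence(60)
    expect_setequal(findSites(seqn, spAB),
                    union(findSites(seqn, spA), findSites(seqn, spB)))
  }
})

test_that("serialize-then-recompile yields an equivalent matcher", {
  set.seed(14)
  for (rep in 1:25) {
    p <- randomPattern()
    p2 <- compilePattern(patternToText(p))
    sp1 <- proteaseSpec("a", "3.4.22.99", list(p))
    sp2 <- proteaseSpec("b", "3.4.22.99", list(p2))
    seqn <- randomSequence(60)
    expect_identical(findSites(seqn, sp1), findSites(seqn, sp2))
  }
})

test_that("rule files round-trip name, EC and patterns", {
  rf <- tempfile(fileext = ".rules")
  writeLines(c("# a trypsin-like demo", "name=demo", "ec=3.4.21.4",
               "P1:[KR]", "P1:[W] P1':[G]"), rf)
  sp <- readProteaseRules(rf)
  expect_equal(proteaseName(sp), "demo")
  expect_equal(ecNumber(sp), "3.4.21.4")
  expect_length(cleavagePatterns(sp), 2)
  expect_true(bondMatches(sp, "AWGA", 2))

  writeLines("P1:[K]", rf)
  expect_error(readProteaseRules(rf), "name=")
})
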