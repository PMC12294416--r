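spKR <- proteaseSpec("d", "3.4.22.2", list("P1:[KR]"))

test_that("site finding applies the rules exactly", {
  expect_equal(findSites("AKRG", spKR), c(2L, 3L))
  expect_equal(findSites("A", spKR), integer(0))
  expect_equal(findSites("GGGG", spKR), integer(0))
})

test_that("digestion slices at all sites and counts distinct peptides", {
  d <- digestProtein("AKRG", spKR, id = "P1")
  expect_equal(fragments(d)$sequence, c("AK", "R", "G"))
  expect_equal(fragments(d)$start, c(0L, 2L, 3L))
  expect_equal(fragments(d)$end, c(2L, 3L, 4L))
  expect_equal(peptides(d), "AK")
  expect_equal(totalPeptides(d), 1L)

  # no matching bond: the whole protein is the single fragment
  d0 <- digestProtein("MKV", proteaseSpec("none", "3.4.22.2", list("P1:[W]")))
  expect_equal(fragments(d0)$sequence, "MKV")
  expect_equal(totalPeptides(d0), 1L)

  # minPeptideLength = 1 admits single residues; repeats collapse
  d1 <- digestProtein("AKAKG", spKR, minPeptideLength = 1L)
  expect_equal(fragments(d1)$sequence, c("AK", "AK", "G"))
  expect_equal(peptides(d1), c("AK", "G"))
  expect_error(digestProtein("AKG", spKR, minPeptideLength = 0L), ">= 1")
})

test_that("engine digests equal the brute-force oracle on random instances", {
  set.seed(21)
  for (rep in 1:150) {
    sp <- randomSpec()
    seqn <- randomSequence(sample(1:120, 1))
    d <- digestProtein(seqn, sp)
    expect_identical(cleavageSites(d), oracleSites(seqn, sp))
    expect_identical(fragments(d)$sequence, oracleFragments(seqn, sp))
    expect_identical(peptides(d), oracleDigestPeptides(seqn, sp))
  }
})

test_that("fragments conserve the parent and number sites + 1", {
  set.seed(22)
  for (rep in 1:100) {
    sp <- randomSpec()
    seqn <- randomSequence(sample(1:150, 1))
    d <- digestProtein(seqn, sp)
    expect_equal(paste(fragments(d)$sequence, collapse = ""), seqn)
    expect_equal(nrow(fragments(d)), length(cleavageSites(d)) + 1L)
  }
})

test_that("complete hydrolysis is a fixed point; corrupted results are caught", {
  set.seed(23)
  for (rep in 1:50) {
    sp <- randomSpec()
    d <- digestProtein(randomSequence(sample(2:100, 1)), sp)
    expect_true(redigestIsStable(d, sp))
  }
  # negative control: a hand-built "fragment" with an internal cut site
  spK <- proteaseSpec("d", "3.4.22.2", list("P1:[K]"))
  fake <- methods::new("DigestResult", proteinId = "P", protease = "d",
                       sequence = "AKA", sites = integer(0),
                       fragments = data.frame(start = 0L, end = 3L,
                                              sequence = "AKA"),
                       peptides = "AKA", minPeptideLength = 2L)
  expect_false(redigestIsStable(fake, spK))
})

test_that("adding patterns never decreases the site count", {
  set.seed(24)
  for (rep in 1:30) {
    base <- randomSpec(1)
    extra <- proteaseSpec("more", "3.4.22.99",
                          c(cleavagePatterns(base), list(randomPattern())))
    seqn <- randomSequence(80)
    expect_true(all(findSites(seqn, base) %in% findSites(seqn, extra)))
    expect_gte(length(findSites(seqn, extra)), length(findSites(seqn, base)))
  }
})

test_that("digestSet covers every protein x enzyme cell once", {
  prots <- c(A = "AKRGG", B = "MKVLIP")
  specs <- list(builtinProtease("papain"), builtinProtease("ficin"))
  res <- digestSet(prots, specs)
  expect_length(res, 4)
  cells <- vapply(res, function(r) paste(r@proteinId, r@protease), character(1))
  expect_setequal(cells, c("A papain", "B papain", "A ficin", "B ficin"))
})
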