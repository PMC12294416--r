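spK <- proteaseSpec("demo", "3.4.22.2", list("P1:[K]"))

test_that("matching is exact full-fragment membership", {
  db <- activityDB(c("AK", "GG"), c("ACE inhibitor", "antioxidative"))
  d <- digestProtein("AKGAV", spK, id = "P")
  m <- matchFragments(d, db)
  expect_equal(m$peptide, "AK")
  expect_equal(m$activities[[1]], "ACE inhibitor")

  # a DB dipeptide buried inside a longer released fragment does not count
  expect_false("GG" %in% m$peptide)  # GG sits inside fragment "GGAV"? recheck:
  d2 <- digestProtein("AKGGAV", spK, id = "P")
  m2 <- matchFragments(d2, db)
  expect_equal(m2$peptide, "AK")  # "GGAV" contains GG but is not equal to it

  # disjoint peptide set and DB
  m3 <- matchFragments(digestProtein("MKVW", spK, id = "P"),
                       activityDB("YY", "ACE inhibitor"))
  expect_equal(nrow(m3), 0)
})

test_that("matching equals a brute-force set intersection on random digests", {
  set.seed(41)
  labels <- paste("act", 1:4)
  for (rep in 1:25) {
    sp <- randomSpec()
    seqn <- randomSequence(sample(20:120, 1))
    d <- digestProtein(seqn, sp, id = "P")
    # DB built from a mix of released and never-released sequences
    somePeps <- sample(peptides(d), min(3, totalPeptides(d)))
    others <- replicate(4, randomSequence(sample(2:6, 1)))
    dbPeps <- unique(c(somePeps, others))
    db <- activityDB(dbPeps, sample(labels, length(dbPeps), replace = TRUE))
    m <- matchFragments(d, db)
    expect_setequal(m$peptide, intersect(peptides(d), names(dbEntries(db))))
  }
})

test_that("summary rows count totals and bioactives per cell with enzyme totals", {
  db <- activityDB(c("AK", "VV"), c("ACE inhibitor", "antioxidative"))
  prots <- c(A = "AKGAVVKAK", B = "GGKAKVV")
  res <- digestSet(prots, list(spK))
  m <- matchAll(res, db)
  s <- buildSummary(res, m)
  expect_equal(names(s),
               c("protein_id", "enzyme", "total_peptides", "bioactive_peptides"))
  rowA <- s[s$protein_id == "A", ]
  expect_equal(rowA$total_peptides, totalPeptides(res[[1]]))
  tot <- s[s$protein_id == "in total", ]
  expect_equal(tot$total_peptides,
               sum(s$total_peptides[s$protein_id != "in total"]))
  expect_equal(tot$bioactive_peptides,
               sum(s$bioactive_peptides[s$protein_id != "in total"]))
  expect_true(all(s$bioactive_peptides <= s$total_peptides))

  # a missing protein x enzyme cell is a consistency error
  res2 <- digestSet(prots, list(spK, builtinProtease("ficin")))
  expect_error(buildSummary(res2[-1], matchAll(res2[-1], db)), "missing digest")
})

test_that("occurrence counting counts positional fragments, not sequences", {
  db <- activityDB("AK", "ACE inhibitor")
  res <- digestSet(c(A = "AKAKAK"), list(spK))
  m <- matchAll(res, db)
  sDist <- buildSummary(res, m, counting = "distinct")
  sOcc <- buildSummary(res, m, counting = "occurrence")
  expect_equal(sDist$total_peptides[1], 1L)   # {"AK"}
  expect_equal(sOcc$total_peptides[1], 3L)    # AK, AK, AK
  expect_equal(sDist$bioactive_peptides[1], 1L)
  expect_equal(sOcc$bioactive_peptides[1], 3L)
})

test_that("activity profiles count distinct (protein, peptide) pairs per label", {
  db <- activityDB(c("AK", "AK", "VV"),
                   c("ACE inhibitor", "DPP IV inhibitor", "antioxidative"))
  vocab <- activityVocabulary(db)

  # one multifunctional match counts once under each of its labels
  res <- digestSet(c(A = "AKG"), list(spK))
  prof <- buildActivityProfile(matchAll(res, db), vocab, protease = "demo")
  expect_equal(prof$count[prof$activity == "ACE inhibitor"], 1L)
  expect_equal(prof$count[prof$activity == "DPP IV inhibitor"], 1L)
  expect_equal(attr(prof, "bioactive_total"), 1L)
  expect_gte(sum(prof$count), attr(prof, "bioactive_total"))

  # the same peptide matched in two proteins counts twice
  res2 <- digestSet(c(A = "AKG", B = "KAKC"), list(spK))
  prof2 <- buildActivityProfile(matchAll(res2, db), vocab, protease = "demo")
  expect_equal(prof2$count[prof2$activity == "ACE inhibitor"], 2L)
  expect_equal(attr(prof2, "bioactive_total"), 2L)

  # full vocabulary is reported, zeros included, alphabetically
  expect_setequal(prof2$activity, vocab)
  expect_equal(prof2$activity, sort(vocab))
  expect_equal(prof2$count[prof2$activity == "antioxidative"], 0L)
})

test_that("heatmap matrices carry the full grid and reconcile with profiles", {
  db <- activityDB(c("AK", "VV"), c("ACE inhibitor", "antioxidative"))
  vocab <- activityVocabulary(db)
  res <- digestSet(c(A = "AKG", B = "CCCC"), list(spK))
  m <- matchAll(res, db)
  grid <- data.frame(protein_id = c("A", "B"), enzyme = "demo")
  hm <- buildHeatmapMatrix(m, vocab, grid = grid)
  expect_equal(dim(hm$matrix), c(2L, 2L))
  expect_equal(hm$matrix["A|demo", "ACE inhibitor"], 1L)
  expect_equal(sum(hm$matrix["B|demo", ]), 0L)  # all-zero row kept
  expect_equal(nrow(hm$long), 4L)
  expect_equal(sum(hm$long$count), sum(hm$matrix))

  # column marginals equal the profile counts
  prof <- buildActivityProfile(m, vocab, protease = "demo")
  expect_equal(unname(colSums(hm$matrix)[prof$activity]), prof$count)

  # labels outside the vocabulary are a consistency error
  expect_error(buildHeatmapMatrix(m, "something else", grid = grid),
               "outside the vocabulary")
})
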