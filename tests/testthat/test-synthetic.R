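test_that("planted distances and angles are realized to 0.01 A", {
  for (s in c(1, 2, 3)) {
    d1 <- 3.6 + 0.3 * s; d2 <- 4.8 - 0.2 * s; ang <- 4 * s; da <- 3.1 + 0.4 * s
    g <- siteGeometry(
      aromatic1 = list(resid = "PHE", chain = "A", resno = 706L, dC5CG = d1,
                       angle = ang, centroidDist = 3.5),
      aromatic2 = list(resid = "HIS", chain = "B", resno = 710L, dC5CG = d2,
                       angle = 0, centroidDist = 4.0),
      arginine = list(present = TRUE, chain = "B", resno = 711L, dPGCZ = da),
      seed = s)
    m <- makeBindingSiteStructure(g)$model
    lig <- extractLigands(m)[[1]]
    ct <- assessStacking(m, lig, findAromaticContacts(m, lig), screenCriteria())
    expect_equal(sort(ct$distC5CG), sort(c(d1, d2)), tolerance = 0.01)
    expect_equal(sort(ct$stackingAngle), sort(c(ang, 0)), tolerance = 0.5)
    ac <- findArginineGammaContacts(m, lig)
    expect_equal(ac$distPGCZ, da, tolerance = 0.01)
  }
})

test_that("every decoy mode is labelled with its designed tier and screens to it", {
  modes <- c("none", "far_aromatic", "single_aromatic", "same_chain",
             "no_stacking", "no_arginine")
  want <- c("T4_full", "none", "none", "T1_pair_contact",
            "T2_cross_subunit", "T3_dual_stacking")
  for (i in seq_along(modes)) {
    g <- siteGeometry(decoyMode = modes[i], seed = 90 + i)
    expect_equal(g$expectedTier, want[i])
    res <- makeBindingSiteStructure(g)
    f <- tempfile(fileext = ".pdb")
    writeStructure(res$model, f)
    hits <- screenLibrary(f)
    got <- if (nrow(hits) == 0) "none" else hits$tier[1]
    expect_equal(got, want[i])
  }
})

test_that("a labelled library screens back to its ground truth end-to-end", {
  lib <- makeStructureLibrary(30, tempfile("lib"), seed = 19)
  hits <- screenLibrary(lib$path)
  got <- hits$tier[match(lib$entryId, hits$entryId)]
  got[is.na(got)] <- "none"
  expect_equal(got, lib$tier)
  # sidecar labels are written alongside the fixtures
  expect_true(file.exists(file.path(dirname(lib$path[1]), "labels.tsv")))
})

test_that("structure and sequence generation are byte-identical under a fixed seed", {
  d1 <- tempfile("gen1"); d2 <- tempfile("gen2")
  makeStructureLibrary(4, d1, seed = 33)
  makeStructureLibrary(4, d2, seed = 33)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  makeSequenceFamily(familyDesign(nSequences = 25, seed = 5), fasta = f1)
  makeSequenceFamily(familyDesign(nSequences = 25, seed = 5), fasta = f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("family construction hits the designed prevalence and identity band", {
  des <- familyDesign(nSequences = 200, motifPrevalence = 0.75, seed = 7)
  fam <- makeSequenceFamily(des)
  expect_equal(sum(fam$labels$motif != "absent"), 150)
  # deterministic detection: scanning recovers exactly the planted positives
  hasMotif <- vapply(fam$sequences, function(s)
    nrow(scanSequence(s, motifSpec())) > 0, TRUE)
  expect_equal(unname(hasMotif), fam$labels$motif == "canonical")
  # identity to reference equals the per-sequence mutation budget
  ids <- vapply(fam$sequences[1:20], percentIdentity, 0, b = fam$reference)
  expect_equal(unname(ids), 100 * (des$length - fam$labels$nMutations[1:20]) /
                 des$length, tolerance = 1e-9)
  expect_true(all(ids >= 69.9 & ids <= 95.1))
  # zero prevalence -> nothing to find
  fam0 <- makeSequenceFamily(familyDesign(nSequences = 20,
                                          motifPrevalence = 0, seed = 8))
  expect_equal(sum(vapply(fam0$sequences, function(s)
    nrow(scanSequence(s, motifSpec())) > 0, TRUE)), 0)
})

test_that("infeasible designs are rejected up front", {
  expect_error(familyDesign(length = 700, anchorStart = 702),
               "at least anchorStart")
  expect_error(familyDesign(identityRange = c(0.5, 2)),
               "identity band unreachable")
  expect_error(siteGeometry(aromatic1 = list(resid = "TYR", chain = "A",
                                             resno = 706L, dC5CG = -1,
                                             angle = 0, centroidDist = 3.6)),
               "infeasible geometry")
  g <- siteGeometry(aromatic1 = list(resid = "TYR", chain = "A",
                                     resno = 706L, dC5CG = 12,
                                     angle = 0, centroidDist = 3.5))
  expect_error(makeBindingSiteStructure(g), "infeasible geometry")
})
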