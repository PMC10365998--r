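crit <- screenCriteria()

test_that("aromatic contacts match planted distances and sort by distance", {
  g <- siteGeometry(
    aromatic1 = list(resid = "TYR", chain = "A", resno = 706L, dC5CG = 4.0,
                     angle = 0, centroidDist = 3.6),
    aromatic2 = list(resid = "HIS", chain = "B", resno = 710L, dC5CG = 4.5,
                     angle = 0, centroidDist = 3.6),
    seed = 31)
  m <- makeBindingSiteStructure(g)$model
  lig <- extractLigands(m)[[1]]
  ct <- findAromaticContacts(m, lig, crit)
  expect_equal(ct$resid, c("TYR", "HIS"))
  expect_equal(ct$distC5CG, c(4.0, 4.5), tolerance = 1e-6)
})

test_that("the 5 A aromatic cutoff is inclusive and 5.2 A is out", {
  # hand-built site: C5 at origin, CG atoms at exact distances on an axis
  base <- list(
    atomRow("HETATM", "L", 900, "ATP", "C5", c(0, 0, 0)),
    atomRow("HETATM", "L", 900, "ATP", "N9", c(1.4, 0, 0)),
    atomRow("ATOM", "A", 10, "GLY", "CA", c(20, 20, 20)))
  mIn <- handModel(c(base, list(
    atomRow("ATOM", "A", 1, "TYR", "CG", c(5.0, 0, 0)))))
  mOut <- handModel(c(base, list(
    atomRow("ATOM", "A", 1, "TYR", "CG", c(5.2, 0, 0)))))
  ligIn <- extractLigands(mIn, "ATP")[[1]]
  ligOut <- extractLigands(mOut, "ATP")[[1]]
  expect_equal(nrow(findAromaticContacts(mIn, ligIn, crit)), 1)
  expect_equal(findAromaticContacts(mIn, ligIn, crit)$distC5CG, 5.0)
  expect_equal(nrow(findAromaticContacts(mOut, ligOut, crit)), 0)
})

test_that("contacts and arginine hits equal the brute-force all-atom oracle", {
  lib <- makeStructureLibrary(15, tempfile("lib"), seed = 77)
  for (p in lib$path) {
    m <- readStructure(p)
    for (lig in extractLigands(m)) {
      ct <- suppressWarnings(findAromaticContacts(m, lig, crit))
      bf <- bruteAromaticContacts(m, lig)
      expect_equal(nrow(ct), nrow(bf))
      expect_equal(ct$distC5CG, bf$d, tolerance = 1e-9)
      expect_equal(paste(ct$chain, ct$resno), paste(bf$chain, bf$resno))
      ac <- findArginineGammaContacts(m, lig, crit)
      ba <- bruteArgContacts(m, lig)
      expect_equal(nrow(ac), nrow(ba))
      expect_equal(ac$distPGCZ, ba$d, tolerance = 1e-9)
    }
  }
})

test_that("arginine criterion handles multiple and absent gamma-phosphates", {
  g <- siteGeometry(seed = 41)
  m <- makeBindingSiteStructure(g)$model
  lig <- extractLigands(m)[[1]]
  a1 <- findArginineGammaContacts(m, lig, crit)
  expect_equal(a1$distPGCZ, 3.8, tolerance = 1e-6)
  # add a second arginine CZ by hand at 4.9 A from PG
  at <- atomTable(m)
  pg <- pgCoords(lig)
  extra <- at[at$resid == "ARG" & at$elety == "CZ", ][1, ]
  dirv <- c(0, 0, 1)
  extra$x <- pg[1] + 4.9 * dirv[1]; extra$y <- pg[2] + 4.9 * dirv[2]
  extra$z <- pg[3] + 4.9 * dirv[3]; extra$resno <- 715L; extra$chain <- "A"
  m2 <- new("StructureModel", entryId = "X", atoms = rbind(at, extra),
            sourceFormat = "synthetic")
  lig2 <- extractLigands(m2)[[1]]
  a2 <- findArginineGammaContacts(m2, lig2, crit)
  expect_equal(nrow(a2), 2)
  expect_equal(a2$distPGCZ, sort(a2$distPGCZ))  # ascending
  # ADP carries no gamma-phosphate -> vacuously empty
  expect_warning(
    mAdp <- makeBindingSiteStructure(
      siteGeometry(seed = 41, ligandCode = "ADP",
                   arginine = list(present = TRUE, chain = "B", resno = 711L,
                                   dPGCZ = 3.8)))$model,
    "no gamma-phosphate")
  ligAdp <- suppressWarnings(extractLigands(mAdp, "ADP"))[[1]]
  expect_equal(nrow(findArginineGammaContacts(mAdp, ligAdp, crit)), 0)
})

test_that("stacking requires both near-parallel planes and close centroids", {
  mk <- function(angle, cent) {
    g <- siteGeometry(
      aromatic1 = list(resid = "TYR", chain = "A", resno = 706L,
                       dC5CG = 4.5, angle = angle, centroidDist = cent),
      aromatic2 = NULL, decoyMode = "single_aromatic", seed = 8)
    m <- makeBindingSiteStructure(g)$model
    lig <- extractLigands(m)[[1]]
    assessStacking(m, lig, findAromaticContacts(m, lig, crit), crit)
  }
  parallel <- mk(0, 3.6)
  expect_true(parallel$stacked[1])
  expect_lt(parallel$stackingAngle[1], 1)
  expect_equal(parallel$centroidDistance[1], 3.6, tolerance = 1e-6)
  tshaped <- mk(90, 4.4)
  expect_false(tshaped$stacked[1])
  expect_gt(tshaped$stackingAngle[1], 60)
  farCent <- mk(0, 6.0)
  expect_false(farCent$stacked[1])
})

test_that("tryptophan stacking uses the full bicyclic indole plane", {
  # indole built as purine-shaped 9-atom system 3.5 A above the ligand ring
  pur <- allosite:::.purineCoords()
  trpNames <- c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2")
  rows <- c(
    lapply(rownames(pur), function(a)
      atomRow("HETATM", "L", 900, "ATP", a, pur[a, ])),
    lapply(seq_along(trpNames), function(i)
      atomRow("ATOM", "A", 50, "TRP", trpNames[i],
              pur[i, ] + c(0, 0, 3.5))),
    list(atomRow("ATOM", "A", 60, "GLY", "CA", c(30, 0, 0))))
  m <- handModel(rows)
  lig <- extractLigands(m, "ATP")[[1]]
  ct <- assessStacking(m, lig, findAromaticContacts(m, lig, crit), crit)
  expect_equal(nrow(ct), 1)
  expect_equal(ct$resid, "TRP")
  expect_true(ct$stacked[1])
  expect_equal(ct$centroidDistance[1], 3.5, tolerance = 1e-9)
  expect_lt(ct$stackingAngle[1], 1e-6)
})

test_that("site classification follows the cumulative tier ladder", {
  contact <- function(chain, d, stacked)
    data.frame(chain = chain, resno = 1L, insert = "", resid = "TYR",
               distC5CG = d, stacked = stacked, stackingAngle = 0,
               centroidDistance = 3.5)
  argRow <- data.frame(chain = "B", resno = 7L, insert = "", resid = "ARG",
                       distPGCZ = 4.0)
  noArg <- argRow[0, ]
  lig <- new("LigandInstance", compId = "ATP", chainId = "L",
             seqNum = 900L, insert = "", atoms = data.frame(),
             purineAtoms = "C5", c5 = c(0, 0, 0), pg = c(8, 0, 0))
  ligNoPg <- new("LigandInstance", compId = "ADP", chainId = "L",
                 seqNum = 900L, insert = "", atoms = data.frame(),
                 purineAtoms = "C5", c5 = c(0, 0, 0), pg = numeric(0))
  # enumerated truth table over (pair, cross, dual-stack, arg)
  expect_null(classifySite(contact("A", 4, TRUE), noArg, lig))
  t1 <- rbind(contact("A", 4, TRUE), contact("A", 4.5, FALSE))
  expect_equal(classifySite(t1, noArg, lig)$tier, "T1_pair_contact")
  t2 <- rbind(contact("A", 4, TRUE), contact("B", 4.5, FALSE))
  expect_equal(classifySite(t2, noArg, lig)$tier, "T2_cross_subunit")
  t3 <- rbind(contact("A", 4, TRUE), contact("B", 4.5, TRUE))
  expect_equal(classifySite(t3, noArg, lig)$tier, "T3_dual_stacking")
  expect_equal(classifySite(t3, argRow, lig)$tier, "T4_full")
  # same-chain pair with an arginine still caps at T1
  expect_equal(classifySite(t1, argRow, lig)$tier, "T1_pair_contact")
  # arginine cannot promote a ligand without a gamma-phosphate
  expect_equal(classifySite(t3, argRow, ligNoPg)$tier, "T3_dual_stacking")
})

test_that("tier is monotone in the cutoffs", {
  g <- siteGeometry(seed = 55)        # full T4 site, distances 4.0/4.5/3.8
  m <- makeBindingSiteStructure(g)$model
  f <- tempfile(fileext = ".pdb"); writeStructure(m, f)
  tierAt <- function(dAromatic = 5, dArg = 5, angleMax = 30) {
    h <- screenLibrary(f, screenCriteria(dAromatic = dAromatic, dArg = dArg,
                                         stackingAngleMax = angleMax))
    h$tier[1]
  }
  byAromatic <- vapply(c(3.0, 4.2, 4.6, 5.0, 6.0), function(d)
    tierIndex(tierAt(dAromatic = d)), 0)
  expect_true(all(diff(byAromatic) >= 0))
  byArg <- vapply(c(3.0, 3.9, 5.0), function(d)
    tierIndex(tierAt(dArg = d)), 0)
  expect_true(all(diff(byArg) >= 0))
  byAngle <- vapply(c(2, 10, 30), function(a)
    tierIndex(tierAt(angleMax = a)), 0)
  expect_true(all(diff(byAngle) >= 0))
})

test_that("screening is invariant under rigid rotation and translation", {
  base <- siteGeometry(seed = 60, rigidTransform = FALSE)
  m0 <- makeBindingSiteStructure(base)$model
  lig0 <- extractLigands(m0)[[1]]
  ct0 <- assessStacking(m0, lig0, findAromaticContacts(m0, lig0, crit), crit)
  for (s in c(61, 62)) {
    rot <- siteGeometry(seed = s, rigidTransform = TRUE)
    m1 <- makeBindingSiteStructure(rot)$model
    lig1 <- extractLigands(m1)[[1]]
    ct1 <- assessStacking(m1, lig1, findAromaticContacts(m1, lig1, crit),
                          crit)
    expect_equal(ct1$distC5CG, ct0$distC5CG, tolerance = 1e-6)
    expect_equal(ct1$stackingAngle, ct0$stackingAngle, tolerance = 1e-6)
    expect_equal(ct1$centroidDistance, ct0$centroidDistance,
                 tolerance = 1e-6)
  }
})

test_that("criterion-1-only mode admits ADP/AMP and never reports T4", {
  dir <- tempfile("c1lib")
  lib <- makeStructureLibrary(10, dir, seed = 13,
                              modeMix = c(none = 1))  # all full T4 designs
  hits <- screenLibrary(lib$path, crit, mode = "criterion1_only")
  expect_true(all(hits$tier != "T4_full"))
  expect_true(all(hits$tier == "T3_dual_stacking"))
  # an ADP site is visible in criterion1_only but not in full mode
  gAdp <- siteGeometry(seed = 14, ligandCode = "ADP",
                       arginine = list(present = FALSE, chain = "B",
                                       resno = 711L, dPGCZ = 3.8))
  fAdp <- tempfile(fileext = ".pdb")
  writeStructure(makeBindingSiteStructure(gAdp)$model, fAdp)
  expect_equal(nrow(screenLibrary(fAdp, crit, mode = "full")), 0)
  expect_equal(screenLibrary(fAdp, crit, mode = "criterion1_only")$tier,
               "T3_dual_stacking")
})

test_that("unreadable files yield error rows without stopping the screen", {
  good <- tempfile(fileext = ".pdb")
  writeStructure(makeBindingSiteStructure(siteGeometry(seed = 2))$model, good)
  bad <- tempfile(fileext = ".pdb")
  writeLines("HEADER ONLY", bad)
  hits <- screenLibrary(c(bad, good))
  expect_equal(nrow(hits), 2)
  expect_true(any(!is.na(hits$error)))
  expect_true(any(hits$tier == "T4_full"))
})

test_that("tier summaries count sites and entries distinctly", {
  lib <- makeStructureLibrary(12, tempfile("sum"), seed = 5)
  hits <- screenLibrary(lib$path)
  cs <- tierCounts(hits, "site")
  ce <- tierCounts(hits, "entry")
  expect_equal(sum(cs), nrow(hits))
  expect_equal(sum(ce), length(unique(hits$entryId)))
  expect_equal(unname(cs["T4_full"]), sum(lib$tier == "T4_full"))
})
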