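test_that("PDB and mmCIF round-trips preserve atoms, names, chains and coordinates", {
  g <- siteGeometry(seed = 21)
  m <- makeBindingSiteStructure(g)$model
  for (fmt in c("pdb", "mmcif")) {
    f <- tempfile(fileext = if (fmt == "pdb") ".pdb" else ".cif")
    writeStructure(m, f, fmt)
    back <- readStructure(f)
    a0 <- atomTable(m); a1 <- atomTable(back)
    expect_equal(nrow(a1), nrow(a0))
    k <- function(a) paste(a$chain, a$resno, a$resid, a$elety)
    expect_setequal(k(a1), k(a0))
    idx <- match(k(a0), k(a1))
    expect_equal(as.matrix(a1[idx, c("x", "y", "z")]),
                 as.matrix(a0[, c("x", "y", "z")]),
                 tolerance = 1e-3, ignore_attr = TRUE)
    expect_equal(sourceFormat(back), fmt)
  }
})

test_that("only the first coordinate model of a multi-model file is read", {
  m <- makeBindingSiteStructure(siteGeometry(seed = 3))$model
  f1 <- tempfile(fileext = ".pdb")
  writeStructure(m, f1)
  lines <- readLines(f1)
  atomLines <- grep("^(ATOM|HETATM)", lines, value = TRUE)
  shifted <- atomLines
  multi <- c("MODEL     1", atomLines, "ENDMDL",
             "MODEL     2", shifted, "ENDMDL", "END")
  f2 <- tempfile(fileext = ".pdb")
  writeLines(multi, f2)
  back <- readStructure(f2)
  expect_equal(nrow(atomTable(back)), nrow(atomTable(m)))
})

test_that("altlocs collapse to the highest-occupancy conformer, ties to 'A'", {
  f <- tempfile(fileext = ".pdb")
  bio3d::write.pdb(file = f, type = rep("ATOM", 4),
                   xyz = c(0, 0, 0, 1, 0, 0, 5, 5, 5, 6, 5, 5),
                   resno = c(1, 1, 2, 2), resid = rep("GLY", 4),
                   chain = rep("A", 4), elety = rep("CA", 4),
                   eleno = 1:4, alt = c("A", "B", "B", "A"),
                   o = c(0.4, 0.6, 0.5, 0.5), b = rep(0, 4),
                   elesy = rep("C", 4))
  back <- atomTable(readStructure(f))
  expect_equal(nrow(back), 2)
  # residue 1: occupancy 0.6 wins (altloc B); residue 2: tie, altloc A wins
  expect_equal(back$x[back$resno == 1], 1)
  expect_equal(back$x[back$resno == 2], 6)
})

test_that("hydrogens are dropped and waters flagged on read", {
  f <- tempfile(fileext = ".pdb")
  bio3d::write.pdb(file = f, type = c("ATOM", "ATOM", "HETATM"),
                   xyz = c(0, 0, 0, 1, 0, 0, 9, 9, 9),
                   resno = c(1, 1, 300), resid = c("GLY", "GLY", "HOH"),
                   chain = c("A", "A", "A"), elety = c("CA", "HA", "O"),
                   eleno = 1:3, o = rep(1, 3), b = rep(0, 3),
                   elesy = c("C", "H", "O"))
  back <- atomTable(readStructure(f))
  expect_false(any(back$elesy == "H"))
  expect_equal(back$category[back$resid == "HOH"], "water")
  expect_equal(nrow(back), 2)
})

test_that("ligand extraction resolves C5/PG and respects component chemistry", {
  g <- siteGeometry(seed = 4, ligandCode = "ANP")
  m <- makeBindingSiteStructure(g)$model
  ligs <- extractLigands(m, codes = "ANP")
  expect_length(ligs, 1)
  expect_equal(compId(ligs[[1]]), "ANP")
  expect_length(c5Coords(ligs[[1]]), 3)
  expect_length(pgCoords(ligs[[1]]), 3)

  gAdp <- siteGeometry(seed = 4, ligandCode = "ADP",
                       arginine = list(present = FALSE, chain = "B",
                                       resno = 711L, dPGCZ = 3.8))
  mAdp <- makeBindingSiteStructure(gAdp)$model
  adp <- extractLigands(mAdp, codes = "ADP")
  expect_length(adp, 1)
  expect_length(pgCoords(adp[[1]]), 0)

  expect_length(extractLigands(m, codes = "ATP"), 0)
})

test_that("ligand extraction is format-independent", {
  m <- makeBindingSiteStructure(siteGeometry(seed = 9))$model
  fp <- tempfile(fileext = ".pdb"); fc <- tempfile(fileext = ".cif")
  writeStructure(m, fp); writeStructure(m, fc)
  lp <- extractLigands(readStructure(fp))
  lc <- extractLigands(readStructure(fc))
  expect_equal(length(lp), length(lc))
  expect_equal(compId(lp[[1]]), compId(lc[[1]]))
  expect_equal(c5Coords(lp[[1]]), c5Coords(lc[[1]]), tolerance = 1e-3)
  expect_equal(sort(lp[[1]]@purineAtoms), sort(lc[[1]]@purineAtoms))
})

test_that("unreadable and empty files raise informative errors", {
  expect_error(readStructure(tempfile()), "not found")
  f <- tempfile(fileext = ".pdb")
  writeLines(c("HEADER    EMPTY", "END"), f)
  expect_error(readStructure(f), "empty coordinate section")
})

test_that("a nucleotide residue lacking all purine atoms is excluded with a warning", {
  rows <- list(
    atomRow("ATOM", "A", 1, "GLY", "CA", c(0, 0, 0)),
    atomRow("ATOM", "A", 2, "GLY", "CA", c(3, 0, 0)),
    atomRow("HETATM", "A", 900, "ATP", "PG", c(9, 0, 0)))
  m <- handModel(rows)
  expect_warning(ligs <- extractLigands(m, codes = "ATP"),
                 "lacks all purine ring atoms")
  expect_length(ligs, 0)
})
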