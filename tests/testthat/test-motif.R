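test_that("the canonical motif is found at its reference position", {
  seq <- plantMotif(strrep("A", 800), 702)
  m <- scanSequence(seq, motifSpec())
  expect_equal(nrow(m), 1)
  expect_equal(m$start, 702)
  expect_equal(m$anchorPositions[[1]],
               c(702, 703, 706, 710, 711, 719, 721, 753))
  expect_equal(m$anchorResidues[[1]],
               c("P", "W", "H", "Y", "R", "H", "R", "R"))
  expect_equal(nrow(scanSequence(strrep("A", 800), motifSpec())), 0)
  # too-short sequences return empty, not an error
  expect_equal(nrow(scanSequence("PWAAH", motifSpec())), 0)
})

test_that("the lysine variant at the gamma-phosphate arginine is fungal-only", {
  seqK <- plantMotif(strrep("A", 800), 702, fungal = TRUE)
  expect_equal(nrow(scanSequence(seqK, motifSpec())), 0)
  mK <- scanSequence(seqK, motifSpec(fungalVariant = TRUE))
  expect_equal(nrow(mK), 1)
  expect_true(mK$usedFungalVariant)
  expect_equal(mK$anchorResidues[[1]][5], "K")
})

test_that("scanning equals a brute-force window check on random sequences", {
  set.seed(101)
  spec <- motifSpec()
  for (i in 1:60) {
    L <- sample(60:200, 1)
    s <- paste(sample(c("P","W","H","Y","R","A","G"), L, replace = TRUE,
                      prob = c(3, 3, 4, 3, 6, 4, 4)), collapse = "")
    if (i %% 3 == 0 && L >= 60) s <- plantMotif(s, sample(L - 52, 1), spec)
    expect_equal(scanSequence(s, spec)$start, bruteMotifScan(s))
  }
})

test_that("spacer slack absorbs small insertions between anchors", {
  base <- strsplit(plantMotif(strrep("A", 200), 20), "")[[1]]
  # insert one residue inside the 31-residue spacer (after offset 25)
  stretched <- paste(c(base[1:50], "G", base[51:200]), collapse = "")
  expect_equal(nrow(scanSequence(stretched, motifSpec())), 0)
  m <- scanSequence(stretched, motifSpec(spacerSlack = 1L))
  expect_equal(nrow(m), 1)
  expect_equal(m$start, 20)
  expect_equal(m$anchorPositions[[1]][8], 20 + 52)  # last anchor shifted by 1
})

test_that("X never matches an anchor and input is case/terminator tolerant", {
  seq <- plantMotif(strrep("a", 800), 702)
  expect_equal(nrow(scanSequence(paste0(tolower(seq), "*"), motifSpec())), 1)
  chars <- strsplit(seq, "")[[1]]
  chars[702] <- "X"
  expect_equal(nrow(scanSequence(paste(chars, collapse = ""), motifSpec())), 0)
})

test_that("percent identity matches hand and combinatorial counts", {
  expect_equal(percentIdentity("PWAAH", "PWAAH"), 100)
  expect_equal(percentIdentity("PWAAH", "PWAAY"), 80)
  expect_equal(percentIdentity("PWAAH", "PWAAY"),
               percentIdentity("PWAAY", "PWAAH"))
  set.seed(102)
  aa <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
  L <- 300
  s <- sample(aa, L, replace = TRUE)
  k <- 30                                   # mutate exactly 10% of positions
  pos <- sample(L, k)
  s2 <- s
  for (p in pos) s2[p] <- sample(setdiff(aa, s[p]), 1)
  expect_equal(percentIdentity(paste(s, collapse = ""),
                               paste(s2, collapse = "")),
               100 * (L - k) / L, tolerance = 1e-9)
  expect_error(percentIdentity("", "PW"), "empty")
})

test_that("surveys recover planted prevalence and respect the variant flag", {
  fam <- makeSequenceFamily(familyDesign(nSequences = 80,
                                         motifPrevalence = 0.75,
                                         fungalFraction = 0.25, seed = 7))
  expect_equal(sum(fam$labels$motif != "absent"), 60)
  expect_equal(sum(fam$labels$motif == "fungal"), 15)
  # canonical spec: the 15 fungal members count as motif-absent
  svCanon <- motifSurvey(fam$sequences, fam$reference, spec = motifSpec())
  expect_equal(svCanon$nPassIdentity, 80)
  expect_equal(svCanon$nMotif, 45)
  # fungal-variant spec finds all 60
  svFun <- motifSurvey(fam$sequences, fam$reference,
                       spec = motifSpec(fungalVariant = TRUE))
  expect_equal(svFun$nMotif, 60)
  expect_equal(svFun$prevalence, 0.75)
  # an impossible identity threshold filters everything
  svNone <- motifSurvey(fam$sequences, fam$reference, minIdentity = 101)
  expect_equal(svNone$nPassIdentity, 0)
  expect_warning(motifSurvey(fam$sequences[1:2], strrep("A", 100)),
                 "does not contain the motif")
})
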