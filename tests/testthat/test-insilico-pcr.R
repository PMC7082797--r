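test_that("findPrimerMatches finds planted sites with IUPAC semantics", {
  tpl <- paste0("AAAA", "TTTGGG", "AAAA")
  hits <- findPrimerMatches(tpl, "TTTGGG")
  expect_identical(hits$start, 4L)
  expect_identical(hits$end, 10L)
  expect_identical(hits$mismatches, 0L)

  # degenerate primer, exact under subset matching
  hits2 <- findPrimerMatches(paste0("AAAA", "TTCGGG", "AAAA"), "TTYGGG")
  expect_identical(nrow(hits2), 1L)
  expect_identical(hits2$mismatches, 0L)

  # single planted mismatch: invisible at 0, found at 1
  tpl3 <- paste0("CCCC", "TTAGGG", "CCCC")
  expect_identical(nrow(findPrimerMatches(tpl3, "TTTGGG", maxMismatch = 0)), 0L)
  h3 <- findPrimerMatches(tpl3, "TTTGGG", maxMismatch = 1)
  expect_identical(h3$mismatches, 1L)

  expect_error(findPrimerMatches("ACGT", "ACGTACGT"),
               class = "NoMatchPossible")
})

test_that("mismatch counting agrees with a brute-force scan oracle", {
  set.seed(7)
  for (i in 1:25) {
    tpl <- randomDna(120)
    prm <- randomIupac(sample(8:15, 1))
    mmOracle <- oracleMismatch(tpl, prm)
    for (cutoff in c(0, 2, 5)) {
      got <- findPrimerMatches(tpl, prm, maxMismatch = cutoff)
      expect_identical(got$start, which(mmOracle <= cutoff) - 1L)
      expect_identical(got$mismatches, mmOracle[mmOracle <= cutoff])
    }
  }
})

test_that("the 3' anchor vetoes terminal mispairing", {
  # mismatch at the primer's last position
  tpl <- paste0("AAAA", "CCCGGT", "AAAA")
  expect_identical(nrow(findPrimerMatches(tpl, "CCCGGG", maxMismatch = 1)), 1L)
  expect_identical(
    nrow(findPrimerMatches(tpl, "CCCGGG", maxMismatch = 1, anchor3 = 3)), 0L)
  # mismatch well before the 3' end passes the anchor
  tpl2 <- paste0("AAAA", "CTCGGG", "AAAA")
  expect_identical(
    nrow(findPrimerMatches(tpl2, "CCCGGG", maxMismatch = 1, anchor3 = 3)), 1L)
})

test_that("amplify reports the spanned product with both primer regions", {
  fwd <- primer("F", "GGTCAACAAATCATAAAGAT")         # 20 nt
  rev <- primer("R", "TAAACTTCAGGGTGACCAAAAA")       # 22 nt
  tpl <- paste0(randomDna(50), residues(fwd),
                randomDna(330), revComp(residues(rev)),
                randomDna(78))
  amps <- amplify(tpl, primerPair(fwd, rev), maxMismatch = 0)
  expect_length(amps, 1)
  a <- amps[[1]]
  expect_identical(a@start, 50L)
  expect_identical(a@end, 422L)
  expect_identical(nchar(residues(a)), 372L)
  expect_identical(substr(residues(a), 1, 20), residues(fwd))
  expect_identical(substr(residues(a), 372 - 21, 372), revComp(residues(rev)))

  trimmed <- amplify(tpl, primerPair(fwd, rev), maxMismatch = 0,
                     trimPrimers = TRUE)[[1]]
  expect_identical(nchar(residues(trimmed)), 372L - 20L - 22L)

  # no reverse site anywhere: empty result, not an error
  tpl2 <- paste0(randomDna(50), residues(fwd), randomDna(200))
  expect_length(amplify(tpl2, primerPair(fwd, rev)), 0)
})

test_that("amplify spans the origin on circular templates", {
  fwd <- primer("F", "GGTCAACAAATCATAAAG")   # 18 nt
  rev <- primer("R", "TAAACTTCAGGGTGACCAAA") # 20 nt
  # forward site at [280, 298), reverse-complement site at [40, 60) on a
  # 300 nt circle: product wraps, length (60 - 280) mod 300 = 80
  tpl <- paste0(randomDna(40), revComp(residues(rev)),
                randomDna(220), residues(fwd), randomDna(2))
  expect_identical(nchar(tpl), 300L)
  amps <- amplify(tpl, primerPair(fwd, rev), maxMismatch = 0, circular = TRUE)
  expect_length(amps, 1)
  expect_identical(amps[[1]]@start, 280L)
  expect_identical(amps[[1]]@end, 360L)
  expect_identical(nchar(residues(amps[[1]])), 80L)
  # linear reading of the same template yields nothing
  expect_length(amplify(tpl, primerPair(fwd, rev), maxMismatch = 0), 0)
})

test_that("amplification lengths are strand-symmetric", {
  set.seed(11)
  pair <- defaultPrimerPairs()[["16S"]]
  cfg <- syntheticConfig(list(A = list(c(250, 188))), seqsPerSpecies = 3,
                         seed = 303)
  seqs <- simulateAmplicons(cfg)$sequences
  for (i in seq_along(seqs)) {
    tpl <- paste0(randomDna(25), as.character(seqs[[i]]), randomDna(25))
    lenPlus <- vapply(amplify(tpl, pair, maxMismatch = 0),
                      function(a) nchar(residues(a)), integer(1))
    lenMinus <- vapply(amplify(revComp(tpl), pair, maxMismatch = 0),
                       function(a) nchar(residues(a)), integer(1))
    expect_identical(sort(lenPlus), sort(lenMinus))
  }
})

test_that("a single planted primer pair yields exactly one product", {
  set.seed(23)
  pair <- defaultPrimerPairs()[["16S"]]
  fLen <- nchar(residues(pair@forward))
  rLen <- nchar(residues(pair@reverse))
  for (i in 1:100) {
    innerLen <- sample(80:300, 1)
    cfgLen <- fLen + rLen + innerLen
    cfg <- syntheticConfig(list(X = list(cfgLen)), seqsPerSpecies = 1,
                           ampliconLength = cfgLen, seed = i)
    tplSeq <- as.character(simulateAmplicons(cfg)$sequences[[1]])
    amps <- amplify(tplSeq, pair, maxMismatch = 0)
    expect_length(amps, 1)
    expect_identical(nchar(residues(amps[[1]])), cfgLen)
  }
})

test_that("bundled primer pairs carry the published geometry", {
  pairs <- defaultPrimerPairs()
  expect_setequal(names(pairs), c("16S", "COI-short", "COI-LCO", "COI-long"))
  expect_identical(residues(pairs[["16S"]]@forward), "TTAAATTGCTGTRGTATT")
  expect_identical(pairs[["16S"]]@expectedLength, 438L)
  expect_identical(pairs[["COI-LCO"]]@expectedLength, 710L)
})
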