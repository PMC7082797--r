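test_that("parseFasta normalizes residues and reads header tags", {
  fa <- parseFasta(c(">x", "acgt"), text = TRUE)
  expect_identical(as.character(fa)[[1]], "ACGT")
  expect_identical(S4Vectors::mcols(fa)$topology, "linear")

  fa2 <- parseFasta(c(">a [species=H. longicornis] [region=16S]", "TTTAAA"),
                    text = TRUE)
  expect_identical(names(fa2), "a")
  expect_identical(S4Vectors::mcols(fa2)$species, "H. longicornis")
  expect_identical(S4Vectors::mcols(fa2)$region, "16S")

  # RNA input folds to DNA
  fa3 <- parseFasta(c(">r", "acgu"), text = TRUE)
  expect_identical(as.character(fa3)[[1]], "ACGT")
})

test_that("parseFasta reports bad alphabet with record and position", {
  err <- tryCatch(parseFasta(c(">b", "ACQT"), text = TRUE),
                  error = function(e) e)
  expect_s3_class(err, "AlphabetError")
  expect_identical(err$record, "b")
  expect_identical(err$position, 3L)

  expect_error(parseFasta(character(0), text = TRUE), class = "EmptyInput")
  expect_error(parseFasta(c(">a", "ACGT", ">a", "ACGT"), text = TRUE),
               class = "DuplicateId")
})

test_that("FASTA writing round-trips records and is byte-stable", {
  lines <- c(">s1 [species=H. longicornis] [region=16S]",
             paste(rep("ACGTRYSWKMBDHVN", 10), collapse = ""),
             ">s2 [topology=circular]", "TTTAAACCC",
             ">s3", "ACGT")
  seqs <- parseFasta(lines, text = TRUE)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  writeFasta(seqs, f1)
  back <- parseFasta(f1)
  expect_identical(names(back), names(seqs))
  expect_identical(as.character(back), as.character(seqs))
  expect_identical(S4Vectors::mcols(back), S4Vectors::mcols(seqs))
  writeFasta(back, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("sidecar species map fills in labels", {
  seqs <- parseFasta(c(">a", "ACGT", ">b", "TTTT"), text = TRUE)
  mapFile <- tempfile()
  writeLines("a\tH. leachi", mapFile)
  mapped <- applySpeciesMap(seqs, mapFile)
  expect_identical(S4Vectors::mcols(mapped)$species, c("H. leachi", NA))
})

test_that("revComp complements ambiguity codes and is an involution", {
  expect_identical(revComp("ACGT"), "ACGT")
  expect_identical(revComp("RGA"), "TCY")
  expect_error(revComp("ACXT"), class = "AlphabetError")

  set.seed(101)
  for (i in 1:300) {
    s <- randomIupac(sample(1:60, 1))
    expect_identical(revComp(revComp(s)), s)
    expect_identical(revComp(s), oracleRevComp(s))
  }
})

test_that("iupacMatch implements subset and intersection semantics", {
  expect_true(iupacMatch("R", "A"))
  expect_false(iupacMatch("R", "N"))
  expect_true(iupacMatch("R", "N", mode = "permissive"))
  expect_false(iupacMatch("A", "C", mode = "permissive"))

  # across all 225 symbol pairs: strict implies permissive, and both agree
  # with direct base-set computations
  codes <- names(ORACLE_SETS)
  for (p in codes) {
    for (t in codes) {
      strict <- iupacMatch(p, t)
      perm <- iupacMatch(p, t, mode = "permissive")
      expect_identical(strict, all(ORACLE_SETS[[t]] %in% ORACLE_SETS[[p]]))
      expect_identical(perm,
                       length(intersect(ORACLE_SETS[[t]],
                                        ORACLE_SETS[[p]])) > 0)
      if (strict) expect_true(perm)
    }
  }
})

test_that("positionwise matching works on whole strings", {
  expect_identical(iupacMatch("TTYGGG", "TTCGGG"), rep(TRUE, 6))
})
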