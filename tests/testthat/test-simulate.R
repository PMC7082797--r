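draI <- restrictionEnzyme("DraI", "TTTAAA", 3)

test_that("planted fragment patterns are exact ground truth at zero noise", {
  cfg <- syntheticConfig(list(A = list(c(200L, 150L, 88L))),
                         seqsPerSpecies = 4, seed = 17)
  sim <- simulateAmplicons(cfg)
  expect_length(sim$sequences, 4)
  for (i in seq_along(sim$sequences)) {
    expect_identical(fragments(digestLinear(sim$sequences[i], draI)),
                     c(200L, 150L, 88L))
  }
  expect_identical(unique(sim$truth$intended_fragments), "200,150,88")
})

test_that("the same seed reproduces the dataset byte for byte", {
  cfg <- syntheticConfig(list(A = list(c(300L, 138L)), B = list(438L)),
                         seqsPerSpecies = 5, substitutionRate = 0.01,
                         seed = 4242)
  f1 <- tempfile(); f2 <- tempfile()
  writeFasta(simulateAmplicons(cfg)$sequences, f1)
  writeFasta(simulateAmplicons(cfg)$sequences, f2)
  expect_identical(readLines(f1), readLines(f2))
  # a different seed gives different residues
  cfg2 <- syntheticConfig(list(A = list(c(300L, 138L)), B = list(438L)),
                          seqsPerSpecies = 5, substitutionRate = 0.01,
                          seed = 4243)
  f3 <- tempfile()
  writeFasta(simulateAmplicons(cfg2)$sequences, f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("infeasible geometries are refused", {
  expect_error(syntheticConfig(list()), class = "InfeasibleConfig")
  # fragments not summing to the amplicon length fail validity
  expect_error(syntheticConfig(list(A = list(c(100L, 100L)))))
  # a cut so close to the next that sites would overlap
  expect_error(
    simulateAmplicons(syntheticConfig(list(A = list(c(100L, 3L, 335L))),
                                      seed = 1)),
    class = "InfeasibleConfig")
  # a cut inside the primer-binding region
  expect_error(
    simulateAmplicons(syntheticConfig(list(A = list(c(5L, 433L))), seed = 1)),
    class = "InfeasibleConfig")
})

test_that("generated amplicons amplify to exactly one full-length product", {
  cfg <- syntheticConfig(list(A = list(c(250L, 188L)), B = list(438L)),
                         seqsPerSpecies = 3, substitutionRate = 0.005,
                         seed = 88)
  sim <- simulateAmplicons(cfg)
  pair <- defaultPrimerPairs()[["16S"]]
  for (i in seq_along(sim$sequences)) {
    amps <- amplify(sim$sequences[i], pair, maxMismatch = 0)
    expect_length(amps, 1)
    expect_identical(nchar(residues(amps[[1]])),
                     nchar(as.character(sim$sequences[[i]])))
  }
})

test_that("zero-noise datasets reproduce their planted pattern counts", {
  set.seed(2025)
  for (rep in 1:10) {
    planted <- randomPlanted(sample(2:4, 1))
    cfg <- syntheticConfig(planted,
                           seqsPerSpecies = sample(3:8, 1),
                           seed = 5000 + rep)
    sim <- simulateAmplicons(cfg)
    counts <- patternCounts(groupPatterns(sim$sequences, draI))
    expect_identical(counts[names(planted)],
                     vapply(planted, function(p) length(p), integer(1)))
  }
})

test_that("low mutation rates mostly preserve planted counts", {
  set.seed(3030)
  ok <- 0
  nRep <- 20
  for (rep in 1:nRep) {
    planted <- list(A = list(c(250L, 188L)), B = list(438L))
    cfg <- syntheticConfig(planted, seqsPerSpecies = 10,
                           substitutionRate = 0.005, seed = 7000 + rep)
    sim <- simulateAmplicons(cfg)
    counts <- patternCounts(groupPatterns(sim$sequences, draI))
    if (identical(counts, c(A = 1L, B = 1L))) ok <- ok + 1
  }
  expect_gte(ok, 0.8 * nRep)
})

test_that("indels shift fragment boundaries but keep the amplicon viable", {
  cfg <- syntheticConfig(list(A = list(c(250L, 188L))), seqsPerSpecies = 6,
                         indelRate = 0.01, seed = 61)
  sim <- simulateAmplicons(cfg)
  lens <- unname(nchar(as.character(sim$sequences)))
  expect_true(any(lens != 438L))
  for (i in seq_along(sim$sequences)) {
    dg <- digestLinear(sim$sequences[i], draI)
    expect_identical(sum(fragments(dg)), lens[i])
  }
})
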